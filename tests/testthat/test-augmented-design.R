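test_that("check ANOVA recovers zero error on purely additive data", {
  cm <- outer(c(10, 14, 18), c(0, 2, 5, 1), "+")  # check mean + block offset
  dimnames(cm) <- list(paste0("chk", 1:3), paste0("B", 1:4))
  x <- toy_trial(cm, list(B1 = c(G1 = 9), B2 = c(G2 = 12)))
  ca <- check_anova(x, "TFM")
  expect_equal(ca$sigma2_e, 0, tolerance = 1e-12)
  expect_equal(ca$df_error, 6)
})

test_that("check ANOVA matches the least-squares oracle", {
  for (seed in 1:5) {
    x <- random_trial(b = 4, c = 3, n_tests = 6, seed = seed)
    chk <- x[x$role == "check", ]
    chk_tab <- trial_table(chk, traits = trait_registry(x))
    ora <- lm_oracle(chk_tab, "TFM")
    expect_equal(check_anova(x, "TFM")$sigma2_e, ora$sigma2, tolerance = 1e-10)
  }
  # explicit 2x2 instance against the direct residual computation
  cm <- matrix(c(1, 3, 2, 5), 2, 2, dimnames = list(c("c1", "c2"), c("B1", "B2")))
  x <- toy_trial(cm, list(B1 = c(G1 = 4), B2 = c(G2 = 6)))
  # residual of a saturated-minus-interaction 2x2 layout: (y11 - y12 - y21 + y22)^2 / 4
  expect_equal(check_anova(x, "TFM")$sigma2_e, (1 - 2 - 3 + 5)^2 / 4, tolerance = 1e-12)
})

test_that("error estimate is invariant to block and genotype relabeling", {
  x <- random_trial(b = 3, c = 4, n_tests = 6, seed = 21)
  s0 <- check_anova(x, "TFM")$sigma2_e
  y <- as.data.frame(x)
  y$block <- c(B1 = "Bz", B2 = "Ba", B3 = "Bm")[y$block]
  y$genotype_id <- paste0("re_", y$genotype_id)
  y <- trial_table(y, traits = trait_registry(x))
  expect_equal(check_anova(y, "TFM")$sigma2_e, s0, tolerance = 1e-12)
})

test_that("block effects come from check means and sum to zero", {
  cm <- matrix(c(10, 20, 20, 30), 2, 2,
               dimnames = list(c("c1", "c2"), c("B1", "B2")))  # B2 uniformly +10
  x <- toy_trial(cm, list(B1 = c(G1 = 5), B2 = c(G2 = 7)))
  be <- block_effects(x, "TFM")
  expect_equal(unname(be), c(-5, 5))
  expect_equal(sum(be), 0)

  # identical blocks give zero effects; adding a constant changes nothing
  cm0 <- matrix(c(10, 20, 10, 20), 2, 2,
                dimnames = list(c("c1", "c2"), c("B1", "B2")))
  x0 <- toy_trial(cm0, list(B1 = c(G1 = 5), B2 = c(G2 = 7)))
  expect_equal(unname(block_effects(x0, "TFM")), c(0, 0))
  xc <- as.data.frame(x)
  xc$TFM <- xc$TFM + 100
  xc <- trial_table(xc, traits = trait_registry(x))
  expect_equal(block_effects(xc, "TFM"), be)
})

test_that("adjustment subtracts block effects and matches the lm oracle", {
  # zero block effects: adjusted equals raw
  cm0 <- matrix(c(10, 20, 10, 20), 2, 2,
                dimnames = list(c("c1", "c2"), c("B1", "B2")))
  x0 <- toy_trial(cm0, list(B1 = c(G1 = 5), B2 = c(G2 = 7)))
  ad0 <- adjust_trial(x0, "TFM")
  expect_equal(ad0$adjusted$value, ad0$adjusted$observed)

  # test-genotype contrasts equal the least-squares solution
  for (seed in 6:9) {
    x <- random_trial(b = 4, c = 3, n_tests = 6, seed = seed)
    ad <- adjust_trial(x, "TFM")
    ora <- lm_oracle(x, "TFM")
    v <- ad$adjusted$value
    names(v) <- ad$adjusted$genotype_id
    ids <- names(v)
    for (k in seq(2, length(ids))) {
      expect_equal(unname(v[ids[1]] - v[ids[k]]),
                   lm_contrast(ora, ids[1], ids[k]), tolerance = 1e-8)
    }
    expect_equal(ad$sigma2_e, ora$sigma2, tolerance = 1e-8)
  }
})

test_that("noiseless simulated trials recover genotype effects exactly", {
  cfg <- simulation_config(
    traits = data.frame(name = "TFM", mu = 100, sigma2_g = 25, sigma2_e = 0,
                        block_sd = 3),
    n_blocks = 3, checks = c("c1", "c2", "c3"), n_tests = 12, seed = 99
  )
  sim <- simulate_trial(cfg)
  ad <- adjust_trial(sim$table, "TFM")
  g_true <- sim$truth$genetic[ad$adjusted$genotype_id, "TFM"]
  expect_equal(ad$adjusted$value, unname(100 + g_true), tolerance = 1e-9)
})

test_that("per-block shifts leave adjusted test values unchanged", {
  x <- random_trial(b = 3, c = 3, n_tests = 6, seed = 31)
  ad <- adjust_trial(x, "TFM")
  # mean-zero block shifts cancel exactly
  y <- as.data.frame(x)
  shift0 <- c(B1 = 4, B2 = -2, B3 = -2)
  y$TFM <- y$TFM + shift0[y$block]
  y <- trial_table(y, traits = trait_registry(x))
  ady <- adjust_trial(y, "TFM")
  expect_equal(ady$adjusted$value, ad$adjusted$value, tolerance = 1e-10)
  # a general shift moves every adjusted value by its mean only:
  # genotype contrasts are untouched
  z <- as.data.frame(x)
  shift <- c(B1 = 4, B2 = -2, B3 = 11)
  z$TFM <- z$TFM + shift[z$block]
  z <- trial_table(z, traits = trait_registry(x))
  adz <- adjust_trial(z, "TFM")
  expect_equal(adz$adjusted$value - mean(shift), ad$adjusted$value,
               tolerance = 1e-10)
})

test_that("missing check plots abort the analysis rather than being imputed", {
  x <- as.data.frame(random_trial(b = 3, c = 3, n_tests = 3, seed = 41))
  x$TFM[x$genotype_id == "chk1" & x$block == "B2"] <- NA
  x <- trial_table(x, traits = trait_spec("TFM"))
  expect_error(check_anova(x, "TFM"), "missing check plot.*chk1.*B2")
})

test_that("augmented ANOVA degrees of freedom are additive", {
  x <- random_trial(b = 4, c = 3, n_tests = 9, seed = 51)
  tab <- anova_augmented(x, "TFM")
  top <- tab[tab$source %in% c("blocks", "treatments (adj.)", "error"), ]
  expect_equal(sum(top$df), nrow(x) - 1)
  split_df <- tab$df[tab$source %in%
                       c("  checks", "  genotypes (adj.)", "  checks vs genotypes")]
  expect_equal(sum(split_df), tab$df[tab$source == "treatments (adj.)"])
  expect_true(all(tab$df >= 0))
  p <- tab$p[!is.na(tab$p)]
  expect_true(all(p >= 0 & p <= 1))
})

test_that("identical checks yield zero check sum of squares", {
  cm <- matrix(5, 3, 3, dimnames = list(paste0("c", 1:3), paste0("B", 1:3)))
  x <- toy_trial(cm, list(B1 = c(G1 = 3, G2 = 9), B2 = c(G3 = 1), B3 = c(G4 = 2)))
  tab <- anova_augmented(x, "TFM")
  expect_equal(tab$ss[tab$source == "  checks"], 0)
})

test_that("genotype F is near 1 on average when genotypic variance is zero", {
  cfg <- simulation_config(
    traits = data.frame(name = "TFM", mu = 50, sigma2_g = 0, sigma2_e = 4),
    n_blocks = 4, checks = sprintf("c%d", 1:10), n_tests = 20, seed = 1
  )
  f <- vapply(1:300, function(r) {
    sim <- simulate_trial(cfg, seed = 5000 + r)
    tab <- anova_augmented(sim$table, "TFM")
    tab$f[tab$source == "  genotypes (adj.)"]
  }, 0)
  # adjusted values carry a little block-estimation noise, so E[F] sits
  # slightly above 1; the null is still far from the significance region
  expect_gt(mean(f), 0.85)
  expect_lt(mean(f), 1.35)
})

test_that("Federer weighted mean reduces to the grand mean for all-check trials", {
  cm <- matrix(rnorm(12, 20), 3, 4,
               dimnames = list(paste0("c", 1:3), paste0("B", 1:4)))
  x <- toy_trial(cm, setNames(list(), character()))
  expect_equal(federer_weighted_mean(x, "TFM"), mean(cm), tolerance = 1e-12)
})

test_that("Federer weighted mean matches the hand-computed replication weighting", {
  cm <- matrix(c(10, 12, 14, 16), 2, 2,
               dimnames = list(c("c1", "c2"), c("B1", "B2")))
  x <- toy_trial(cm, list(B1 = c(G1 = 20), B2 = c(G2 = 30)))
  ad <- adjust_trial(x, "TFM")
  adj <- ad$adjusted$value
  by_hand <- (2 * mean(cm["c1", ]) + 2 * mean(cm["c2", ]) + sum(adj)) / (4 + 2)
  expect_equal(ad$mu_f, by_hand, tolerance = 1e-12)
  # sanity: mu and muF stay within one check-range of each other
  expect_lt(abs(ad$mu - ad$mu_f), diff(range(cm)) + diff(range(adj)) + 1)
})

test_that("coefficient of variation follows 100*sqrt(MSe)/mean", {
  expect_equal(cv_percent(100^2 / 100, 100), 10)
  expect_equal(cv_percent(12997.73, 976.67), 11.67, tolerance = 0.005)
  expect_equal(cv_percent(4 * 12997.73, 2 * 976.67), cv_percent(12997.73, 976.67))
  expect_error(cv_percent(1, 0), "positive mean")
})
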