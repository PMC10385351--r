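# Fixtures built in code: small deterministic augmented trials and
# independent oracles used across test files.

# A toy augmented trial from an explicit check matrix (checks x blocks) and a
# named list of test-genotype plot values (block -> named value vector).
toy_trial <- function(check_values, test_values, trait = "TFM",
                      specs = trait_spec(trait, direction = 1L)) {
  checks <- rownames(check_values)
  blocks <- colnames(check_values)
  rows <- data.frame(
    genotype_id = rep(checks, times = ncol(check_values)),
    population_id = "checks", role = "check",
    block = rep(blocks, each = nrow(check_values)),
    value = as.vector(check_values), stringsAsFactors = FALSE
  )
  for (blk in names(test_values)) {
    v <- test_values[[blk]]
    rows <- rbind(rows, data.frame(
      genotype_id = names(v), population_id = "tests", role = "test",
      block = blk, value = unname(v), stringsAsFactors = FALSE
    ))
  }
  names(rows)[names(rows) == "value"] <- trait
  trial_table(rows, traits = specs)
}

# A random small augmented trial (values standard normal plus optional
# additive structure), for oracle-equivalence and invariance loops.
random_trial <- function(b, c, n_tests, seed, trait = "TFM") {
  set.seed(seed)
  blocks <- sprintf("B%d", seq_len(b))
  checks <- sprintf("chk%d", seq_len(c))
  cm <- matrix(rnorm(b * c, mean = 10), c, b, dimnames = list(checks, blocks))
  tv <- lapply(seq_len(b), function(j) {
    ids <- sprintf("G%d_%d", j, seq_len(ceiling(n_tests / b)))
    stats::setNames(rnorm(length(ids), mean = 10), ids)
  })
  names(tv) <- blocks
  toy_trial(cm, tv, trait = trait)
}

# Independent least-squares oracle for the augmented model
# y = mu + genotype + block: plain lm() fit, treatment contrasts.
lm_oracle <- function(x, trait) {
  df <- as.data.frame(x)
  df$genotype_id <- factor(df$genotype_id)
  df$block <- factor(df$block)
  fit <- stats::lm(stats::reformulate(c("genotype_id", "block"), trait), data = df)
  list(fit = fit, sigma2 = stats::sigma(fit)^2,
       effects = stats::coef(fit))
}

# Effect contrast between two genotypes from the lm oracle.
lm_contrast <- function(oracle, g1, g2) {
  cf <- oracle$effects
  pick <- function(g) {
    nm <- paste0("genotype_id", g)
    if (nm %in% names(cf)) cf[[nm]] else 0  # reference level
  }
  pick(g1) - pick(g2)
}

# Brute-force Mulamba-Mock oracle: ranks by pairwise comparison counting
# (average ties), weighted sums by explicit loops, selection by smallest
# (index, id).
brute_rank_sum <- function(values, directions, weights) {
  n <- nrow(values)
  ranks <- matrix(NA_real_, n, ncol(values))
  for (j in seq_len(ncol(values))) {
    v <- directions[j] * values[, j]
    for (i in seq_len(n)) {
      better <- sum(v > v[i])
      tied <- sum(v == v[i])
      ranks[i, j] <- better + (1 + tied) / 2  # average rank among ties
    }
  }
  idx <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(values))) idx[i] <- idx[i] + weights[j] * ranks[i, j]
  }
  list(ranks = ranks, index = idx)
}

brute_select <- function(index, ids, n_sel) {
  ord <- order(index, ids)
  ids[ord][seq_len(n_sel)]
}

# Brute-force UPGMA oracle: explicit agglomeration over the original
# distance matrix; returns the cophenetic matrix (height at which each pair
# first shares a cluster).
brute_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < best_h) {
          best_h <- h
          best <- c(a, b)
        }
      }
    }
    for (i in clusters[[best[1]]]) {
      for (j in clusters[[best[2]]]) coph[i, j] <- coph[j, i] <- best_h
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Printed genetic-parameter report rows used by the identity suite
# (column order: TFM, CFM, CFN, ACFM, TSS, F, L, Hue, C).
published_panel <- function() {
  list(
    traits = c("TFM", "CFM", "CFN", "ACFM", "TSS", "F", "L", "Hue", "C"),
    sigma2_p = c(29096.89, 24564.06, 160.38, 7.63, 0.31, 0.98, 114.72, 344.01, 80.25),
    sigma2_e = c(12997.73, 11262.51, 64.69, 1.90, 0.14, 0.32, 0.81, 30.83, 5.05),
    sigma2_g = c(16098.97, 13301.55, 95.69, 5.73, 0.17, 0.66, 113.91, 313.17, 75.70),
    h2 = c(55.32, 54.15, 59.66, 75.09, 54.02, 67.49, 99.29, 91.03, 93.70),
    cvg_cve = c(1.11, 1.08, 1.21, 1.73, 1.08, 1.44, 11.84, 3.19, 3.86),
    xo = c(976.67, 785.21, 50.19, 19.12, 6.66, 9.66, 39.91, 54.84, 32.55),
    xs = c(1219.45, 1047.56, 65.68, 20.07, 6.68, 9.94, 52.98, 71.66, 37.65),
    gg = c(134.33, 142.06, 9.24, 0.71, 0.01, 0.19, 12.98, 15.31, 4.78),
    gs_pct = c(13.75, 18.09, 18.42, 3.72, 0.16, 1.98, 32.52, 27.91, 14.68)
  )
}
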