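#' Configure a synthetic augmented-block trial
#'
#' Defines the generative model the analysis assumes: plot value =
#' trait mean + genotypic effect + block effect + residual, with genotypic
#' effects drawn from a multivariate normal across traits (configured
#' variances and genetic correlation matrix), fixed normal block effects,
#' and residuals independent across traits unless a residual correlation
#' matrix is supplied.  Checks receive one fixed genotypic draw each and are
#' replicated in every block; test genotypes appear once, assigned to blocks
#' round-robin.
#'
#' @param traits data.frame with columns `name`, `mu` (trait units),
#'   `sigma2_g`, `sigma2_e` (squared trait units), and optionally `block_sd`
#'   (defaults to `0.3 * sqrt(sigma2_e)`), `direction`, `units`.
#' @param n_blocks number of blocks (default 5).
#' @param checks character vector of check ids (default 13 checks).
#' @param n_tests number of unreplicated test genotypes (default 870).
#' @param genetic_cor trait x trait genetic correlation matrix (symmetric
#'   positive semi-definite, unit diagonal; default identity).
#' @param residual_cor optional residual correlation matrix across traits
#'   (default: independent residuals).
#' @param populations optional named integer vector of per-population test
#'   counts summing to `n_tests`.
#' @param seed integer master seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(traits, n_blocks = 5,
                              checks = sprintf("check_%02d", 1:13),
                              n_tests = 870, genetic_cor = NULL,
                              residual_cor = NULL, populations = NULL,
                              seed = 20230714) {
  traits <- as.data.frame(traits)
  stopifnot(all(c("name", "mu", "sigma2_g", "sigma2_e") %in% names(traits)))
  if (any(traits$sigma2_g < 0) || any(traits$sigma2_e < 0)) {
    stop("variances must be non-negative")
  }
  if (is.null(traits$block_sd)) traits$block_sd <- 0.3 * sqrt(traits$sigma2_e)
  if (is.null(traits$direction)) traits$direction <- 1L
  if (is.null(traits$units)) traits$units <- ""
  k <- nrow(traits)
  if (is.null(genetic_cor)) genetic_cor <- diag(k)
  genetic_cor <- as.matrix(genetic_cor)
  check_cor_matrix(genetic_cor, k, "genetic")
  if (!is.null(residual_cor)) check_cor_matrix(as.matrix(residual_cor), k, "residual")
  if (!is.null(populations)) {
    if (sum(populations) != n_tests) {
      stop("population counts must sum to n_tests")
    }
  }
  cfg <- list(traits = traits, n_blocks = as.integer(n_blocks),
              checks = as.character(checks), n_tests = as.integer(n_tests),
              genetic_cor = genetic_cor, residual_cor = residual_cor,
              populations = populations, seed = as.integer(seed))
  if (cfg$n_blocks < 2) stop("need at least 2 blocks")
  if (length(cfg$checks) < 2) stop("need at least 2 checks")
  class(cfg) <- "simulation_config"
  cfg
}

check_cor_matrix <- function(m, k, what) {
  if (!all(dim(m) == k)) stop(what, " correlation matrix has wrong dimension")
  if (!isSymmetric(unname(m), tol = 1e-8)) stop(what, " correlation matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop(what, " correlation matrix must have unit diagonal")
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop(what, " correlation matrix is not positive semi-definite")
  }
  invisible(m)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Synthetic augmented trial: %d blocks x %d checks + %d tests, %d traits, seed %d\n",
              x$n_blocks, length(x$checks), x$n_tests, nrow(x$traits), x$seed))
  invisible(x)
}

#' Reference simulation preset at published trial scale
#'
#' A nine-trait configuration at the scale of a real strawberry augmented
#' trial (5 blocks, 13 checks, 870 test genotypes in five cross-derived
#' populations), with per-trait means and variance components of the
#' magnitudes reported for strawberry production and post-harvest traits,
#' a mildly positive genetic correlation block among the production traits
#' (TFM/CFM/CFN r = 0.7) and a negative hue-production correlation
#' (Hue-TFM r = -0.4).  Directions are all set to +1 (including L and Hue,
#' an explicit choice).  Fully reproducible from its fixed default seed.
#'
#' @param seed master seed (default 20230714).
#' @return a [simulation_config()].
#' @export
table1_preset <- function(seed = 20230714) {
  traits <- data.frame(
    name = c("TFM", "CFM", "CFN", "ACFM", "TSS", "F", "L", "Hue", "C"),
    mu = c(976.67, 785.21, 50.19, 19.12, 6.66, 9.66, 39.91, 54.84, 32.55),
    sigma2_g = c(16098.97, 13301.55, 95.69, 5.73, 0.17, 0.66, 113.91, 313.17, 75.70),
    sigma2_e = c(12997.73, 11262.51, 64.69, 1.90, 0.14, 0.32, 0.81, 30.83, 5.05),
    direction = 1L,
    units = c("g/plant", "g/plant", "count", "g/fruit", "degrees Brix", "N",
              "", "degrees", ""),
    stringsAsFactors = FALSE
  )
  k <- nrow(traits)
  r <- diag(k)
  dimnames(r) <- list(traits$name, traits$name)
  prod <- c("TFM", "CFM", "CFN")
  r[prod, prod] <- 0.7
  diag(r) <- 1
  r["Hue", "TFM"] <- r["TFM", "Hue"] <- -0.4
  simulation_config(
    traits = traits, n_blocks = 5, checks = sprintf("check_%02d", 1:13),
    n_tests = 870, genetic_cor = r,
    populations = c(pop_1 = 194L, pop_2 = 171L, pop_3 = 163L,
                    pop_4 = 152L, pop_5 = 190L),
    seed = seed
  )
}

#' Simulate an augmented-block trial with known truth
#'
#' Draws genotypic effects (checks and tests) from the configured
#' multivariate normal, fixed block effects, and residuals, and assembles the
#' plot table Y = mu + g + B + e.  Identical seeds give identical tables.
#'
#' @param config a [simulation_config()].
#' @param seed seed override (default: `config$seed`).
#' @return list with `table` (a [trial_table()]) and `truth` (list with
#'   `genetic` — genotype x trait matrix of true genotypic effects,
#'   `blocks` — block x trait matrix of true block effects, and `config`).
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  tr <- config$traits
  k <- nrow(tr)
  b <- config$n_blocks
  blocks <- sprintf("B%d", seq_len(b))
  test_ids <- sprintf("G%04d", seq_len(config$n_tests))
  ids <- c(config$checks, test_ids)
  n_all <- length(ids)

  d <- sqrt(tr$sigma2_g)
  sigma_g <- diag(d, k) %*% config$genetic_cor %*% diag(d, k)
  g <- MASS::mvrnorm(n_all, mu = rep(0, k), Sigma = sigma_g)
  dimnames(g) <- list(ids, tr$name)

  blk <- matrix(stats::rnorm(b * k, 0, rep(tr$block_sd, each = b)), b, k,
                dimnames = list(blocks, tr$name))
  # fixed block effects carry the usual sum-to-zero constraint; the grand
  # mean absorbs any common level
  blk <- sweep(blk, 2, colMeans(blk))

  # plot layout: every check in every block, tests round-robin
  plot_geno <- c(rep(config$checks, times = b), test_ids)
  plot_block <- c(rep(blocks, each = length(config$checks)),
                  blocks[(seq_len(config$n_tests) - 1L) %% b + 1L])
  n_plots <- length(plot_geno)

  if (is.null(config$residual_cor)) {
    e <- matrix(stats::rnorm(n_plots * k, 0, rep(sqrt(tr$sigma2_e), each = n_plots)),
                n_plots, k)
  } else {
    d_e <- sqrt(tr$sigma2_e)
    sigma_e <- diag(d_e, k) %*% config$residual_cor %*% diag(d_e, k)
    e <- MASS::mvrnorm(n_plots, mu = rep(0, k), Sigma = sigma_e)
  }

  y <- matrix(rep(tr$mu, each = n_plots), n_plots, k) +
    g[plot_geno, , drop = FALSE] + blk[plot_block, , drop = FALSE] + e
  colnames(y) <- tr$name

  pop <- rep("checks", n_plots)
  is_test <- plot_geno %in% test_ids
  if (!is.null(config$populations)) {
    pop_of_test <- rep(names(config$populations), times = config$populations)
    pop[is_test] <- pop_of_test[match(plot_geno[is_test], test_ids)]
  } else {
    pop[is_test] <- "tests"
  }

  df <- data.frame(
    genotype_id = plot_geno, population_id = pop,
    role = ifelse(is_test, "test", "check"), block = plot_block,
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(y))
  specs <- trait_spec(tr$name, direction = tr$direction, units = tr$units)
  list(
    table = trial_table(df, traits = specs),
    truth = list(genetic = g, blocks = blk, config = config, seed = seed)
  )
}

sub_seed <- function(master, rep) {
  as.integer((as.numeric(master) * 2654435761 + rep * 97) %% 2147483647)
}

#' Monte-Carlo parameter-recovery experiment
#'
#' Runs the full pipeline (simulate, adjust, estimate parameters, weight,
#' rank, select) `n_reps` times and summarizes, per trait, the bias and RMSE
#' of the heritability and genotypic-variance estimates, the expected gain
#' GG = (Xs - Xo) h2, and the realized response to selection (mean true
#' genotypic value of the selected set minus the test-population mean of
#' true genotypic values).  Replicate seeds are derived deterministically
#' from the master seed.
#'
#' @param config a [simulation_config()].
#' @param n_reps number of replicates (>= 2).
#' @param intensity selection intensity (default 0.05).
#' @param weights `"cvg"`, `"unit"`, or a numeric vector of per-trait
#'   weights.
#' @param tie_policy rank tie policy (see [rank_traits()]).
#' @param seed master seed (default `config$seed`).
#' @return object of class `recovery_summary`: data.frame with one row per
#'   trait and columns `trait`, `true_h2`, `mean_h2`, `bias_h2`, `rmse_h2`,
#'   `true_sigma2_g`, `mean_sigma2_g`, `bias_sigma2_g`, `mean_expected_gg`,
#'   `mean_realized_gg`, `se_gain_diff` (Monte-Carlo standard error of the
#'   mean paired difference between realized and expected gain),
#'   `mean_gs_pct`; `n_reps` attached as an attribute.
#' @export
recovery_experiment <- function(config, n_reps = 200, intensity = 0.05,
                                weights = "cvg", tie_policy = "average",
                                seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_reps < 2) stop("need at least 2 replicates")
  tr <- config$traits
  k <- nrow(tr)
  h2_hat <- s2g_hat <- exp_gg <- real_gg <- gs_pct <-
    matrix(NA_real_, n_reps, k, dimnames = list(NULL, tr$name))

  for (r in seq_len(n_reps)) {
    sim <- tryCatch(
      simulate_trial(config, seed = sub_seed(seed, r)),
      error = function(e) stop(sprintf("replicate %d: %s", r, conditionMessage(e)))
    )
    res <- tryCatch(
      replicate_estimates(sim, intensity = intensity, weights = weights,
                          tie_policy = tie_policy),
      error = function(e) stop(sprintf("replicate %d: %s", r, conditionMessage(e)))
    )
    h2_hat[r, ] <- res$h2
    s2g_hat[r, ] <- res$sigma2_g
    exp_gg[r, ] <- res$expected_gg
    real_gg[r, ] <- res$realized_gg
    gs_pct[r, ] <- res$gs_pct
  }

  true_h2 <- tr$sigma2_g / (tr$sigma2_g + tr$sigma2_e)
  diff <- real_gg - exp_gg
  out <- data.frame(
    trait = tr$name,
    true_h2 = true_h2,
    mean_h2 = colMeans(h2_hat),
    bias_h2 = colMeans(h2_hat) - true_h2,
    rmse_h2 = sqrt(colMeans((h2_hat - matrix(true_h2, n_reps, k, byrow = TRUE))^2)),
    true_sigma2_g = tr$sigma2_g,
    mean_sigma2_g = colMeans(s2g_hat),
    bias_sigma2_g = colMeans(s2g_hat) - tr$sigma2_g,
    mean_expected_gg = colMeans(exp_gg),
    mean_realized_gg = colMeans(real_gg),
    se_gain_diff = apply(diff, 2, stats::sd) / sqrt(n_reps),
    mean_gs_pct = colMeans(gs_pct),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_reps") <- n_reps
  class(out) <- c("recovery_summary", "data.frame")
  out
}

# One replicate's estimates: parameter panel, CVg-weighted rank selection,
# expected gain, and realized response read off the simulation truth.
replicate_estimates <- function(sim, intensity, weights, tie_policy) {
  x <- sim$table
  traits <- trial_traits(x)
  adjusted <- lapply(traits, function(t) adjust_trial(x, t))
  names(adjusted) <- traits

  est <- lapply(adjusted, function(ad) {
    vc <- variance_components(ad)
    xo <- mean(ad$adjusted$value, na.rm = TRUE)
    c(sigma2_g = vc$sigma2_g, h2 = heritability(vc$sigma2_g, vc$sigma2_p), xo = xo,
      cv_g = coefficients_of_variation(vc$sigma2_g, vc$sigma2_e, xo)$cv_g)
  })
  est <- do.call(rbind, est)

  m <- sapply(adjusted, function(ad) {
    v <- ad$adjusted$value
    names(v) <- ad$adjusted$genotype_id
    v
  })
  specs <- trait_registry(x)
  ranks <- rank_traits(m, specs, tie_policy = tie_policy)
  w <- if (identical(weights, "cvg")) est[, "cv_g"] else
    if (identical(weights, "unit")) NULL else weights
  idx <- mulamba_mock(ranks, w)
  if (intensity >= 1) {
    sel <- NULL
    ids <- rownames(m)  # no truncation: the "selected" set is everyone
  } else {
    sel <- select_genotypes(idx, intensity)
    ids <- selected_ids(sel)
  }
  xs <- colMeans(m[ids, , drop = FALSE])
  gain <- selection_gain(xs, est[, "xo"], est[, "h2"])

  g_true <- sim$truth$genetic[rownames(m), colnames(m), drop = FALSE]
  realized <- colMeans(g_true[ids, , drop = FALSE]) - colMeans(g_true)

  list(h2 = est[, "h2"], sigma2_g = est[, "sigma2_g"],
       expected_gg = gain$gg, realized_gg = realized, gs_pct = gain$gs_pct,
       selection = sel)
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates\n", attr(x, "n_reps")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}
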