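#' Check-plot matrix for one trait
#'
#' Internal helper: the complete checks x blocks matrix of observations for a
#' trait.  The augmented design estimates error and block effects from this
#' layout only, so any missing check plot aborts the trait's analysis rather
#' than being imputed.
#'
#' @noRd
check_matrix <- function(x, trait) {
  stopifnot(inherits(x, "trial_table"))
  if (!trait %in% trial_traits(x)) stop("unregistered or absent trait: ", trait)
  chk <- x[x$role == "check", c("genotype_id", "block", trait)]
  blocks <- sort(unique(x$block))
  checks <- sort(unique(chk$genotype_id))
  m <- matrix(NA_real_, length(checks), length(blocks),
              dimnames = list(checks, blocks))
  m[cbind(match(chk$genotype_id, checks), match(chk$block, blocks))] <- chk[[trait]]
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing check plot for trait '%s': check '%s' in block '%s'",
                 trait, checks[bad[1]], blocks[bad[2]]))
  }
  m
}

#' Two-way ANOVA on the replicated checks
#'
#' The checks form a complete randomized-block layout inside the augmented
#' trial; their two-way ANOVA (checks + blocks) provides the residual mean
#' square used as the error estimate for the whole trial, with
#' (b - 1)(c - 1) degrees of freedom.
#'
#' @param x a `trial_table`.
#' @param trait trait name.
#' @return list with `sigma2_e` (residual mean square), `df_error`,
#'   `ss_block`, `ss_check`, `ss_error`, `n_blocks`, `n_checks`,
#'   `grand_mean` (mean over check plots).
#' @export
check_anova <- function(x, trait) {
  m <- check_matrix(x, trait)
  b <- ncol(m)
  cc <- nrow(m)
  gm <- mean(m)
  ss_block <- cc * sum((colMeans(m) - gm)^2)
  ss_check <- b * sum((rowMeans(m) - gm)^2)
  ss_total <- sum((m - gm)^2)
  ss_error <- max(ss_total - ss_block - ss_check, 0)
  df_error <- (b - 1L) * (cc - 1L)
  list(sigma2_e = ss_error / df_error, df_error = df_error,
       ss_block = ss_block, ss_check = ss_check, ss_error = ss_error,
       n_blocks = b, n_checks = cc, grand_mean = gm)
}

#' Block effects estimated from the checks
#'
#' The classical Federer estimator: the effect of block j is the mean of the
#' checks in block j minus the grand mean of all check plots.  Effects sum to
#' zero and are unaffected by adding a constant to every plot.
#'
#' @inheritParams check_anova
#' @return named numeric vector of block effects (trait units).
#' @export
block_effects <- function(x, trait) {
  m <- check_matrix(x, trait)
  colMeans(m) - mean(m)
}

#' Adjust test-genotype values for block effects
#'
#' For a test genotype grown in block j, the adjusted value is the observed
#' plot value minus the estimated effect of block j.  Checks are summarized
#' by their raw replicated means.  Also reports the check-derived error mean
#' square, the grand mean over all plots, and the Federer replication-
#' weighted mean (see [federer_weighted_mean()]).
#'
#' @inheritParams check_anova
#' @return object of class `adjusted_values`: list with `trait`,
#'   `block_effects`, `adjusted` (data.frame `genotype_id`, `population_id`,
#'   `block`, `observed`, `value`), `check_means`, `sigma2_e`, `df_error`,
#'   `mu` (grand mean of all non-missing plots), `mu_f`, `n_missing`.
#' @export
adjust_trial <- function(x, trait) {
  be <- block_effects(x, trait)
  ca <- check_anova(x, trait)
  tst <- x[x$role == "test", c("genotype_id", "population_id", "block", trait)]
  missing <- is.na(tst[[trait]])
  if (any(missing)) {
    message(sprintf("trait '%s': %d test plot(s) missing, excluded from this trait",
                    trait, sum(missing)))
  }
  adj <- data.frame(
    genotype_id = tst$genotype_id, population_id = tst$population_id,
    block = tst$block, observed = tst[[trait]],
    value = tst[[trait]] - be[tst$block],
    stringsAsFactors = FALSE
  )
  chk <- x[x$role == "check", c("genotype_id", trait)]
  check_means <- tapply(chk[[trait]], chk$genotype_id, mean)
  mu <- mean(x[[trait]], na.rm = TRUE)
  out <- list(
    trait = trait, block_effects = be, adjusted = adj,
    check_means = check_means, sigma2_e = ca$sigma2_e, df_error = ca$df_error,
    mu = mu, n_missing = sum(missing)
  )
  out$mu_f <- federer_weighted_mean_impl(check_means, adj$value[!missing],
                                         n_blocks = ca$n_blocks)
  class(out) <- "adjusted_values"
  out
}

#' @export
print.adjusted_values <- function(x, ...) {
  cat(sprintf("Adjusted values for trait '%s'\n", x$trait))
  cat(sprintf("  blocks: %d  checks: %d  tests: %d (missing: %d)\n",
              length(x$block_effects), length(x$check_means),
              nrow(x$adjusted), x$n_missing))
  cat(sprintf("  sigma2_e = %.4g on %d df;  mu = %.4g;  muF = %.4g\n",
              x$sigma2_e, x$df_error, x$mu, x$mu_f))
  invisible(x)
}

federer_weighted_mean_impl <- function(check_means, adjusted_tests, n_blocks) {
  w_checks <- rep(n_blocks, length(check_means))
  vals <- c(check_means, adjusted_tests)
  wts <- c(w_checks, rep(1, length(adjusted_tests)))
  sum(vals * wts) / sum(wts)
}

#' Federer replication-weighted grand mean
#'
#' Weighted average of entry means (raw means for checks, block-adjusted
#' values for tests) with weights proportional to each entry's replication:
#' b plots per check, one per test genotype.  Reduces to the plain grand mean
#' when every entry is equally replicated.  Reported alongside the grand mean
#' for the parameter panel; never used downstream.
#'
#' @inheritParams check_anova
#' @return scalar weighted mean (trait units).
#' @export
federer_weighted_mean <- function(x, trait) {
  adjust_trial(x, trait)$mu_f
}

#' Coefficient of variation from an error mean square
#'
#' 100 * sqrt(ms_error) / mean.  The parameter panel reports it against three
#' reference means: the check mean, the adjusted test mean, and the combined
#' mean.
#'
#' @param ms_error error mean square (squared trait units).
#' @param mean reference mean (> 0).
#' @return CV in percent.
#' @export
cv_percent <- function(ms_error, mean) {
  if (any(mean <= 0)) stop("cv_percent requires a positive mean")
  100 * sqrt(ms_error) / mean
}

#' ANOVA table for the augmented block design
#'
#' Decomposes variation into blocks, checks, test genotypes (block-adjusted),
#' and the checks-vs-genotypes contrast, with all F-ratios tested against the
#' check-derived error mean square.  Check and block sums of squares come
#' from the complete check layout; the adjusted-genotype sum of squares is
#' computed from the block-adjusted test values (each test genotype carries
#' one plot).  Degrees of freedom are additive: (b-1) + (c-1) + (n_g-1) + 1 +
#' (b-1)(c-1) = N - 1.
#'
#' @inheritParams check_anova
#' @param alpha significance level for flagging sources (default 0.01).
#' @return object of class `augmented_anova`: data.frame with columns
#'   `source`, `df`, `ss`, `ms`, `f`, `p`, `significant`, plus attributes
#'   `trait` and `alpha`.
#' @export
anova_augmented <- function(x, trait, alpha = 0.01) {
  ca <- check_anova(x, trait)
  ad <- adjust_trial(x, trait)
  g <- ad$adjusted$value[!is.na(ad$adjusted$value)]
  n_g <- length(g)
  if (n_g < 2) stop("need at least 2 non-missing test genotypes for trait: ", trait)
  b <- ca$n_blocks
  cc <- ca$n_checks

  ss_gen <- sum((g - mean(g))^2)
  df_gen <- n_g - 1L
  # checks-vs-genotypes: contrast between the check grand mean (b*c plots)
  # and the adjusted test mean (n_g effective plots)
  delta <- ca$grand_mean - mean(g)
  ss_cvg <- delta^2 / (1 / (b * cc) + 1 / n_g)

  src <- data.frame(
    source = c("blocks", "treatments (adj.)", "  checks", "  genotypes (adj.)",
               "  checks vs genotypes", "error"),
    df = c(b - 1L, (cc - 1L) + df_gen + 1L, cc - 1L, df_gen, 1L, ca$df_error),
    ss = c(ca$ss_block, ca$ss_check + ss_gen + ss_cvg, ca$ss_check, ss_gen,
           ss_cvg, ca$ss_error),
    stringsAsFactors = FALSE
  )
  src$ms <- src$ss / src$df
  if (ca$df_error == 0 || ca$sigma2_e == 0) {
    src$f <- NA_real_
    src$p <- NA_real_
    if (ca$df_error == 0) warning("error df = 0: no F-tests available")
  } else {
    src$f <- src$ms / ca$sigma2_e
    src$p <- stats::pf(src$f, src$df, ca$df_error, lower.tail = FALSE)
    src$f[src$source == "error"] <- NA_real_
    src$p[src$source == "error"] <- NA_real_
  }
  src$significant <- !is.na(src$p) & src$p <= alpha
  attr(src, "trait") <- trait
  attr(src, "alpha") <- alpha
  class(src) <- c("augmented_anova", "data.frame")
  src
}

#' @export
print.augmented_anova <- function(x, ...) {
  cat(sprintf("Augmented-design ANOVA for trait '%s' (alpha = %g)\n",
              attr(x, "trait"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6)
  df$ms <- signif(df$ms, 6)
  df$f <- signif(df$f, 4)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Is the genotype effect significant for a trait?
#'
#' Convenience wrapper reading the adjusted-genotypes F-test from
#' [anova_augmented()]; the pipeline drops traits whose genotypes do not
#' differ at `alpha` before index construction.
#'
#' @inheritParams anova_augmented
#' @return logical scalar (`NA` if no test is available).
#' @export
genotype_significant <- function(x, trait, alpha = 0.01) {
  tab <- anova_augmented(x, trait, alpha = alpha)
  p <- tab$p[tab$source == "  genotypes (adj.)"]
  if (is.na(p)) NA else p <= alpha
}
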