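#' Variance components from adjusted test values
#'
#' The phenotypic variance is the sample variance (n - 1 denominator) of the
#' block-adjusted test-genotype values; the genotypic variance is the
#' phenotypic variance minus the check-derived environmental variance,
#' truncated at zero (with a warning) since variances are non-negative
#' parameters.
#'
#' @param adjusted an `adjusted_values` object from [adjust_trial()].
#' @return list with `sigma2_p`, `sigma2_g`, `sigma2_e`, `truncated`.
#' @export
variance_components <- function(adjusted) {
  stopifnot(inherits(adjusted, "adjusted_values"))
  v <- adjusted$adjusted$value
  v <- v[!is.na(v)]
  if (length(v) < 2) stop("need at least 2 adjusted test values")
  sigma2_p <- stats::var(v)
  sigma2_g <- sigma2_p - adjusted$sigma2_e
  truncated <- sigma2_g < 0
  if (truncated) {
    warning(sprintf("trait '%s': sigma2_p < sigma2_e; genotypic variance truncated to 0",
                    adjusted$trait))
    sigma2_g <- 0
  }
  list(sigma2_p = sigma2_p, sigma2_g = sigma2_g,
       sigma2_e = adjusted$sigma2_e, truncated = truncated)
}

#' Broad-sense heritability
#'
#' The proportion of phenotypic variance attributable to genotypic variance,
#' h2 = Vg / Vf.  Stored as a proportion; reports render it in percent.
#'
#' @param vg genotypic variance (0 <= vg <= vf).
#' @param vf phenotypic variance (> 0).
#' @return heritability as a proportion in \[0, 1\].
#' @export
#' @examples
#' heritability(113.91, 114.72)  # 0.9929
heritability <- function(vg, vf) {
  if (any(vf <= 0)) stop("phenotypic variance must be positive")
  if (any(vg < 0) || any(vg > vf)) stop("need 0 <= vg <= vf")
  vg / vf
}

#' Genotypic and environmental coefficients of variation
#'
#' CVg = 100 * sqrt(sigma2_g) / mean, CVe = 100 * sqrt(sigma2_e) / mean, and
#' their ratio sqrt(sigma2_g / sigma2_e).  A ratio above 1 signals genetic
#' variation exceeding environmental noise, a classical indicator of
#' selection feasibility.
#'
#' @param sigma2_g genotypic variance (>= 0).
#' @param sigma2_e environmental variance (>= 0).
#' @param mean reference mean (> 0).
#' @return list with `cv_g`, `cv_e` (percent) and `ratio` (`NA` with a
#'   warning when `sigma2_e` is zero).
#' @export
coefficients_of_variation <- function(sigma2_g, sigma2_e, mean) {
  if (mean <= 0) stop("coefficients of variation require a positive mean")
  if (sigma2_g < 0 || sigma2_e < 0) stop("variances must be non-negative")
  cv_g <- 100 * sqrt(sigma2_g) / mean
  cv_e <- 100 * sqrt(sigma2_e) / mean
  if (sigma2_e == 0) {
    warning("sigma2_e = 0: CVg/CVe ratio undefined")
    ratio <- NA_real_
  } else {
    ratio <- sqrt(sigma2_g / sigma2_e)
  }
  list(cv_g = cv_g, cv_e = cv_e, ratio = ratio)
}

#' Expected gain from selection
#'
#' The breeder's-equation gain for truncation selection: GG = (Xs - Xo) * h2
#' in trait units, and GS% = 100 * GG / Xo as a percentage of the reference
#' mean, where Xs is the mean of the selected set and Xo the reference
#' (candidate-population) mean.
#'
#' @param xs mean of the selected genotypes.
#' @param xo reference mean (> 0).
#' @param h2 broad-sense heritability as a proportion.
#' @return list with `gg` (trait units) and `gs_pct` (percent).
#' @export
#' @examples
#' selection_gain(1219.45, 976.67, 0.5532)  # GS% = 13.75
selection_gain <- function(xs, xo, h2) {
  if (any(xo <= 0)) stop("reference mean Xo must be positive")
  if (any(h2 < 0 | h2 > 1)) stop("heritability must lie in [0, 1]")
  gg <- (xs - xo) * h2
  list(gg = gg, gs_pct = 100 * gg / xo)
}

#' Per-trait genetic-parameter panel
#'
#' Assembles, for each analyzed trait, the full parameter panel: grand and
#' Federer-weighted means, variance components, broad-sense heritability,
#' genotypic/environmental coefficients of variation and their ratio, the
#' reference mean Xo, the selected-set mean Xs, and the expected gains GG and
#' GS%.
#'
#' Xo defaults to the mean of the adjusted test-genotype values (the
#' candidate population the gain formula operates on); `xo_reference =
#' "checks"` switches it to the check mean.
#'
#' @param x a `trial_table`.
#' @param selection character vector of selected genotype ids (possibly
#'   empty: gains are then `NA`).
#' @param traits traits to include (default: all registered traits present).
#' @param xo_reference `"tests"` or `"checks"`.
#' @return object of class `genetic_params`: data.frame with one row per
#'   trait and columns `trait`, `mu`, `mu_f`, `cv_checks`, `cv_tests`,
#'   `cv_all`, `sigma2_p`, `sigma2_e`, `sigma2_g`, `h2`, `cv_g`, `cv_e`,
#'   `cvg_cve`, `xo`, `xs`, `gg`, `gs_pct`, `truncated`.
#' @export
parameter_panel <- function(x, selection = character(),
                            traits = trial_traits(x),
                            xo_reference = c("tests", "checks")) {
  xo_reference <- match.arg(xo_reference)
  rows <- lapply(traits, function(tr) {
    ad <- adjust_trial(x, tr)
    vc <- variance_components(ad)
    h2 <- heritability(vc$sigma2_g, vc$sigma2_p)
    ok <- !is.na(ad$adjusted$value)
    test_mean <- mean(ad$adjusted$value[ok])
    check_mean <- mean(ad$check_means)
    xo <- if (xo_reference == "tests") test_mean else check_mean
    cvs <- coefficients_of_variation(vc$sigma2_g, vc$sigma2_e, xo)
    if (length(selection)) {
      sel <- ad$adjusted$value[ad$adjusted$genotype_id %in% selection]
      xs <- mean(sel, na.rm = TRUE)
      gain <- selection_gain(xs, xo, h2)
    } else {
      xs <- NA_real_
      gain <- list(gg = NA_real_, gs_pct = NA_real_)
    }
    data.frame(
      trait = tr, mu = ad$mu, mu_f = ad$mu_f,
      cv_checks = cv_percent(ad$sigma2_e, check_mean),
      cv_tests = cv_percent(ad$sigma2_e, test_mean),
      cv_all = cv_percent(ad$sigma2_e, ad$mu),
      sigma2_p = vc$sigma2_p, sigma2_e = vc$sigma2_e, sigma2_g = vc$sigma2_g,
      h2 = h2, cv_g = cvs$cv_g, cv_e = cvs$cv_e, cvg_cve = cvs$ratio,
      xo = xo, xs = xs, gg = gain$gg, gs_pct = gain$gs_pct,
      truncated = vc$truncated, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genetic_params", "data.frame")
  out
}

panel_row_labels <- c(
  mu = "mu", mu_f = "muF", cv_checks = "CV_checks (%)",
  cv_tests = "CV_genotypes (%)", cv_all = "CV_all (%)",
  sigma2_p = "sigma2_p", sigma2_e = "sigma2_e", sigma2_g = "sigma2_g",
  h2 = "h2 (%)", cv_g = "CVg (%)", cv_e = "CVe (%)", cvg_cve = "CVg/CVe",
  xo = "Xo", xs = "Xs", gg = "GG", gs_pct = "GS%"
)

#' Render the parameter panel in report layout
#'
#' Transposes the panel into the conventional report table: one row per
#' parameter (mu, muF, the three CV rows, variance components, h2 in
#' percent, CVg/CVe, Xo, Xs, GG, GS%), one column per trait.
#'
#' @param panel a `genetic_params` data.frame.
#' @return data.frame with a `parameter` column and one column per trait.
#' @export
panel_report <- function(panel) {
  stopifnot(inherits(panel, "genetic_params"))
  num <- as.matrix(panel[, names(panel_row_labels)])
  num[, "h2"] <- 100 * num[, "h2"]  # rendered in percent
  out <- as.data.frame(t(num))
  names(out) <- panel$trait
  cbind(parameter = unname(panel_row_labels), out, stringsAsFactors = FALSE)
}

#' @export
print.genetic_params <- function(x, ...) {
  cat("Genetic-parameter panel (", nrow(x), " traits)\n", sep = "")
  rep <- panel_report(x)
  rep[-1] <- lapply(rep[-1], signif, digits = 5)
  print(rep, row.names = FALSE)
  invisible(x)
}
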