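#' Rank genotypes per trait in the direction of improvement
#'
#' For a trait with direction +1 the largest value receives rank 1; direction
#' -1 reverses the order.  Ties are resolved by the chosen policy (average by
#' default); missing values always rank worst and are logged.  Ranks are
#' invariant to any strictly increasing transform of a trait's values.
#'
#' @param values genotypes x traits numeric matrix (rownames = genotype ids).
#' @param specs a [trait_spec()] registry covering every column; columns with
#'   `NA` direction are an error (the breeder must decide).
#' @param tie_policy one of `"average"`, `"min"`, `"first"`.
#' @return object of class `rank_matrix`: numeric matrix of ranks with the
#'   tie policy attached as attribute `"tie_policy"`.
#' @export
rank_traits <- function(values, specs, tie_policy = c("average", "min", "first")) {
  tie_policy <- match.arg(tie_policy)
  values <- as.matrix(values)
  unregistered <- setdiff(colnames(values), specs$name)
  if (length(unregistered)) {
    stop("unregistered traits: ", paste(unregistered, collapse = ", "))
  }
  dir <- specs$direction[match(colnames(values), specs$name)]
  if (anyNA(dir)) {
    stop("direction not set for traits: ",
         paste(colnames(values)[is.na(dir)], collapse = ", "),
         " (set +1/-1 in the trait specification)")
  }
  ranks <- values
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    if (all(is.na(v))) stop("trait has no observed values: ", colnames(values)[j])
    if (anyNA(v)) {
      message(sprintf("trait '%s': %d missing value(s) ranked worst",
                      colnames(values)[j], sum(is.na(v))))
    }
    # na.last = "keep" then assign the worst rank, so ties among observed
    # values follow the policy and missingness is always penalized
    r <- rank(-dir[j] * v, ties.method = tie_policy, na.last = "keep")
    r[is.na(r)] <- nrow(values)
    ranks[, j] <- r
  }
  attr(ranks, "tie_policy") <- tie_policy
  class(ranks) <- c("rank_matrix", class(ranks))
  ranks
}

#' Mulamba-Mock sum-of-ranks selection index
#'
#' The non-parametric index I_i = sum_j p_j r_ij over traits, where r_ij is
#' genotype i's rank on trait j and p_j the breeder's economic weight
#' (unit weights when none are given).  Lower index values are better.
#'
#' @param ranks a `rank_matrix` from [rank_traits()].
#' @param weights optional positive per-trait weights, recycled or named by
#'   trait.
#' @return named numeric vector of index values.
#' @export
mulamba_mock <- function(ranks, weights = NULL) {
  r <- unclass(ranks)
  if (is.null(weights)) {
    weights <- rep(1, ncol(r))
  } else {
    if (!is.null(names(weights))) {
      miss <- setdiff(colnames(r), names(weights))
      if (length(miss)) stop("no weight for traits: ", paste(miss, collapse = ", "))
      weights <- weights[colnames(r)]
    }
    weights <- rep_len(weights, ncol(r))
    if (any(weights < 0)) stop("economic weights must be non-negative")
  }
  drop(r %*% weights)
}

#' Economic weights from genotypic coefficients of variation
#'
#' Takes p_j = CVg_j (in percent) from a genetic-parameter panel, so traits
#' with more exploitable genetic variation weigh more in the rank-sum index.
#' A zero-CVg trait gets weight 0 (with a warning): it cannot respond to
#' selection and is effectively dropped.
#'
#' @param panel a `genetic_params` data.frame from [parameter_panel()].
#' @param traits traits to extract (default: all in the panel).
#' @return named numeric vector of weights.
#' @export
weights_from_cvg <- function(panel, traits = panel$trait) {
  stopifnot(inherits(panel, "genetic_params"))
  miss <- setdiff(traits, panel$trait)
  if (length(miss)) stop("CVg not available for traits: ", paste(miss, collapse = ", "))
  w <- panel$cv_g[match(traits, panel$trait)]
  names(w) <- traits
  if (any(w == 0)) {
    warning("zero CVg for traits: ", paste(traits[w == 0], collapse = ", "),
            " (weight 0: effectively dropped from the index)")
  }
  w
}

round_half_up <- function(x) floor(x + 0.5)

#' Truncate the index at a selection intensity
#'
#' Selects the round(n * intensity) genotypes with the smallest index values
#' (half-up rounding).  Ties at the cutoff are broken deterministically by
#' genotype id order and logged.
#'
#' @param index named numeric vector of Mulamba-Mock index values.
#' @param intensity selected fraction, in (0, 1).
#' @return object of class `selection_result`: data.frame with columns
#'   `genotype_id`, `index`, `rank`, `selected`, ordered by rank, with the
#'   intensity attached as attribute.
#' @export
select_genotypes <- function(index, intensity) {
  if (intensity <= 0 || intensity >= 1) stop("intensity must lie in (0, 1)")
  n <- length(index)
  n_sel <- round_half_up(n * intensity)
  if (n_sel < 1) stop(sprintf("intensity %g of %d genotypes selects none", intensity, n))
  ids <- names(index)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(index, ids)
  cutoff <- index[ord][n_sel]
  # the boundary splits a tie group only if the group straddles n_sel
  if (sum(index < cutoff) < n_sel && sum(index <= cutoff) > n_sel) {
    message(sprintf("%d genotypes tied at the cutoff index %g; broken by genotype id order",
                    sum(index == cutoff), cutoff))
  }
  out <- data.frame(
    genotype_id = ids[ord], index = unname(index[ord]),
    rank = seq_len(n), selected = seq_len(n) <= n_sel,
    stringsAsFactors = FALSE
  )
  attr(out, "intensity") <- intensity
  attr(out, "n_selected") <- n_sel
  class(out) <- c("selection_result", "data.frame")
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Rank-sum selection: %d of %d genotypes at intensity %g\n",
              attr(x, "n_selected"), nrow(x), attr(x, "intensity")))
  print(utils::head(as.data.frame(x), attr(x, "n_selected")), row.names = FALSE)
  invisible(x)
}

#' Selected genotype ids
#' @param x a `selection_result`.
#' @return character vector of selected genotype ids, best first.
#' @export
selected_ids <- function(x) {
  stopifnot(inherits(x, "selection_result"))
  x$genotype_id[x$selected]
}

#' Adjusted values as a genotype x trait matrix
#'
#' Convenience bridge from the design stage to ranking and multivariate
#' stages: block-adjusted values for test genotypes (and raw means for
#' checks, when requested) assembled into a matrix.
#'
#' @param x a `trial_table`.
#' @param traits traits to include.
#' @param include_checks also include check genotypes (raw replicated means)?
#' @return numeric matrix, rownames = genotype ids.
#' @export
adjusted_matrix <- function(x, traits = trial_traits(x), include_checks = FALSE) {
  cols <- lapply(traits, function(tr) {
    ad <- adjust_trial(x, tr)
    v <- ad$adjusted$value
    names(v) <- ad$adjusted$genotype_id
    if (include_checks) v <- c(v, ad$check_means)
    v
  })
  ids <- unique(unlist(lapply(cols, names)))
  m <- matrix(NA_real_, length(ids), length(traits), dimnames = list(ids, traits))
  for (j in seq_along(cols)) m[names(cols[[j]]), j] <- cols[[j]]
  m
}
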