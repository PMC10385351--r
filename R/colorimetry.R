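#' CIELab hue angle
#'
#' Hue angle of the (a, b) chromaticity pair, in degrees on \[0, 360).  Uses
#' the two-argument arctangent so every quadrant maps correctly; in the first
#' quadrant (a > 0, b > 0, the usual regime for ripe strawberry skin) this
#' equals atan(b/a) in degrees.  Lower hue means redder fruit.
#'
#' @param a red/green coordinate (positive toward red).
#' @param b yellow/blue coordinate (positive toward yellow).
#' @return hue angle(s) in degrees, in \[0, 360).
#' @export
#' @examples
#' hue_angle(3, 4)  # 53.1301
hue_angle <- function(a, b) {
  if (any(a == 0 & b == 0)) {
    stop("hue angle undefined at the origin (a = 0, b = 0)")
  }
  (atan2(b, a) * 180 / pi) %% 360
}

#' CIELab chroma
#'
#' Color saturation/intensity: the Euclidean norm sqrt(a^2 + b^2) of the
#' chromaticity pair.  Non-negative and invariant to sign flips of either
#' coordinate.
#'
#' @inheritParams hue_angle
#' @return chroma value(s), >= 0.
#' @export
#' @examples
#' chroma(3, 4)  # 5
chroma <- function(a, b) {
  sqrt(a^2 + b^2)
}

firmness_columns <- function(fruits) {
  grep("^firmness", names(fruits), value = TRUE)
}

#' Aggregate fruit-level records into plot-level traits
#'
#' Derives the plot (genotype x block) production and post-harvest traits
#' from individual fruit measurements: TFM (total mass), TFN (count), AFM
#' (mean mass), the marketable counterparts CFM/CFN/ACFM restricted to fruits
#' with diameter strictly above `marketable_min_diameter`, F (mean of all
#' firmness readings supplied), and the color traits L, Hue and C, where hue
#' and chroma are computed per fruit from that fruit's mean (a, b) and then
#' averaged over fruits.
#'
#' A plot with no marketable fruit gets CFM = CFN = 0 and ACFM missing.
#'
#' @param fruits data.frame with columns `genotype_id`, `block`, `mass` (g),
#'   `diameter` (mm), one or more `firmness*` columns (N), and optionally
#'   `L`, `a`, `b` (CIELab, per-fruit means).
#' @param marketable_min_diameter marketable-size threshold in mm (default
#'   35; fruits must exceed it strictly).
#' @return data.frame with one row per genotype x block and the derived trait
#'   columns.
#' @export
aggregate_plots <- function(fruits, marketable_min_diameter = 35) {
  fruits <- as.data.frame(fruits)
  needed <- c("genotype_id", "block", "mass", "diameter")
  missing_cols <- setdiff(needed, names(fruits))
  if (length(missing_cols)) {
    stop("fruit records lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!nrow(fruits)) stop("no fruit records supplied")
  if (any(fruits$mass <= 0, na.rm = TRUE)) stop("fruit mass must be positive")
  if (any(fruits$diameter <= 0, na.rm = TRUE)) stop("fruit diameter must be positive")
  fcols <- firmness_columns(fruits)
  has_color <- all(c("L", "a", "b") %in% names(fruits))
  if (has_color && any(fruits$L < 0 | fruits$L > 100, na.rm = TRUE)) {
    stop("CIELab L must lie in [0, 100]")
  }
  key <- interaction(fruits$genotype_id, fruits$block, drop = TRUE, sep = "\r")
  pieces <- lapply(split(fruits, key), function(p) {
    mkt <- p$diameter > marketable_min_diameter
    out <- data.frame(
      genotype_id = p$genotype_id[1], block = p$block[1],
      TFM = sum(p$mass), TFN = nrow(p), AFM = mean(p$mass),
      CFM = sum(p$mass[mkt]), CFN = sum(mkt),
      ACFM = if (any(mkt)) mean(p$mass[mkt]) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (length(fcols)) {
      out$F <- mean(unlist(p[fcols]), na.rm = TRUE)
    }
    if (has_color) {
      out$L <- mean(p$L)
      out$Hue <- mean(hue_angle(p$a, p$b))
      out$C <- mean(chroma(p$a, p$b))
    }
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$genotype_id, out$block), , drop = FALSE]
}
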