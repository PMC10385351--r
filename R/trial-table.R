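#' Trait specifications
#'
#' A trait specification registers, for each analyzed trait, the direction of
#' improvement (+1 when larger values are better, -1 when smaller values are
#' better) and a unit label.  Direction drives per-trait ranking in the
#' selection index; units are carried as labels only.
#'
#' @param name character vector of unique trait names.
#' @param direction integer vector of +1/-1 (recycled); `NA` marks a trait
#'   whose direction the breeder must set explicitly before ranking.
#' @param units character vector of unit labels (recycled).
#'
#' @return A data.frame of class `trait_spec` with columns `name`,
#'   `direction`, `units`.
#' @export
#' @examples
#' trait_spec(c("TFM", "Hue"), direction = c(1, NA), units = c("g", "degrees"))
trait_spec <- function(name, direction = 1L, units = "") {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("trait names must be unique: ", paste(name[duplicated(name)], collapse = ", "))
  }
  direction <- rep_len(as.integer(direction), length(name))
  if (!all(is.na(direction) | direction %in% c(-1L, 1L))) {
    stop("trait direction must be +1, -1 or NA")
  }
  out <- data.frame(name = name, direction = direction,
                    units = rep_len(as.character(units), length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_spec", "data.frame")
  out
}

#' Default trait registry for strawberry production and post-harvest traits
#'
#' Total fruit mass (TFM, g/plant), total fruit number (TFN), average fruit
#' mass (AFM, g/fruit), their marketable counterparts (CFM, CFN, ACFM), total
#' soluble solids (TSS, degrees Brix), firmness (F, N), CIELab lightness (L),
#' hue angle (Hue, degrees) and chroma (C).  L and Hue ship with `NA`
#' direction: whether lighter/redder fruit is "better" is a breeding decision
#' that must be made explicitly.
#'
#' @return A `trait_spec` data.frame with eleven rows.
#' @export
default_trait_spec <- function() {
  trait_spec(
    name = c("TFM", "TFN", "AFM", "CFM", "CFN", "ACFM", "TSS", "F", "L", "Hue", "C"),
    direction = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, NA, NA, 1L),
    units = c("g/plant", "count", "g/fruit", "g/plant", "count", "g/fruit",
              "degrees Brix", "N", "", "degrees", "")
  )
}

id_cols <- c("genotype_id", "population_id", "role", "block")

#' Construct a validated augmented-trial table
#'
#' A trial table holds one row per genotype x block plot with a `role` column
#' separating replicated checks (present in every block) from unreplicated
#' test genotypes (present in exactly one block), plus one numeric column per
#' registered trait.
#'
#' @param data data.frame with columns `genotype_id`, `population_id`, `role`
#'   (values `"check"`/`"test"` after alias mapping), `block`, and one column
#'   per trait.
#' @param traits a [trait_spec()] registry covering every trait column in
#'   `data`.
#' @param role_aliases named character vector mapping dialect role labels to
#'   `"check"`/`"test"` (e.g. `c(control = "check")`).
#'
#' @return `data` with class `trial_table` and the registry attached as
#'   attribute `"traits"`.
#' @export
trial_table <- function(data, traits = default_trait_spec(), role_aliases = NULL) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(id_cols, names(data))
  if (length(missing_cols)) {
    stop("trial table lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(role_aliases)) {
    hit <- data$role %in% names(role_aliases)
    data$role[hit] <- unname(role_aliases[data$role[hit]])
  }
  bad_roles <- setdiff(unique(data$role), c("check", "test"))
  if (length(bad_roles)) {
    stop("unknown role labels: ", paste(bad_roles, collapse = ", "),
         " (map them via role_aliases)")
  }
  trait_cols <- setdiff(names(data), id_cols)
  unregistered <- setdiff(trait_cols, traits$name)
  if (length(unregistered)) {
    stop("unregistered trait columns: ", paste(unregistered, collapse = ", "))
  }
  for (tr in trait_cols) {
    v <- data[[tr]]
    if (!is.numeric(v)) stop("trait column not numeric: ", tr)
    if (any(!is.na(v) & !is.finite(v))) stop("non-finite values in trait: ", tr)
  }
  data$genotype_id <- as.character(data$genotype_id)
  data$block <- as.character(data$block)
  attr(data, "traits") <- traits
  class(data) <- c("trial_table", "data.frame")
  validate_trial(data)
  data
}

#' Validate the check/test layout of a trial table
#'
#' Asserts the augmented-design invariants: every check appears exactly once
#' in every block, and every test genotype appears in exactly one block.
#' Errors name the offending genotype and block.
#'
#' @param x a `trial_table`.
#' @return `x`, invisibly, on success.
#' @export
validate_trial <- function(x) {
  stopifnot(inherits(x, "trial_table"))
  blocks <- sort(unique(x$block))
  checks <- unique(x$genotype_id[x$role == "check"])
  if (length(blocks) < 2) stop("augmented design needs at least 2 blocks")
  if (length(checks) < 2) stop("augmented design needs at least 2 checks")
  chk <- x[x$role == "check", ]
  tab <- table(factor(chk$genotype_id, levels = checks),
               factor(chk$block, levels = blocks))
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop(sprintf("check '%s' appears %d times in block '%s' (expected exactly once)",
                 checks[bad[1]], tab[bad[1], bad[2]], blocks[bad[2]]))
  }
  tst <- x[x$role == "test", ]
  if (nrow(tst)) {
    n_per <- table(tst$genotype_id)
    if (any(n_per != 1L)) {
      bad <- names(n_per)[n_per != 1L][1]
      stop(sprintf("test genotype '%s' appears in %d plots (expected exactly one block)",
                   bad, n_per[[bad]]))
    }
  }
  both <- intersect(checks, unique(tst$genotype_id))
  if (length(both)) stop("genotype listed as both check and test: ", both[1])
  invisible(x)
}

#' Trait registry of a trial table
#' @param x a `trial_table`.
#' @return the attached `trait_spec` registry.
#' @export
trait_registry <- function(x) attr(x, "traits")

#' Trait columns present in a trial table
#' @param x a `trial_table`.
#' @return character vector of trait column names, in registry order.
#' @export
trial_traits <- function(x) {
  intersect(trait_registry(x)$name, setdiff(names(x), id_cols))
}

#' @export
print.trial_table <- function(x, ...) {
  blocks <- unique(x$block)
  checks <- unique(x$genotype_id[x$role == "check"])
  tests <- unique(x$genotype_id[x$role == "test"])
  cat(sprintf("Augmented-block trial: %d blocks, %d checks, %d test genotypes\n",
              length(blocks), length(checks), length(tests)))
  cat("Traits:", paste(trial_traits(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more plots\n")
}

#' Read a plot-level trial table from CSV
#'
#' Expects a comma-separated, UTF-8, "." decimal file with a header row and
#' the required identifier columns; all remaining columns are taken as
#' traits.  The optional trait configuration is a YAML file with a `traits`
#' list (`name`/`direction`/`units` per entry), an optional `role_aliases`
#' map, and an optional `marketable_min_diameter`.
#'
#' @param path CSV file path.
#' @param trait_config_path optional YAML trait configuration path.
#' @return a validated [trial_table()].
#' @export
read_trial <- function(path, trait_config_path = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), fileEncoding = "UTF-8")
  traits <- default_trait_spec()
  aliases <- NULL
  if (!is.null(trait_config_path)) {
    cfg <- read_trait_config(trait_config_path)
    if (!is.null(cfg$traits)) traits <- cfg$traits
    aliases <- cfg$role_aliases
  }
  trial_table(raw, traits = traits, role_aliases = aliases)
}

#' Read a YAML trait configuration
#'
#' @param path YAML file with keys `traits` (list of `name`, `direction`,
#'   `units`), optional `role_aliases` (map), optional
#'   `marketable_min_diameter` (mm).
#' @return list with elements `traits` (a [trait_spec()]), `role_aliases`,
#'   `marketable_min_diameter`.
#' @export
read_trait_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(traits = NULL, role_aliases = NULL,
              marketable_min_diameter = cfg$marketable_min_diameter)
  if (!is.null(cfg$traits)) {
    out$traits <- trait_spec(
      name = vapply(cfg$traits, function(t) t$name, ""),
      direction = vapply(cfg$traits, function(t) {
        d <- t$direction
        if (is.null(d)) NA_integer_ else as.integer(d)
      }, 0L),
      units = vapply(cfg$traits, function(t) {
        u <- t$units
        if (is.null(u)) "" else as.character(u)
      }, "")
    )
  }
  if (!is.null(cfg$role_aliases)) {
    out$role_aliases <- unlist(cfg$role_aliases)
  }
  out
}

#' Write a YAML trait configuration
#'
#' Inverse of [read_trait_config()]; used by the pipeline to archive the
#' trait registry next to a written trial table so a run can be re-read and
#' verified without the original configuration.
#'
#' @param traits a [trait_spec()] registry.
#' @param path output YAML path.
#' @param role_aliases optional named character vector.
#' @param marketable_min_diameter optional threshold (mm).
#' @return `path`, invisibly.
#' @export
write_trait_config <- function(traits, path, role_aliases = NULL,
                               marketable_min_diameter = NULL) {
  cfg <- list(traits = lapply(seq_len(nrow(traits)), function(i) {
    list(name = traits$name[i],
         direction = if (is.na(traits$direction[i])) NULL else traits$direction[i],
         units = traits$units[i])
  }))
  if (!is.null(role_aliases)) cfg$role_aliases <- as.list(role_aliases)
  if (!is.null(marketable_min_diameter)) {
    cfg$marketable_min_diameter <- marketable_min_diameter
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a tabular artifact to CSV
#'
#' Comma-separated, "." decimal, UTF-8, missing values as empty cells; the
#' common serialization for every tabular output of the pipeline.  Round-trips
#' a trial table losslessly (up to numeric print precision).
#'
#' @param x data.frame (including `trial_table` objects).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
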