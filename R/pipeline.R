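#' Configure an end-to-end pipeline run
#'
#' @param input path to a plot-level trial CSV, or `NULL` to simulate.
#' @param trait_config optional YAML trait configuration path (directions,
#'   units, role aliases) for CSV input.
#' @param simulation a [simulation_config()] used when `input` is `NULL`
#'   (default: [table1_preset()]).
#' @param intensity selection intensity in (0, 1) (default 0.05).
#' @param alpha significance level of the genotype F-test used to screen
#'   traits (default 0.01).
#' @param weights `"cvg"`, `"unit"`, or a named numeric vector.
#' @param tie_policy rank tie policy (default `"average"`).
#' @param xo_reference reference mean for gains: `"tests"` or `"checks"`.
#' @param keep_nonsignificant keep traits whose genotype effect fails the
#'   F-test (default `FALSE`: they are dropped before ranking, with a log
#'   entry).
#' @param n_clusters dendrogram cut for reporting cluster labels (default 2).
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the simulation path.
#' @param figures write figure files? (default `TRUE`).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, trait_config = NULL,
                       simulation = table1_preset(),
                       intensity = 0.05, alpha = 0.01, weights = "cvg",
                       tie_policy = "average",
                       xo_reference = c("tests", "checks"),
                       keep_nonsignificant = FALSE, n_clusters = 2,
                       outdir = "augselect-run", seed = simulation$seed,
                       figures = TRUE) {
  if (intensity <= 0 || intensity >= 1) stop("intensity must lie in (0, 1)")
  cfg <- list(input = input, trait_config = trait_config,
              simulation = simulation, intensity = intensity, alpha = alpha,
              weights = weights, tie_policy = tie_policy,
              xo_reference = match.arg(xo_reference),
              keep_nonsignificant = keep_nonsignificant,
              n_clusters = n_clusters, outdir = outdir, seed = seed,
              figures = figures)
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full selection pipeline
#'
#' Stages, in order: (1) load or simulate the trial; (2) augmented-design
#' ANOVA per trait, screening out traits whose genotype effect is not
#' significant at `alpha`; (3) genetic-parameter panel; (4) CVg-weighted
#' Mulamba-Mock rank-sum selection at the configured intensity; (5)
#' multivariate characterization of the selected set (Z-scores, UPGMA
#' heatmap, PCA, correlation network); (6) report: CSV tables, figures, a
#' run log and a machine-readable JSON manifest from which every reported
#' number can be re-derived ([verify_run()]).
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `table`, `anova`,
#'   `panel`, `selection`, `zscores`, `heatmap`, `pca`, `network`,
#'   `clusters`, `traits_used`, `traits_excluded`, `manifest`, `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  cat("", file = log_path)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    log_line(log_path, sprintf("stage %-12s done in %.2fs", name,
                               as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  stages_done <- character()

  # -- load / simulate ------------------------------------------------------
  x <- stage("input", {
    if (!is.null(config$input)) {
      read_trial(config$input, config$trait_config)
    } else {
      sim <- simulate_trial(config$simulation, seed = config$seed)
      write_table(sim$table, file.path(config$outdir, "trial.csv"))
      write_trait_config(trait_registry(sim$table),
                         file.path(config$outdir, "traits.yaml"))
      truth <- data.frame(genotype_id = rownames(sim$truth$genetic),
                          sim$truth$genetic, check.names = FALSE)
      write_table(truth, file.path(config$outdir, "truth_genetic_effects.csv"))
      sim$table
    }
  })
  stages_done <- c(stages_done, "input")

  # -- per-trait ANOVA and trait screening ----------------------------------
  traits <- trial_traits(x)
  anovas <- stage("anova", {
    out <- lapply(traits, function(t) anova_augmented(x, t, alpha = config$alpha))
    names(out) <- traits
    long <- do.call(rbind, lapply(traits, function(t) {
      cbind(trait = t, as.data.frame(out[[t]]))
    }))
    write_table(long, file.path(config$outdir, "anova.csv"))
    out
  })
  sig <- vapply(anovas, function(a) {
    p <- a$p[a$source == "  genotypes (adj.)"]
    is.na(p) || p <= config$alpha
  }, TRUE)
  excluded <- traits[!sig]
  if (length(excluded) && !config$keep_nonsignificant) {
    log_line(log_path, "traits excluded (genotype effect not significant at alpha=",
             config$alpha, "): ", paste(excluded, collapse = ", "))
    traits_used <- traits[sig]
  } else {
    traits_used <- traits
  }
  if (length(traits_used) < 1) stop("no trait passed the genotype F-test")
  stages_done <- c(stages_done, "anova")

  # -- genetic parameters + selection (CVg weights need the panel first) ----
  panel0 <- stage("parameters", {
    parameter_panel(x, traits = traits_used, xo_reference = config$xo_reference)
  })
  if (any(panel0$truncated)) {
    log_line(log_path, "genotypic variance truncated to 0 for: ",
             paste(panel0$trait[panel0$truncated], collapse = ", "))
  }
  stages_done <- c(stages_done, "parameters")

  selres <- stage("selection", {
    m <- adjusted_matrix(x, traits = traits_used)
    ranks <- rank_traits(m, trait_registry(x), tie_policy = config$tie_policy)
    w <- if (identical(config$weights, "cvg")) weights_from_cvg(panel0)
         else if (identical(config$weights, "unit")) NULL
         else config$weights
    idx <- mulamba_mock(ranks, w)
    sel <- select_genotypes(idx, config$intensity)
    pop <- x$population_id[match(rownames(m), x$genotype_id)]
    report <- data.frame(genotype_id = rownames(m), population_id = pop,
                         as.data.frame(unclass(ranks), check.names = FALSE))
    report <- merge(report, as.data.frame(sel), by = "genotype_id")
    report <- report[order(report$rank), ]
    write_table(report, file.path(config$outdir, "selection.csv"))
    list(matrix = m, ranks = ranks, weights = w, selection = sel)
  })
  sel_ids <- selected_ids(selres$selection)
  panel <- parameter_panel(x, selection = sel_ids, traits = traits_used,
                           xo_reference = config$xo_reference)
  write_table(panel_report(panel), file.path(config$outdir, "genetic_parameters.csv"))
  stages_done <- c(stages_done, "selection")

  # -- multivariate characterization of the selected set --------------------
  mv <- stage("multivariate", {
    z <- zscore(selres$matrix[sel_ids, , drop = FALSE])
    fig <- function(name) if (config$figures) file.path(config$outdir, name) else NULL
    hm <- heatmap_layout(z, file = fig("heatmap.pdf"))
    clusters <- cut_clusters(hm$row_tree, k = config$n_clusters)
    pca <- pca_traits(z, file = fig("pca_biplot.pdf"))
    net <- correlation_network(selres$matrix[sel_ids, , drop = FALSE],
                               file = fig("correlation_network.pdf"))
    write_table(data.frame(genotype_id = rownames(z), z, check.names = FALSE),
                file.path(config$outdir, "zscores.csv"))
    write_table(data.frame(genotype_id = names(clusters), cluster = clusters),
                file.path(config$outdir, "clusters.csv"))
    write_table(data.frame(genotype_id = rownames(pca$scores), pca$scores,
                           check.names = FALSE),
                file.path(config$outdir, "pc_scores.csv"))
    contrib <- pca$contributions
    colnames(contrib) <- paste0("contribution_", colnames(pca$loadings))
    write_table(data.frame(trait = rownames(pca$loadings), pca$loadings,
                           contrib, check.names = FALSE),
                file.path(config$outdir, "pc_loadings.csv"))
    write_table(data.frame(trait = rownames(net$r), net$r, check.names = FALSE),
                file.path(config$outdir, "correlation_matrix.csv"))
    list(z = z, heatmap = hm, clusters = clusters, pca = pca, network = net)
  })
  stages_done <- c(stages_done, "multivariate")

  # -- manifest -------------------------------------------------------------
  manifest <- stage("report", {
    man <- list(
      package_version = as.character(utils::packageVersion("augselect")),
      seed = config$seed,
      parameters = list(intensity = config$intensity, alpha = config$alpha,
                        weights = if (is.character(config$weights)) config$weights
                                  else as.list(config$weights),
                        tie_policy = config$tie_policy,
                        xo_reference = config$xo_reference,
                        n_clusters = config$n_clusters),
      input = if (is.null(config$input)) "simulated" else config$input,
      stages = c(stages_done, "report"),
      traits_used = traits_used, traits_excluded = excluded,
      n_selected = length(sel_ids), selected = sel_ids,
      panel = panel[, c("trait", "sigma2_p", "sigma2_e", "sigma2_g", "h2",
                        "cv_g", "cv_e", "cvg_cve", "xo", "xs", "gg", "gs_pct")],
      pc_explained = mv$pca$explained,
      correlation_range = range(mv$network$edges$r, na.rm = TRUE),
      cluster_sizes = as.integer(table(mv$clusters))
    )
    jsonlite::write_json(man, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
    man
  })

  out <- list(table = x, anova = anovas, panel = panel,
              selection = selres$selection, ranks = selres$ranks,
              weights = selres$weights, zscores = mv$z, heatmap = mv$heatmap,
              pca = mv$pca, network = mv$network, clusters = mv$clusters,
              traits_used = traits_used, traits_excluded = excluded,
              manifest = manifest, outdir = config$outdir, config = config)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run in ", x$outdir, "\n", sep = "")
  cat(sprintf("  traits used: %s\n", paste(x$traits_used, collapse = ", ")))
  if (length(x$traits_excluded)) {
    cat(sprintf("  traits excluded: %s\n", paste(x$traits_excluded, collapse = ", ")))
  }
  cat(sprintf("  selected %d genotypes; leading components explain %.1f%%\n",
              attr(x$selection, "n_selected"),
              sum(utils::head(x$pca$explained, 2))))
  invisible(x)
}

#' Re-run a pipeline from its manifest and verify the reported numbers
#'
#' Re-executes the pipeline from the archived inputs (the written trial CSV
#' for simulated runs, or the original input path) with the manifest's seed
#' and parameters, and compares the key numbers (panel, selection, explained
#' variance) against the stored manifest.
#'
#' @param outdir directory of a previous [run_pipeline()] run.
#' @param tolerance numeric comparison tolerance (default 1e-8).
#' @return `TRUE` invisibly on success; stops with a diff message otherwise.
#' @export
verify_run <- function(outdir, tolerance = 1e-8) {
  man_path <- file.path(outdir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", outdir)
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  input <- if (identical(man$input, "simulated")) file.path(outdir, "trial.csv")
           else man$input
  trait_config <- file.path(outdir, "traits.yaml")
  if (!file.exists(trait_config)) trait_config <- NULL
  cfg <- run_config(
    input = input, trait_config = trait_config,
    intensity = man$parameters$intensity,
    alpha = man$parameters$alpha,
    weights = if (is.character(man$parameters$weights)) man$parameters$weights
              else unlist(man$parameters$weights),
    tie_policy = man$parameters$tie_policy,
    xo_reference = man$parameters$xo_reference,
    n_clusters = man$parameters$n_clusters,
    outdir = file.path(tempdir(), paste0("verify-", basename(outdir))),
    figures = FALSE, seed = man$seed
  )
  res <- run_pipeline(cfg)
  if (!identical(sort(man$selected), sort(selected_ids(res$selection)))) {
    stop("verification failed: selected sets differ")
  }
  stored <- as.data.frame(man$panel)
  fresh <- res$panel[, names(stored)]
  num <- vapply(stored, is.numeric, TRUE)
  if (any(abs(as.matrix(stored[num]) - as.matrix(fresh[num])) > tolerance,
          na.rm = TRUE)) {
    stop("verification failed: genetic-parameter panel differs")
  }
  if (any(abs(man$pc_explained - res$pca$explained) > tolerance)) {
    stop("verification failed: PCA explained variances differ")
  }
  message("verify: run in ", outdir, " reproduced within tolerance ", tolerance)
  invisible(TRUE)
}
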