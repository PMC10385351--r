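#' Z-score standardization
#'
#' Columnwise standardization Z = (x - mean) / s with the sample standard
#' deviation (n - 1 denominator), putting traits measured on different
#' scales onto a common one before clustering and ordination.
#'
#' @param m genotypes x traits numeric matrix.
#' @return matrix of Z-scores with attributes `center` and `scale` holding
#'   the per-trait mean and standard deviation used.
#' @export
zscore <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("Z-scores need at least 2 rows")
  s <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(s)) || any(s == 0)) {
    bad <- colnames(m)[!is.finite(s) | s == 0]
    stop("constant (or unobserved) trait cannot be standardized: ",
         paste(bad, collapse = ", "))
  }
  ctr <- colMeans(m, na.rm = TRUE)
  z <- sweep(sweep(m, 2, ctr), 2, s, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- s
  z
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration (unweighted pair-group method with
#' arithmetic mean) on a symmetric distance matrix: each merge happens at the
#' mean inter-cluster distance, yielding an ultrametric dendrogram.
#'
#' @param d a `dist` object or symmetric matrix with zero diagonal.
#' @return an [stats::hclust] tree (`method = "average"`).
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an `hclust` tree (e.g. from [upgma()]).
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return named integer vector of cluster labels.
#' @export
cut_clusters <- function(tree, k = 2) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop(sprintf("k must lie in [1, %d]", n))
  stats::cutree(tree, k = k)
}

#' Doubly clustered heatmap layout
#'
#' Builds the dual Euclidean/UPGMA dendrograms of a Z-score matrix (genotypes
#' on the rows, traits on the transposed matrix), reorders the matrix to
#' both leaf orders, and optionally renders the clustered heatmap to a file.
#'
#' @param z a Z-score matrix (see [zscore()]).
#' @param file optional figure path (`.pdf` or `.png`); `NULL` skips drawing.
#' @return list with `row_tree`, `col_tree` (hclust or `NULL` for a single
#'   row/column), `matrix` (reordered), `file`.
#' @export
heatmap_layout <- function(z, file = NULL) {
  z <- as.matrix(z)
  row_tree <- if (nrow(z) > 1) upgma(stats::dist(z)) else NULL
  col_tree <- if (ncol(z) > 1) upgma(stats::dist(t(z))) else NULL
  ro <- if (is.null(row_tree)) 1L else row_tree$order
  co <- if (is.null(col_tree)) 1L else col_tree$order
  reordered <- z[ro, co, drop = FALSE]
  if (!is.null(file)) {
    pheatmap::pheatmap(
      z, clustering_method = "average",
      clustering_distance_rows = "euclidean",
      clustering_distance_cols = "euclidean",
      cluster_rows = !is.null(row_tree), cluster_cols = !is.null(col_tree),
      filename = file, silent = TRUE
    )
  }
  list(row_tree = row_tree, col_tree = col_tree, matrix = reordered, file = file)
}

# Deterministic sign convention: flip each loading vector so its
# largest-magnitude element is positive.
fix_signs <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Principal component analysis of standardized traits
#'
#' Eigen-decomposition of the correlation structure via singular values of
#' the Z-score matrix.  Reports genotype scores, trait loadings, the percent
#' of variance explained by each component (summing to 100 over all
#' components) and each trait's percent contribution to each component
#' (100 x squared loading; columns sum to 100).  Loading signs follow a
#' deterministic convention (largest-magnitude element positive) so results
#' are reproducible across platforms.
#'
#' @param z a Z-score matrix.
#' @param file optional biplot figure path rendered with ggplot2.
#' @return object of class `pca_result`: list with `scores`, `loadings`,
#'   `explained` (percent), `contributions` (percent), `sdev`, `file`.
#' @export
pca_traits <- function(z, file = NULL) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop("PCA needs at least 2 genotypes")
  fit <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  fx <- fix_signs(fit$rotation, fit$x)
  vars <- fit$sdev^2
  explained <- 100 * vars / sum(vars)
  contributions <- 100 * fx$rotation^2
  out <- list(scores = fx$scores, loadings = fx$rotation,
              explained = explained, contributions = contributions,
              sdev = fit$sdev, file = file)
  class(out) <- "pca_result"
  if (!is.null(file)) plot_biplot(out, file)
  out
}

plot_biplot <- function(pca, file) {
  sc <- as.data.frame(pca$scores[, 1:2, drop = FALSE])
  names(sc) <- c("PC1", "PC2")
  ld <- as.data.frame(pca$loadings[, 1:2, drop = FALSE])
  names(ld) <- c("PC1", "PC2")
  ld$trait <- rownames(pca$loadings)
  arrow_scale <- 0.8 * max(abs(as.matrix(sc))) / max(abs(as.matrix(ld[, 1:2])), 1e-9)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = PC1, y = PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(colour = "grey30", size = 1.6) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = PC1 * arrow_scale,
                   yend = PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")), colour = "firebrick"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = PC1 * arrow_scale * 1.08,
                   y = PC2 * arrow_scale * 1.08, label = trait),
      colour = "firebrick", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", pca$explained[1]),
      y = sprintf("PC2 (%.1f%%)", pca$explained[2])
    ) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file, p, width = 6.5, height = 5.5)
  invisible(file)
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$explained))
  cat("PCA of standardized traits\n")
  cat("  explained (%):", paste(sprintf("PC%d=%.1f", seq_len(k), x$explained[seq_len(k)]),
                                collapse = "  "), "\n")
  invisible(x)
}

#' Pearson correlation network of traits
#'
#' All pairwise Pearson correlations between traits across genotypes
#' (pairwise-complete observations).  Every r is retained in the returned
#' matrix and edge list; edges with |r| below `display_threshold` are only
#' flagged for visual de-emphasis, never removed.  A constant trait yields
#' undefined correlations and is flagged with a warning.
#'
#' @param values genotypes x traits matrix (raw or standardized; Pearson r is
#'   affine-invariant).
#' @param display_threshold |r| below which an edge is visually de-emphasized
#'   (cosmetic only; default 0.3).
#' @param file optional network figure path.
#' @return object of class `correlation_graph`: list with `r` (full matrix),
#'   `edges` (data.frame `from`, `to`, `r`, `displayed`), `threshold`,
#'   `file`.
#' @export
correlation_network <- function(values, display_threshold = 0.3, file = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("correlation network needs at least 3 genotypes")
  s <- apply(values, 2, stats::sd, na.rm = TRUE)
  if (any(s == 0)) {
    warning("constant trait(s) with undefined correlations: ",
            paste(colnames(values)[s == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(values, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(r), arr.ind = TRUE)
  edges <- data.frame(
    from = colnames(r)[idx[, 1]], to = colnames(r)[idx[, 2]],
    r = r[idx], stringsAsFactors = FALSE
  )
  edges$displayed <- !is.na(edges$r) & abs(edges$r) >= display_threshold
  out <- list(r = r, edges = edges, threshold = display_threshold, file = file)
  class(out) <- "correlation_graph"
  if (!is.null(file)) plot_network(out, file)
  out
}

plot_network <- function(graph, file) {
  edges <- graph$edges[!is.na(graph$edges$r), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = colnames(graph$r))
  ew <- abs(edges$r)
  # palette indexed by sign x displayed: de-emphasized edges are near-transparent
  pal <- c(pos_dim = grDevices::adjustcolor("forestgreen", 0.15),
           pos = grDevices::adjustcolor("forestgreen", 0.9),
           neg_dim = grDevices::adjustcolor("firebrick", 0.15),
           neg = grDevices::adjustcolor("firebrick", 0.9))
  key <- paste0(ifelse(edges$r >= 0, "pos", "neg"),
                ifelse(edges$displayed, "", "_dim"))
  open_dev(file, width = 6, height = 6)
  on.exit(grDevices::dev.off())
  plot(
    g, layout = igraph::layout_in_circle(g),
    edge.width = 0.5 + 4 * ew,
    edge.color = unname(pal[key]),
    vertex.color = "grey90", vertex.label.color = "black",
    vertex.size = 28, vertex.label.cex = 0.9
  )
  invisible(file)
}

open_dev <- function(file, width, height) {
  if (grepl("\\.png$", file)) {
    grDevices::png(file, width = width, height = height, units = "in", res = 150)
  } else {
    grDevices::pdf(file, width = width, height = height)
  }
}

#' @export
print.correlation_graph <- function(x, ...) {
  rng <- range(x$edges$r, na.rm = TRUE)
  cat(sprintf("Trait correlation network: %d traits, r in [%.2f, %.2f], display |r| >= %g\n",
              ncol(x$r), rng[1], rng[2], x$threshold))
  invisible(x)
}
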