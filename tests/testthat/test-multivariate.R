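test_that("Z-scores have zero mean, unit sample SD, and match hand computation", {
  expect_equal(unname(zscore(cbind(t = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  v <- c(2, 4, 4, 4, 5, 5, 7, 9)
  z <- zscore(cbind(t = v))
  expect_equal(z[1, 1], (2 - 5) / sd(v), ignore_attr = TRUE)
  set.seed(3)
  m <- matrix(rnorm(50, 10, 4), 10, 5, dimnames = list(NULL, paste0("t", 1:5)))
  z <- zscore(m)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-10)
  expect_equal(attr(z, "center"), colMeans(m))
})

test_that("a constant trait cannot be standardized and is named", {
  m <- cbind(ok = rnorm(5), flat = rep(3, 5))
  expect_error(zscore(m), "flat")
})

test_that("UPGMA merges at average distances (hand-computed 3-point case)", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(sort(tree$height), c(2, 6))
  cl <- cut_clusters(tree, 2)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["A"]] == cl[["C"]])
})

test_that("identical rows merge first at height zero", {
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(5, 9))
  tree <- upgma(dist(m))
  expect_equal(min(tree$height), 0)
  expect_equal(sort(tree$merge[1, ]), sort(-which(rownames(m) %in% c("a", "b"))))
})

test_that("UPGMA validates its input matrix", {
  m <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(m), "symmetric")
  m2 <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(upgma(m2), "zero diagonal")
})

test_that("UPGMA equals brute-force average linkage on small instances", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    m <- matrix(rnorm(2 * n), n, 2)
    d <- dist(m)
    tree <- upgma(d)
    coph <- as.matrix(stats::cophenetic(tree))
    expect_equal(unname(coph), unname(brute_upgma_cophenetic(d)), tolerance = 1e-8)
  }
})

test_that("UPGMA trees are ultrametric: heights non-decreasing along merges", {
  set.seed(23)
  m <- matrix(rnorm(60), 20, 3)
  tree <- upgma(dist(m))
  expect_true(all(diff(tree$height) >= -1e-12))
  coph <- as.matrix(stats::cophenetic(tree))
  n <- nrow(coph)
  # three-point ultrametric condition on a sample of triples
  for (i in 1:30) {
    t3 <- sample(n, 3)
    h <- sort(c(coph[t3[1], t3[2]], coph[t3[1], t3[3]], coph[t3[2], t3[3]]))
    expect_lte(h[2], h[3] + 1e-10)
    expect_equal(h[2], h[3], tolerance = 1e-8)
  }
})

test_that("cluster labels are stable under row permutations", {
  set.seed(29)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(letters[1:10], NULL))
  cl <- cut_clusters(upgma(dist(m)), 3)
  perm <- sample(10)
  cl_p <- cut_clusters(upgma(dist(m[perm, ])), 3)[rownames(m)]
  # same partition up to label renaming
  expect_equal(outer(cl, cl, "=="), outer(cl_p, cl_p, "=="), ignore_attr = TRUE)
  expect_equal(unname(cut_clusters(upgma(dist(m)), 10)), 1:10)
  expect_equal(unname(cut_clusters(upgma(dist(m)), 1)), rep(1L, 10))
  expect_error(cut_clusters(upgma(dist(m)), 11), "k must lie")
})

test_that("heatmap layout reorders without altering values and finds planted groups", {
  set.seed(31)
  base <- matrix(rnorm(20 * 4, 0, 0.3), 20, 4)
  base[1:10, ] <- base[1:10, ] + 2   # planted block structure
  base[11:20, ] <- base[11:20, ] - 2
  rownames(base) <- sprintf("g%02d", 1:20)
  colnames(base) <- paste0("t", 1:4)
  shuffled <- base[sample(20), ]
  lay <- heatmap_layout(zscore(shuffled))
  expect_equal(sort(as.vector(lay$matrix)), sort(as.vector(zscore(shuffled))))
  leaf_groups <- substr(rownames(lay$matrix), 2, 3) <= "10"
  expect_equal(sum(diff(leaf_groups) != 0), 1)  # the two groups are contiguous
})

test_that("degenerate single-genotype layout works without error", {
  z <- matrix(c(0.1, -0.2, 0.4), 1, 3, dimnames = list("g1", paste0("t", 1:3)))
  lay <- heatmap_layout(z)
  expect_null(lay$row_tree)
  expect_setequal(as.vector(lay$matrix), as.vector(z))
  expect_equal(lay$matrix["g1", colnames(z)], z["g1", ])
})

test_that("heatmap figure file is written", {
  set.seed(37)
  z <- zscore(matrix(rnorm(40), 10, 4,
                     dimnames = list(sprintf("g%02d", 1:10), paste0("t", 1:4))))
  f <- withr::local_tempfile(fileext = ".pdf")
  heatmap_layout(z, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("PCA explained variances sum to 100 and degenerate cases collapse", {
  set.seed(41)
  z <- zscore(matrix(rnorm(60), 20, 3))
  p <- pca_traits(z)
  expect_equal(sum(p$explained), 100, tolerance = 1e-10)
  expect_equal(unname(colSums(p$contributions)), rep(100, 3), tolerance = 1e-8)
  expect_equal(unname(crossprod(p$loadings)), diag(3), tolerance = 1e-10)
  # two perfectly correlated traits: PC1 carries everything
  v <- rnorm(15)
  z2 <- zscore(cbind(a = v, b = 2 * v + 3))
  p2 <- pca_traits(z2)
  expect_equal(p2$explained[1], 100, tolerance = 1e-8)
})

test_that("PCA is invariant to per-trait affine rescaling of the raw data", {
  set.seed(43)
  m <- matrix(rnorm(80, 50, 9), 20, 4, dimnames = list(NULL, paste0("t", 1:4)))
  m2 <- sweep(sweep(m, 2, c(2, -3, 0.5, 10), "*"), 2, c(1, 100, -7, 0), "+")
  p1 <- pca_traits(zscore(m))
  p2 <- pca_traits(zscore(m2))
  expect_equal(p1$explained, p2$explained, tolerance = 1e-8)
  expect_equal(abs(p1$loadings), abs(p2$loadings), tolerance = 1e-8)
})

test_that("planted two-factor structure is recovered by the first components", {
  set.seed(47)
  n <- 300
  f1 <- rnorm(n)
  f2 <- rnorm(n)
  loads <- cbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  m <- cbind(f1, f2) %*% t(loads) + matrix(rnorm(n * 6, 0, 0.4), n, 6)
  colnames(m) <- paste0("t", 1:6)
  p <- pca_traits(zscore(m))
  # each factor explains ~ 1/(1+0.16) of three traits' variance; over six
  # traits the two leading components should take most of the variance
  expect_gt(sum(p$explained[1:2]), 75)
  expect_lt(sum(p$explained[1:2]), 95)
})

test_that("deterministic sign convention makes repeated PCA identical", {
  set.seed(53)
  z <- zscore(matrix(rnorm(100), 25, 4))
  p1 <- pca_traits(z)
  p2 <- pca_traits(z)
  expect_identical(p1$loadings, p2$loadings)
  expect_true(all(apply(p1$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("correlation network keeps every r and flags by display threshold", {
  set.seed(59)
  v <- rnorm(30)
  m <- cbind(a = v, b = v, c = rnorm(30))
  net <- correlation_network(m, display_threshold = 0.3)
  expect_equal(net$r["a", "b"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(net$r))
  expect_equal(unname(diag(net$r)), rep(1, 3))
  expect_true(all(net$r >= -1 & net$r <= 1))
  ab <- net$edges[net$edges$from == "a" & net$edges$to == "b", ]
  expect_true(ab$displayed)
  expect_equal(nrow(net$edges), 3)  # all pairs retained, displayed or not
})

test_that("independent traits produce only small correlations at n = 1000", {
  set.seed(61)
  m <- matrix(rnorm(5000), 1000, 5, dimnames = list(NULL, paste0("t", 1:5)))
  net <- correlation_network(m)
  off <- net$edges$r
  expect_lt(max(abs(off)), 0.15)
})

test_that("constant traits are flagged in the network", {
  m <- cbind(a = rnorm(10), flat = rep(2, 10))
  expect_warning(net <- correlation_network(m), "flat")
  expect_true(is.na(net$r["a", "flat"]))
})
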