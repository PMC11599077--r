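# Correlation matrix, Ward agglomeration, centroid silhouette, k-selection,
# factor scoring.

# block-structured correlation matrix with exact within/between values
block_corr <- function(sizes, within, between) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  for (b in seq_along(sizes)) m[lab == b, lab == b] <- within
  diag(m) <- 1
  rownames(m) <- colnames(m) <- paste0("i", seq_len(n))
  m
}

test_that("pcc matrix reproduces hand-computed correlations", {
  # x = (1,2,3,4), y = (1,3,2,4) has correlation 0.8 by direct evaluation
  resp <- cbind(x = c(1L, 2L, 3L, 4L), y = c(1L, 3L, 2L, 4L),
                z = c(4L, 3L, 2L, 1L))
  rownames(resp) <- paste0("r", 1:4)
  ds <- survey_dataset(resp, dose = rep(1L, 4),
                       scales = list(scale_definition("S", c("x", "y", "z"))))
  corr <- pcc_matrix(ds, "S")
  expect_equal(corr["x", "y"], 0.8)
  expect_equal(corr["x", "z"], -1)        # reflected copy
  expect_equal(diag(corr), c(x = 1, y = 1, z = 1))
  expect_equal(corr, t(corr))
})

test_that("pcc of an item with a positive affine transform of itself is 1", {
  x <- c(1, 5, 2, 4, 3)
  expect_equal(stats::cor(x, 2 * x + 1), 1)
  resp <- cbind(a = as.integer(x), b = as.integer(x)) # duplicate item
  rownames(resp) <- paste0("r", 1:5)
  ds <- survey_dataset(resp, rep(0L, 5),
                       scales = list(scale_definition("S", c("a", "b"))))
  expect_equal(pcc_matrix(ds, "S")["a", "b"], 1)
})

test_that("zero-variance items are reported by name", {
  resp <- cbind(a = c(1L, 2L, 3L), b = c(2L, 2L, 2L))
  rownames(resp) <- paste0("r", 1:3)
  ds <- survey_dataset(resp, rep(0L, 3),
                       scales = list(scale_definition("S", c("a", "b"))))
  expect_error(pcc_matrix(ds, "S"), "b")
})

test_that("ward partition recovers perfect blocks and handles edge k", {
  corr <- block_corr(c(4, 4), within = 1, between = 0)
  p <- ward_partition(corr, 2)
  expect_identical(length(unique(p$assignment[1:4])), 1L)
  expect_identical(length(unique(p$assignment[5:8])), 1L)
  expect_false(p$assignment[1] == p$assignment[5])
  # k = number of items -> singletons
  expect_identical(sort(unname(ward_partition(corr, 8)$assignment)), 1:8)
  expect_error(ward_partition(corr, 9), "out of range")
})

test_that("ward merge order equals an independent Lance-Williams recursion", {
  # fixed 5-item toy dissimilarity
  set.seed(17)
  corr <- stats::cov2cor(crossprod(matrix(stats::rnorm(40), 8, 5)))
  rownames(corr) <- colnames(corr) <- paste0("i", 1:5)
  d <- 1 - corr
  tree <- ward_partition(corr, 2)$tree
  expect_identical(hclust_merges(tree), lw_ward_merges(d))
})

test_that("ward partition is invariant to item order up to relabeling", {
  ds <- small_dataset(seed = 5)
  corr <- pcc_matrix(ds, "SA")
  perm <- sample(nrow(corr))
  p1 <- ward_partition(corr, 3)$assignment
  p2 <- ward_partition(corr[perm, perm], 3)$assignment
  expect_equal(ari(p1, p2[names(p1)]), 1)
})

test_that("centroid silhouette matches direct formula evaluation", {
  # 1-D: own centroid at 0 (items at -1 and 1), other at 10
  coords <- matrix(c(-1, 1, 10, 10), ncol = 1)
  assignment <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  rownames(coords) <- names(assignment)
  sil <- centroid_silhouette(assignment, coords)
  expect_equal(unname(sil$a["b"]), 1)
  expect_equal(unname(sil$b["b"]), 9)
  expect_equal(unname(sil$s["b"]), 8 / 9)
  # two tight, far-separated clusters approach 1
  expect_gt(sil$sc, 0.9)
  expect_error(centroid_silhouette(c(a = 1L, b = 1L), coords[1:2, , drop = FALSE]),
               "single cluster")
})

test_that("equidistant items score zero and s stays within [-1, 1]", {
  coords <- matrix(c(0, 2, 5, 7, 10, 12), ncol = 1)
  assignment <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])
  rownames(coords) <- letters[1:6]
  sil <- centroid_silhouette(assignment, coords)
  expect_true(all(sil$s >= -1 & sil$s <= 1))
  # item c sits equidistant from its own centroid ((-1+1+6)/3 = 2, distance
  # 4) and the other centroid (10, distance 4): s = 0
  coords2 <- matrix(c(-1, 1, 6, 9, 11), ncol = 1)
  assignment2 <- stats::setNames(c(1L, 1L, 1L, 2L, 2L), letters[1:5])
  rownames(coords2) <- letters[1:5]
  sil2 <- centroid_silhouette(assignment2, coords2)
  expect_equal(unname(sil2$s["c"]), 0)
})

test_that("select_k recovers planted blocks and reports quality per k", {
  corr <- block_corr(c(6, 5, 5, 5), within = 0.7, between = 0.1)
  sol <- select_k(corr, pcc_floor = 0.5)
  expect_identical(sol$chosen_k, 4L)
  expect_identical(nrow(sol$quality), 7L) # k = 2..8 all examined
  truth <- rep(1:4, c(6, 5, 5, 5))
  expect_equal(ari(sol$assignment, truth), 1)
  # two perfect blocks
  sol2 <- select_k(block_corr(c(5, 5), within = 0.99, between = 0),
                   pcc_floor = 0.5)
  expect_identical(sol2$chosen_k, 2L)
})

test_that("select_k returns an inadmissible result with the quality table", {
  corr <- block_corr(c(5, 5), within = 0.3, between = 0.1)
  sol <- select_k(corr, pcc_floor = 0.9)
  expect_true(is.na(sol$chosen_k))
  expect_null(sol$assignment)
  expect_false(any(sol$quality$admissible))
  expect_identical(nrow(sol$quality), 7L)
})

test_that("planted item structure is recovered across seeds with high ARI", {
  hits <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    cfg <- small_config(seed = seed, n = 400)
    gen <- generate_dataset(cfg)
    ds <- reverse_score(gen$dataset)
    truth <- gen$truth$item_partition
    ok <- TRUE
    for (sid in names(ds$scales)) {
      sol <- select_k(pcc_matrix(ds, sid), pcc_floor = 0.5, scale_id = sid)
      if (is.na(sol$chosen_k)) { ok <- FALSE; break }
      t_scale <- truth[names(sol$assignment)]
      if (ari(sol$assignment, t_scale) < 0.9) { ok <- FALSE; break }
    }
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("silhouette of planted blocks clears the weak-structure cutoff", {
  ds <- small_dataset(seed = 11, n = 500)
  sol <- select_k(pcc_matrix(ds, "SA"), pcc_floor = 0.5)
  expect_gte(sol$quality$sc[sol$quality$k == sol$chosen_k], 0.25)
})

test_that("factor scores aggregate clusters and respect conventions", {
  resp <- cbind(a = c(4L, 2L), b = c(5L, 2L), c = c(3L, 2L), d = c(1L, 5L))
  rownames(resp) <- c("r1", "r2")
  ds <- survey_dataset(resp, dose = c(0L, 1L),
                       scales = list(scale_definition("S", letters[1:4],
                                                      prefix = "S")))
  sol <- structure(list(scale_id = "S", chosen_k = 2L,
                        assignment = c(a = 1L, b = 1L, c = 1L, d = 2L)),
                   class = "factor_solution")
  sc_mean <- compute_factor_scores(ds, list(S = sol))
  expect_identical(colnames(sc_mean), c("S-c1", "S-c2"))
  expect_equal(unname(sc_mean["r1", ]), c(4, 1)) # mean(4,5,3); singleton
  sc_sum <- compute_factor_scores(ds, list(S = sol), aggregator = "sum")
  expect_equal(unname(sc_sum["r1", "S-c1"]), 12)
  # mean aggregation is invariant under duplicating every item of a cluster
  resp2 <- cbind(resp, a2 = resp[, "a"], b2 = resp[, "b"], c2 = resp[, "c"])
  ds2 <- survey_dataset(resp2, dose = c(0L, 1L),
                        scales = list(scale_definition("S", colnames(resp2),
                                                       prefix = "S")))
  sol2 <- structure(list(scale_id = "S", chosen_k = 2L,
                         assignment = c(a = 1L, b = 1L, c = 1L, d = 2L,
                                        a2 = 1L, b2 = 1L, c2 = 1L)),
                    class = "factor_solution")
  expect_equal(compute_factor_scores(ds2, list(S = sol2))[, "S-c1"],
               sc_mean[, "S-c1"])
})
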