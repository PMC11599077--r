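# Cell-level signal, aggregation, Gaussian smoothing, ROI extraction.

test_that("cell signal equals the brute-force mutual information oracle", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(10:40, 1)
    f <- stats::rnorm(n)
    dose <- sample(0:5, n, replace = TRUE)
    a <- f > stats::median(f) # the cell-local binarization, reproduced
    expect_equal(cell_sig_factor(f, dose, min_members = 5),
                 if (all(a) || !any(a)) 0 else mi_bruteforce(a, dose),
                 tolerance = 1e-12)
  }
})

test_that("degenerate cells give exactly zero signal", {
  # constant dose: zero entropy
  expect_identical(cell_sig_factor(stats::rnorm(20), rep(2L, 20)), 0)
  # factor split independent of dose: identical dose patterns in both halves
  f <- rep(c(0, 1), each = 10)
  dose <- rep(c(0L, 3L), 10)
  expect_equal(cell_sig_factor(f, dose), 0, tolerance = 1e-12)
  # occupancy below the floor
  expect_identical(cell_sig_factor(c(0, 1, 0, 1), c(0L, 5L, 0L, 5L),
                                   min_members = 5), 0)
  # constant factor: no split
  expect_identical(cell_sig_factor(rep(1, 12), rep(c(0L, 5L), 6)), 0)
})

test_that("a perfect dose split yields ln 2", {
  f <- rep(c(0, 1), each = 10)
  dose <- rep(c(0L, 5L), each = 10)
  expect_equal(cell_sig_factor(f, dose), log(2), tolerance = 1e-12)
})

test_that("signal is nonnegative over random cells", {
  set.seed(77)
  for (rep in 1:50) {
    f <- stats::rnorm(25)
    dose <- sample(0:5, 25, replace = TRUE)
    expect_gte(cell_sig_factor(f, dose), 0)
  }
})

test_that("aggregation is an element-wise weighted sum", {
  a <- matrix(1:6, 2, 3); b <- matrix(6:1, 2, 3)
  expect_equal(aggregate_sig(list(a, b)), a + b)
  expect_equal(aggregate_sig(list(a, b), weights = c(2, 0)), 2 * a)
  expect_equal(aggregate_sig(list(a * 0, b * 0)), a * 0)
  expect_error(aggregate_sig(list(a, matrix(0, 3, 3))), "shape")
})

test_that("Gaussian smoothing matches the kernel formula at unit impulse", {
  coords <- cbind(x = c(0, 3), y = c(0, 0.4))
  rownames(coords) <- c("r1", "r2")
  g <- build_grid(coords, step = 0.5) # 6 x 1 cells, centers 0.5 apart
  raw <- matrix(0, g$nx, g$ny)
  raw[1, 1] <- 1
  sm <- smooth_surface(raw, g, sigma = 1)
  expect_equal(sm[1, 1], 1 / sqrt(2 * pi), tolerance = 1e-9)
  # cell two steps away: distance 1 embedding unit
  expect_equal(sm[3, 1], exp(-0.5) / sqrt(2 * pi), tolerance = 1e-9)
  expect_equal(smooth_surface(raw * 0, g), raw * 0)
  expect_error(smooth_surface(raw, g, sigma = 0), "sigma")
})

test_that("smoothing is linear in the raw signal", {
  set.seed(5)
  coords <- cbind(x = stats::runif(40, 0, 4), y = stats::runif(40, 0, 3))
  rownames(coords) <- paste0("r", 1:40)
  g <- build_grid(coords)
  a <- matrix(stats::rexp(g$nx * g$ny), g$nx, g$ny)
  b <- matrix(stats::rexp(g$nx * g$ny), g$nx, g$ny)
  lhs <- smooth_surface(2.5 * a + 0.3 * b, g)
  rhs <- 2.5 * smooth_surface(a, g) + 0.3 * smooth_surface(b, g)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("ROI extraction separates disconnected components", {
  # two hot cells far apart on a 9x1 strip, members planted in each
  coords <- cbind(x = c(rep(0.1, 12), rep(4.3, 12), 2.2), y = rep(0.1, 25))
  rownames(coords) <- paste0("r", 1:25)
  g <- build_grid(coords, step = 0.5)
  cells <- assign_cells(coords, g)
  smoothed <- matrix(0, g$nx, g$ny)
  smoothed[1, 1] <- 1; smoothed[g$nx, 1] <- 0.9
  dose <- rep(c(0L, 5L), length.out = 25)
  rois <- extract_rois(smoothed, g, cells, dose, min_members = 10)
  expect_length(rois, 2L)
  expect_identical(rois[[1]]$roi_id, "ROI-1")
  expect_identical(rois[[1]]$n, 12L) # strongest peak first
  expect_gte(rois[[2]]$peak_signal, 0.34 * max(smoothed))
  # masks are disjoint and members lie in supra-threshold cells
  cells1 <- paste(rois[[1]]$cells[, 1], rois[[1]]$cells[, 2])
  cells2 <- paste(rois[[2]]$cells[, 1], rois[[2]]$cells[, 2])
  expect_length(intersect(cells1, cells2), 0L)
  # contour levels at the conventional fractions of the maximum
  expect_equal(unname(attr(rois, "contour_values")),
               c(0, 0.17, 0.34, 0.51) * max(smoothed))
})

test_that("a single supra-threshold cell with enough members forms one ROI", {
  coords <- cbind(x = c(rep(0.1, 12), rep(3.9, 4)), y = rep(0.1, 16))
  rownames(coords) <- paste0("r", 1:16)
  g <- build_grid(coords, step = 0.5)
  cells <- assign_cells(coords, g)
  smoothed <- matrix(0, g$nx, g$ny)
  smoothed[1, 1] <- 1; smoothed[g$nx, 1] <- 0.5 # second cell under-populated
  rois <- extract_rois(smoothed, g, cells, dose = rep(1L, 16), min_members = 10)
  expect_length(rois, 1L)
  expect_identical(sort(rois[[1]]$member_ids), sort(paste0("r", 1:12)))
  expect_equal(rois[[1]]$dose_mean, 1)
  expect_equal(rois[[1]]$dose_sd, 0)
})

test_that("an all-zero surface yields an empty ROI list", {
  coords <- cbind(x = stats::runif(20, 0, 2), y = stats::runif(20, 0, 2))
  rownames(coords) <- paste0("r", 1:20)
  g <- build_grid(coords)
  rois <- extract_rois(matrix(0, g$nx, g$ny), g, assign_cells(coords, g),
                       dose = rep(0L, 20))
  expect_length(rois, 0L)
})

test_that("connected components honour 8-connectivity", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE; mask[2, 2] <- TRUE  # diagonal touch: one component
  mask[4, 4] <- TRUE                      # isolated
  lab <- sigroi:::label_components(mask)
  expect_identical(lab[1, 1], lab[2, 2])
  expect_false(lab[4, 4] == lab[1, 1])
  expect_identical(max(lab), 2L)
})

test_that("every ROI cell's smoothed value reaches the cutoff", {
  ds <- small_dataset(seed = 8, n = 400)
  sols <- extract_factors(ds, pcc_floor = 0.5)
  sco <- compute_factor_scores(ds, sols)
  emb <- embed_points(sco, method = "pca")
  sig <- compute_sig(emb, sco, ds$dose)
  for (r in sig$rois) {
    vals <- sig$smoothed[cbind(r$cells[, "ix"], r$cells[, "iy"])]
    expect_true(all(vals >= sig$cutoff - 1e-12))
    expect_gte(r$n, sig$params$min_roi_members)
  }
})
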