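#' Project respondents into a 2D latent space
#'
#' Embeds the respondents' factor-score profiles in two dimensions so that
#' proximity reflects similarity of perceptions. The default method is UMAP
#' (run single-threaded under a fixed seed, so coordinates are reproducible);
#' `"pca"` provides a fast, closed-form deterministic alternative that tests
#' and quick looks can substitute. Factor columns are z-scored first by
#' default so that 4-point and 5-point scales contribute comparably.
#'
#' @param scores Numeric matrix respondents x factors (from
#'   [compute_factor_scores()]).
#' @param method `"umap"` (default) or `"pca"`.
#' @param n_neighbors,min_dist,metric UMAP hyperparameters (defaults 15,
#'   0.1, `"euclidean"`).
#' @param seed Integer seed controlling all embedding randomness.
#' @param standardize Z-score factor columns before projection (default
#'   `TRUE`).
#' @return A `survey_embedding`: list with `coords` (n x 2, columns `x`,`y`,
#'   rownames = respondent ids), `method`, and `params`.
#' @export
embed_points <- function(scores, method = c("umap", "pca"), n_neighbors = 15L,
                         min_dist = 0.1, metric = "euclidean", seed = 42L,
                         standardize = TRUE) {
  method <- match.arg(method)
  x <- as.matrix(scores)
  if (nrow(x) < 3L) stop("need at least 3 respondents to embed")
  if (anyNA(x)) stop("missing factor scores")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) sds[sds == 0] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }
  coords <- switch(method,
    umap = {
      if (n_neighbors >= nrow(x))
        stop("parameter error: n_neighbors (", n_neighbors,
             ") must be smaller than the number of respondents (", nrow(x), ")")
      withr::with_seed(seed,
        uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
                   metric = metric, n_components = 2L, n_threads = 1L,
                   n_sgd_threads = 0L, verbose = FALSE))
    },
    pca = {
      p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      xy <- p$x[, 1:2, drop = FALSE]
      if (ncol(xy) < 2L) xy <- cbind(xy, 0)
      # fix component signs (largest-magnitude loading positive) for
      # order-independent determinism
      for (j in 1:2) {
        rot <- p$rotation[, min(j, ncol(p$rotation))]
        if (rot[which.max(abs(rot))] < 0) xy[, j] <- -xy[, j]
      }
      xy
    })
  coords <- unname(as.matrix(coords))
  colnames(coords) <- c("x", "y")
  rownames(coords) <- rownames(scores)
  if (anyNA(coords) || any(!is.finite(coords))) stop("non-finite coordinates")
  structure(
    list(coords = coords, method = method,
         params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                       metric = metric, seed = seed, standardize = standardize)),
    class = "survey_embedding")
}

#' @export
print.survey_embedding <- function(x, ...) {
  cat("survey_embedding:", nrow(x$coords), "respondents,", x$method,
      "(seed", paste0(x$params$seed, ")"), "\n")
  invisible(x)
}

#' Lay a regular grid over an embedding
#'
#' The grid spans the exact coordinate extrema with square cells of side
#' `step` (default 0.5 embedding units). Cells are half-open
#' `[edge, edge + step)` in each axis except the last cell, which is closed
#' at the top so the maximal point is covered; every respondent therefore
#' falls in exactly one cell.
#'
#' @param embedding A `survey_embedding` (or an n x 2 coordinate matrix).
#' @param step Cell side length, > 0.
#' @return A `sig_grid`: list with `x_min`, `x_max`, `y_min`, `y_max`,
#'   `step`, `nx`, `ny`.
#' @export
build_grid <- function(embedding, step = 0.5) {
  coords <- if (inherits(embedding, "survey_embedding")) embedding$coords
            else as.matrix(embedding)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("parameter error: step must be a positive number")
  if (nrow(coords) < 1L) stop("empty embedding")
  xr <- range(coords[, 1L]); yr <- range(coords[, 2L])
  nx <- max(1L, as.integer(ceiling((xr[2L] - xr[1L]) / step - 1e-9)))
  ny <- max(1L, as.integer(ceiling((yr[2L] - yr[1L]) / step - 1e-9)))
  structure(
    list(x_min = xr[1L], x_max = xr[2L], y_min = yr[1L], y_max = yr[2L],
         step = step, nx = nx, ny = ny),
    class = "sig_grid")
}

#' @export
print.sig_grid <- function(x, ...) {
  cat(sprintf("sig_grid: %d x %d cells, step %g, x [%.3g, %.3g], y [%.3g, %.3g]\n",
              x$nx, x$ny, x$step, x$x_min, x$x_max, x$y_min, x$y_max))
  invisible(x)
}

#' Assign respondents to grid cells
#'
#' Applies the half-open cell convention: a coordinate exactly on an interior
#' edge belongs to the higher cell; points at the grid maximum fall in the
#' last cell.
#'
#' @param embedding A `survey_embedding` (or coordinate matrix) whose grid
#'   this is.
#' @param grid A `sig_grid` built from the same embedding.
#' @return Integer matrix n x 2 (columns `ix`, `iy`, both 1-based) with
#'   respondent ids as rownames.
#' @export
assign_cells <- function(embedding, grid) {
  coords <- if (inherits(embedding, "survey_embedding")) embedding$coords
            else as.matrix(embedding)
  stopifnot(inherits(grid, "sig_grid"))
  if (any(coords[, 1L] < grid$x_min - 1e-9 | coords[, 1L] > grid$x_max + 1e-9 |
          coords[, 2L] < grid$y_min - 1e-9 | coords[, 2L] > grid$y_max + 1e-9))
    stop("internal error: coordinates outside grid bounds")
  ix <- pmin(grid$nx, pmax(1L, floor((coords[, 1L] - grid$x_min) / grid$step) + 1L))
  iy <- pmin(grid$ny, pmax(1L, floor((coords[, 2L] - grid$y_min) / grid$step) + 1L))
  out <- cbind(ix = as.integer(ix), iy = as.integer(iy))
  rownames(out) <- rownames(coords)
  out
}

# internal: cell-center coordinates for every (ix, iy) pair of a grid,
# returned as an (nx*ny) x 2 matrix in column-major cell order (ix fastest).
cell_centers <- function(grid) {
  cx <- grid$x_min + (seq_len(grid$nx) - 0.5) * grid$step
  cy <- grid$y_min + (seq_len(grid$ny) - 0.5) * grid$step
  cbind(x = rep(cx, times = grid$ny), y = rep(cy, each = grid$nx))
}
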