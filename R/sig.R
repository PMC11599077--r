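#' Spatial information gain of one factor within one cell
#'
#' Within a grid cell, the factor is binarized at the cell-local median
#' (values <= median form the "low" group) and the signal is the expected
#' Kullback-Leibler divergence of the conditional dose distribution from the
#' cell's marginal dose distribution,
#' `sum_a P(a) * KL(P(dose | a) || P(dose))`, in nats. This equals the
#' plug-in mutual information between the dose and the binarized factor over
#' the cell's members, and is therefore nonnegative and zero when the two are
#' independent. Cells with fewer members than `min_members` return 0 (the
#' plug-in estimate is strongly upward-biased in tiny samples).
#'
#' @param factor_scores Numeric vector of the factor's scores for the cell's
#'   members.
#' @param dose Integer dose vector aligned with `factor_scores`.
#' @param min_members Occupancy floor (default 5).
#' @return Nonnegative scalar, nats.
#' @export
cell_sig_factor <- function(factor_scores, dose, min_members = 5L) {
  n <- length(dose)
  stopifnot(length(factor_scores) == n)
  if (n < min_members) return(0)
  a <- factor_scores > stats::median(factor_scores) # ties go to the low group
  if (all(a) || !any(a)) return(0)
  plugin_mi(a, dose)
}

# internal: plug-in mutual information (nats) of two discrete vectors,
# with the 0 * log(0/q) = 0 convention.
plugin_mi <- function(x, y) {
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  terms <- joint * log(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Per-factor SIG maps over a grid
#'
#' Evaluates [cell_sig_factor()] in every occupied grid cell for every
#' factor, producing one `nx x ny` signal matrix per factor.
#'
#' @param scores Factor-score matrix (respondents x factors).
#' @param dose Integer dose vector aligned with `scores` rows.
#' @param cells Cell assignment from [assign_cells()].
#' @param grid The `sig_grid`.
#' @param min_members Cell occupancy floor passed to [cell_sig_factor()].
#' @return Named list of `nx x ny` matrices (one per factor), zero in cells
#'   below the occupancy floor.
#' @export
sig_maps <- function(scores, dose, cells, grid, min_members = 5L) {
  stopifnot(inherits(grid, "sig_grid"), nrow(cells) == nrow(scores),
            length(dose) == nrow(scores))
  lin <- (cells[, "iy"] - 1L) * grid$nx + cells[, "ix"]
  groups <- split(seq_len(nrow(scores)), lin)
  groups <- groups[lengths(groups) >= min_members]
  maps <- lapply(colnames(scores), function(f) {
    m <- matrix(0, grid$nx, grid$ny)
    for (cell in names(groups)) {
      idx <- groups[[cell]]
      m[as.integer(cell)] <- cell_sig_factor(scores[idx, f], dose[idx],
                                             min_members = min_members)
    }
    m
  })
  names(maps) <- colnames(scores)
  maps
}

#' Aggregate per-factor SIG maps
#'
#' Element-wise weighted sum of the per-factor signal matrices (weights
#' default to 1, i.e. a plain sum over factors and hence over scales).
#'
#' @param per_factor List of equally sized matrices.
#' @param weights Optional numeric vector, one weight per matrix.
#' @return Single aggregated matrix.
#' @export
aggregate_sig <- function(per_factor, weights = NULL) {
  stopifnot(is.list(per_factor), length(per_factor) >= 1L)
  dims <- vapply(per_factor, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("SIG matrices have mismatched shapes")
  if (is.null(weights)) weights <- rep(1, length(per_factor))
  stopifnot(length(weights) == length(per_factor))
  out <- matrix(0, dims[1L, 1L], dims[2L, 1L])
  for (i in seq_along(per_factor)) out <- out + weights[i] * per_factor[[i]]
  out
}

#' Gaussian interpolation of a SIG signal surface
#'
#' Smooths the raw cell signal with an (unnormalized) Gaussian kernel:
#' the smoothed height at cell p is
#' `sum_v h_v * (1 / (sqrt(2*pi) * sigma)) * exp(-||p - v||^2 / (2 sigma^2))`,
#' where `||p - v||` is the Euclidean distance between cell centers in
#' embedding units. The operation is linear in the raw signal.
#'
#' @param raw `nx x ny` nonnegative signal matrix.
#' @param grid The `sig_grid` the matrix lives on.
#' @param sigma Dispersion scale in embedding units (default 1).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_surface <- function(raw, grid, sigma = 1) {
  stopifnot(inherits(grid, "sig_grid"), is.matrix(raw),
            nrow(raw) == grid$nx, ncol(raw) == grid$ny)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("parameter error: sigma must be > 0")
  ctr <- cell_centers(grid)
  d2 <- outer(rowSums(ctr^2), rowSums(ctr^2), "+") - 2 * ctr %*% t(ctr)
  kern <- exp(-pmax(d2, 0) / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  matrix(kern %*% as.vector(raw), grid$nx, grid$ny)
}

# internal: label connected components of a logical nx x ny mask
# (8-connectivity), returning an integer matrix with 0 off-mask.
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  current <- 0L
  offsets <- cbind(dx = rep(-1:1, 3L), dy = rep(-1:1, each = 3L))
  offsets <- offsets[!(offsets[, 1L] == 0L & offsets[, 2L] == 0L), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- start
    lab[start] <- current
    while (length(queue)) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      cx <- ((cell - 1L) %% nx) + 1L
      cy <- ((cell - 1L) %/% nx) + 1L
      nbx <- cx + offsets[, 1L]; nby <- cy + offsets[, 2L]
      keep <- nbx >= 1L & nbx <= nx & nby >= 1L & nby <= ny
      nb <- (nby[keep] - 1L) * nx + nbx[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- current
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Extract ROI subgroups from a smoothed SIG surface
#'
#' Thresholds the smoothed surface at `c = cutoff_fraction * max(smoothed)`
#' (default 34% of the maximum), labels 8-connected components of the
#' supra-threshold cells, and turns each component holding at least
#' `min_members` respondents into an ROI subgroup with its dose mean and SD.
#' ROIs are numbered by decreasing peak smoothed signal. Contour levels at the four
#' conventional fractions of the maximum (0, 17, 34, 51%) are reported
#' alongside.
#'
#' @param smoothed Smoothed `nx x ny` signal matrix.
#' @param grid The `sig_grid`.
#' @param cells Cell assignment from [assign_cells()].
#' @param dose Integer dose vector aligned with `cells` rows.
#' @param cutoff_fraction Fraction of the maximum defining the ROI cutoff
#'   (default 0.34).
#' @param min_members Minimum respondents per ROI (default 10).
#' @param contour_fractions Fractions of the maximum at which contour level
#'   values are reported (default `c(0, 0.17, 0.34, 0.51)`).
#' @return List of `roi_subgroup` objects (possibly empty), with attributes
#'   `"cutoff"` (the threshold value) and `"contour_values"`.
#' @export
extract_rois <- function(smoothed, grid, cells, dose, cutoff_fraction = 0.34,
                         min_members = 10L,
                         contour_fractions = c(0, 0.17, 0.34, 0.51)) {
  stopifnot(inherits(grid, "sig_grid"), nrow(cells) == length(dose))
  if (any(smoothed < -1e-12)) stop("smoothed surface must be nonnegative")
  mx <- max(smoothed)
  cutoff <- cutoff_fraction * mx
  contour_values <- contour_fractions * mx
  out <- list()
  if (mx > 0) {
    lab <- label_components(smoothed >= cutoff)
    lin <- (cells[, "iy"] - 1L) * grid$nx + cells[, "ix"]
    comp_of_member <- lab[lin]
    comps <- sort(unique(lab[lab > 0L]))
    rois <- list()
    for (cmp in comps) {
      members <- which(comp_of_member == cmp)
      if (length(members) < min_members) next
      cellsets <- which(lab == cmp)
      cxy <- cbind(ix = ((cellsets - 1L) %% grid$nx) + 1L,
                   iy = ((cellsets - 1L) %/% grid$nx) + 1L)
      rois[[length(rois) + 1L]] <- list(
        cells = cxy, member_ids = rownames(cells)[members],
        n = length(members),
        dose_mean = mean(dose[members]),
        dose_sd = if (length(members) > 1L) stats::sd(dose[members]) else 0,
        peak_signal = max(smoothed[cellsets]))
    }
    if (length(rois)) {
      rois <- rois[order(-vapply(rois, `[[`, numeric(1), "peak_signal"))]
      for (i in seq_along(rois)) {
        rois[[i]]$roi_id <- paste0("ROI-", i)
        class(rois[[i]]) <- "roi_subgroup"
      }
      out <- rois
    }
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "contour_values") <- stats::setNames(
    contour_values, paste0(round(100 * contour_fractions), "%"))
  out
}

#' @export
print.roi_subgroup <- function(x, ...) {
  cat(sprintf("%s: n = %d, dose %.1f +/- %.1f, %d cells, peak signal %.3g\n",
              x$roi_id, x$n, x$dose_mean, x$dose_sd, nrow(x$cells),
              x$peak_signal))
  invisible(x)
}

#' Full spatial-information-gain analysis
#'
#' Convenience wrapper running the whole spatial stage: grid construction,
#' cell assignment, per-factor SIG maps, aggregation, Gaussian smoothing,
#' and ROI extraction.
#'
#' @param embedding A `survey_embedding`.
#' @param scores Factor-score matrix aligned with the embedding rows.
#' @param dose Integer dose vector aligned likewise.
#' @param step Grid step (default 0.5 embedding units).
#' @param sigma Smoothing scale (default 1).
#' @param min_cell_members Occupancy floor for the cell-level signal.
#' @param cutoff_fraction,min_roi_members,contour_fractions Passed to
#'   [extract_rois()].
#' @param weights Optional per-factor aggregation weights.
#' @return A `sig_surface`: list with `grid`, `cells`, `per_factor`,
#'   `aggregated`, `smoothed`, `rois`, `cutoff`, `contour_values`, and the
#'   parameters used.
#' @export
compute_sig <- function(embedding, scores, dose, step = 0.5, sigma = 1,
                        min_cell_members = 5L, cutoff_fraction = 0.34,
                        min_roi_members = 10L,
                        contour_fractions = c(0, 0.17, 0.34, 0.51),
                        weights = NULL) {
  stopifnot(inherits(embedding, "survey_embedding"))
  grid <- build_grid(embedding, step = step)
  cells <- assign_cells(embedding, grid)
  per_factor <- sig_maps(scores, dose, cells, grid, min_members = min_cell_members)
  aggregated <- aggregate_sig(per_factor, weights)
  smoothed <- smooth_surface(aggregated, grid, sigma = sigma)
  rois <- extract_rois(smoothed, grid, cells, dose,
                       cutoff_fraction = cutoff_fraction,
                       min_members = min_roi_members,
                       contour_fractions = contour_fractions)
  structure(
    list(grid = grid, cells = cells, per_factor = per_factor,
         aggregated = aggregated, smoothed = smoothed, rois = rois,
         cutoff = attr(rois, "cutoff"),
         contour_values = attr(rois, "contour_values"),
         params = list(step = step, sigma = sigma,
                       min_cell_members = min_cell_members,
                       cutoff_fraction = cutoff_fraction,
                       min_roi_members = min_roi_members)),
    class = "sig_surface")
}

#' @export
print.sig_surface <- function(x, ...) {
  cat(sprintf("sig_surface: %d x %d grid, %d factors, max smoothed %.3g, cutoff %.3g\n",
              x$grid$nx, x$grid$ny, length(x$per_factor), max(x$smoothed),
              x$cutoff))
  cat(" ", length(x$rois), "ROI subgroup(s)\n")
  for (r in x$rois) { cat("  "); print(r) }
  invisible(x)
}
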