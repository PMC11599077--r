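#' PCC heatmap with cluster frames
#'
#' Items are ordered by the Ward dendrogram; dashed frames mark the chosen
#' clusters (the extracted factors).
#'
#' @param corr Item correlation matrix.
#' @param solution The scale's `factor_solution`.
#' @return A ggplot object.
#' @export
plot_pcc_heatmap <- function(corr, solution) {
  ord <- solution$tree$order
  items <- rownames(corr)[ord]
  df <- expand.grid(row = items, col = items, stringsAsFactors = FALSE)
  df$pcc <- corr[cbind(match(df$row, rownames(corr)),
                       match(df$col, colnames(corr)))]
  df$row <- factor(df$row, levels = items)
  df$col <- factor(df$col, levels = items)
  # cluster frame rectangles in dendrogram order
  cl <- solution$assignment[items]
  frames <- do.call(rbind, lapply(unique(cl), function(k) {
    idx <- which(cl == k)
    data.frame(xmin = min(idx) - 0.5, xmax = max(idx) + 0.5,
               ymin = min(idx) - 0.5, ymax = max(idx) + 0.5)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = as.integer(col), y = as.integer(row),
                                   fill = pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::geom_rect(data = frames,
                       ggplot2::aes(xmin = xmin, xmax = xmax,
                                    ymin = ymin, ymax = ymax),
                       inherit.aes = FALSE, fill = NA, colour = "black",
                       linetype = "dashed") +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC",
                  title = solution$scale_id) +
    ggplot2::theme_minimal()
}

#' Embedding scatter colored by dose (or a factor)
#'
#' @param embedding A `survey_embedding`.
#' @param colour Numeric vector aligned with the embedding rows.
#' @param colour_name Legend title.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, colour, colour_name = "dose") {
  df <- data.frame(embedding$coords, colour = colour)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, colour = colour)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c(option = "plasma", name = colour_name) +
    ggplot2::labs(x = "latent x", y = "latent y") +
    ggplot2::theme_minimal()
}

#' Smoothed SIG surface with dashed contour lines
#'
#' Tiles show the smoothed signal; dashed contours mark the configured
#' fractions of the surface maximum (the ROI cutoff among them); points are
#' the respondents' latent positions.
#'
#' @param sig A `sig_surface` (from [compute_sig()]).
#' @param embedding Optional `survey_embedding` to overlay respondents.
#' @return A ggplot object.
#' @export
plot_sig_contours <- function(sig, embedding = NULL) {
  g <- sig$grid
  ctr <- cell_centers(g)
  df <- data.frame(x = ctr[, 1L], y = ctr[, 2L], z = as.vector(sig$smoothed))
  levels <- sig$contour_values[sig$contour_values > 0]
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = z)) +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 name = "SIG") +
    ggplot2::labs(x = "latent x", y = "latent y") +
    ggplot2::theme_minimal()
  if (length(levels))
    pl <- pl + ggplot2::geom_contour(ggplot2::aes(z = z), breaks = levels,
                                     colour = "black", linetype = "dashed")
  if (!is.null(embedding))
    pl <- pl + ggplot2::geom_point(
      data = data.frame(embedding$coords), size = 0.4, colour = "black")
  pl
}

#' Pie-chart panels for an ROI profile
#'
#' One ROI-vs-cohort pie pair per significant demographic variable.
#'
#' @param profile An `roi_profile` (from [profile_roi()]).
#' @return A ggplot object (faceted), or `NULL` when nothing is significant.
#' @export
plot_roi_pies <- function(profile) {
  if (!length(profile$pies)) return(NULL)
  df <- do.call(rbind, lapply(profile$pies, function(p) rbind(
    data.frame(variable = p$variable, group = "cohort",
               category = p$categories, prop = as.numeric(p$cohort)),
    data.frame(variable = p$variable, group = profile$roi_id,
               category = p$categories, prop = as.numeric(p$roi)))))
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = prop, fill = category)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_grid(group ~ variable) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s: dose %.1f ± %.1f", profile$roi_id,
                                  profile$dose_mean, profile$dose_sd)) +
    ggplot2::theme_void()
}
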