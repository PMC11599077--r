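#' Pairwise Pearson correlation matrix of a scale's items
#'
#' @param dataset A reverse-scored `survey_dataset`.
#' @param scale_id Scale whose items to correlate.
#' @return Symmetric items x items correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(dataset, scale_id) {
  stopifnot(inherits(dataset, "survey_dataset"))
  s <- dataset$scales[[scale_id]]
  if (is.null(s)) stop("unknown scale '", scale_id, "'")
  if (length(s$item_ids) < 2L) stop("scale '", scale_id, "' has < 2 items")
  x <- dataset$responses[, s$item_ids, drop = FALSE]
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  stats::cor(x)
}

#' Ward agglomeration of items in correlation space
#'
#' Items are clustered on the dissimilarity d(i,j) = 1 - pcc(i,j) using
#' Ward's minimum-variance linkage (Lance-Williams recursion on squared
#' dissimilarities, i.e. `hclust` method `"ward.D2"`), and the merge tree is
#' cut at `k` clusters.
#'
#' @param corr Symmetric correlation matrix (items x items).
#' @param k Number of clusters, `2 <= k <= nrow(corr)`.
#' @return A `cluster_partition`: list with `k`, `assignment` (named integer
#'   vector, clusters numbered 1..k), and the `hclust` `tree`.
#' @export
ward_partition <- function(corr, k) {
  check_corr(corr)
  n <- nrow(corr)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k out of range [1, ", n, "]")
  tree <- stats::hclust(stats::as.dist(1 - corr), method = "ward.D2")
  assignment <- stats::cutree(tree, k = k)
  structure(list(k = k, assignment = assignment, tree = tree),
            class = "cluster_partition")
}

check_corr <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix not symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("correlation matrix diagonal != 1")
  if (any(abs(corr) > 1 + 1e-8)) stop("correlation entries outside [-1, 1]")
  invisible(TRUE)
}

# internal: item coordinates for the centroid silhouette.
# Items live in correlation space; to give cluster centers a meaning each
# item is represented either by its row of the dissimilarity matrix
# ("dissimilarity", default) or by a classical MDS embedding of d ("cmdscale").
item_coordinates <- function(corr, coords = c("dissimilarity", "cmdscale")) {
  coords <- match.arg(coords)
  d <- 1 - corr
  if (coords == "dissimilarity") return(d)
  n <- nrow(d)
  fit <- stats::cmdscale(stats::as.dist(d), k = min(n - 1L, 8L))
  rownames(fit) <- rownames(corr)
  fit
}

#' Centroid silhouette of an item partition
#'
#' For each item i, `a(i)` is the Euclidean distance to its own cluster's
#' centroid and `b(i)` the smallest distance to any other cluster's centroid;
#' the silhouette is `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, and the
#' cluster-wise score `sc` is the mean of `s(i)`. Items in singleton clusters
#' are assigned `s(i) = 0` so that fragmentation is not rewarded.
#'
#' @param assignment Named integer vector item -> cluster (1..k), or a
#'   `cluster_partition`.
#' @param item_coords Numeric matrix of item coordinates (one row per item,
#'   rows aligned with `assignment`).
#' @return List with `a`, `b`, `s` (per item) and `sc` (mean silhouette).
#' @export
centroid_silhouette <- function(assignment, item_coords) {
  if (inherits(assignment, "cluster_partition")) assignment <- assignment$assignment
  item_coords <- as.matrix(item_coords)
  stopifnot(nrow(item_coords) == length(assignment))
  ks <- sort(unique(assignment))
  if (length(ks) < 2L) stop("silhouette undefined for a single cluster")
  centroids <- do.call(rbind, lapply(ks, function(cl)
    colMeans(item_coords[assignment == cl, , drop = FALSE])))
  # distances from every item to every centroid
  d2 <- outer(rowSums(item_coords^2), rowSums(centroids^2), "+") -
    2 * item_coords %*% t(centroids)
  dmat <- sqrt(pmax(d2, 0))
  own_col <- match(assignment, ks)
  a <- dmat[cbind(seq_along(assignment), own_col)]
  bmat <- dmat
  bmat[cbind(seq_along(assignment), own_col)] <- Inf
  b <- apply(bmat, 1L, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  sizes <- tabulate(own_col, nbins = length(ks))
  s[sizes[own_col] == 1L] <- 0
  names(a) <- names(b) <- names(s) <- names(assignment)
  list(a = a, b = b, s = s, sc = mean(s))
}

# internal: within-cluster PCC statistics of a partition.
# Per cluster: mean / min / variance of the off-diagonal within-cluster
# pairs. Clusters with < 2 items contribute no pairs; a cluster with a single
# pair has variance 0.
cluster_pcc_stats <- function(corr, assignment) {
  ks <- sort(unique(assignment))
  per <- lapply(ks, function(cl) {
    items <- which(assignment == cl)
    if (length(items) < 2L)
      return(list(n_pairs = 0L, mean = NA_real_, min = NA_real_, var = 0))
    sub <- corr[items, items]
    vals <- sub[upper.tri(sub)]
    list(n_pairs = length(vals), mean = mean(vals), min = min(vals),
         var = if (length(vals) > 1L) stats::var(vals) else 0)
  })
  means <- vapply(per, `[[`, numeric(1), "mean")
  mins <- vapply(per, `[[`, numeric(1), "min")
  vars <- vapply(per, `[[`, numeric(1), "var")
  list(per_cluster = data.frame(cluster = ks,
                                n_items = as.integer(table(factor(assignment, levels = ks))),
                                pcc_mean = means, pcc_min = mins, pcc_var = vars),
       mean_min = if (all(is.na(means))) NA_real_ else min(means, na.rm = TRUE),
       pair_min = if (all(is.na(mins))) NA_real_ else min(mins, na.rm = TRUE),
       var_sum = sum(vars))
}

#' Select the number of factors for one scale
#'
#' Examines each candidate cluster count `k`, scoring the Ward partition by
#' the centroid silhouette `sc` and by within-cluster correlation statistics.
#' A `k` is admissible when `sc >= sc_min` and every cluster's within-cluster
#' PCC statistic (the mean of its pairwise correlations by default, the
#' minimum with `floor_stat = "min"`) reaches `pcc_floor`. Among admissible
#' `k` the one with the maximal silhouette is chosen (the cluster-wise score
#' being the max over k of the mean item silhouette); ties go first to the
#' smaller within-cluster PCC variance aggregated (summed) over clusters,
#' then to the smaller `k`. Splitting a genuine item block leaves the
#' sub-blocks' centroids nearly coincident and drags the silhouette down, so
#' the silhouette peaks at the planted structure, while the variance
#' criterion alone keeps rewarding fragmentation.
#'
#' @param corr Correlation matrix of one scale's items.
#' @param k_range Candidate cluster counts (default 2..8, truncated to the
#'   item count).
#' @param sc_min Minimum admissible silhouette (default 0.25, the customary
#'   "weak structure" cutoff).
#' @param pcc_floor Minimum admissible within-cluster PCC statistic.
#' @param floor_stat Apply the floor to the per-cluster `"mean"` (default) or
#'   `"min"` pairwise correlation.
#' @param coords Item-coordinate construction for the silhouette, see
#'   [centroid_silhouette()].
#' @param scale_id Optional label carried into the result.
#' @return A `factor_solution`: list with `scale_id`, `chosen_k` (`NA` when
#'   no admissible k exists), `assignment`, `tree`, and a per-k `quality`
#'   data frame (`k`, `sc`, `pcc_mean_min`, `pcc_pair_min`, `pcc_var_sum`,
#'   `admissible`).
#' @export
select_k <- function(corr, k_range = 2:8, sc_min = 0.25, pcc_floor = 0.5,
                     floor_stat = c("mean", "min"),
                     coords = c("dissimilarity", "cmdscale"),
                     scale_id = NULL) {
  check_corr(corr)
  floor_stat <- match.arg(floor_stat)
  n <- nrow(corr)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n]
  if (!length(k_range)) stop("no feasible k in k_range for ", n, " items")
  xy <- item_coordinates(corr, match.arg(coords))
  tree <- stats::hclust(stats::as.dist(1 - corr), method = "ward.D2")
  rows <- vector("list", length(k_range))
  assignments <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    assignment <- stats::cutree(tree, k = k)
    sil <- centroid_silhouette(assignment, xy)
    st <- cluster_pcc_stats(corr, assignment)
    floor_val <- if (floor_stat == "mean") st$mean_min else st$pair_min
    rows[[i]] <- data.frame(k = k, sc = sil$sc, pcc_mean_min = st$mean_min,
                            pcc_pair_min = st$pair_min, pcc_var_sum = st$var_sum,
                            admissible = isTRUE(sil$sc >= sc_min &&
                                                !is.na(floor_val) &&
                                                floor_val >= pcc_floor))
    assignments[[i]] <- assignment
  }
  quality <- do.call(rbind, rows)
  chosen_k <- NA_integer_; assignment <- NULL
  if (any(quality$admissible)) {
    adm <- quality[quality$admissible, ]
    best <- adm$k[order(-adm$sc, adm$pcc_var_sum, adm$k)][1L]
    chosen_k <- as.integer(best)
    assignment <- assignments[[match(best, k_range)]]
  }
  structure(
    list(scale_id = scale_id, chosen_k = chosen_k, assignment = assignment,
         tree = tree, quality = quality,
         params = list(k_range = k_range, sc_min = sc_min,
                       pcc_floor = pcc_floor, floor_stat = floor_stat)),
    class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("factor_solution", if (!is.null(x$scale_id)) paste0("[", x$scale_id, "]"),
      "chosen k =", x$chosen_k, "\n")
  print(x$quality, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract correlation-based factors for every scale
#'
#' Runs [pcc_matrix()] and [select_k()] per scale. Scales for which no
#' admissible k exists are reported with `chosen_k = NA` (the pipeline then
#' excludes their items downstream).
#'
#' @param dataset A reverse-scored `survey_dataset`.
#' @param sc_min Silhouette floor shared by all scales.
#' @param pcc_floor Named (by scale id) or unnamed numeric vector of
#'   within-cluster PCC floors, recycled if scalar.
#' @param k_range Candidate cluster counts.
#' @inheritParams select_k
#' @return Named list of `factor_solution` objects, one per scale.
#' @export
extract_factors <- function(dataset, sc_min = 0.25, pcc_floor = 0.5,
                            k_range = 2:8, floor_stat = c("mean", "min"),
                            coords = c("dissimilarity", "cmdscale")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  ids <- names(dataset$scales)
  floors <- if (!is.null(names(pcc_floor))) {
    miss <- setdiff(ids, names(pcc_floor))
    if (length(miss)) stop("pcc_floor missing for scale(s): ",
                           paste(miss, collapse = ", "))
    pcc_floor[ids]
  } else rep_len(pcc_floor, length(ids))
  out <- lapply(seq_along(ids), function(i)
    select_k(pcc_matrix(dataset, ids[i]), k_range = k_range, sc_min = sc_min,
             pcc_floor = floors[i], floor_stat = floor_stat, coords = coords,
             scale_id = ids[i]))
  names(out) <- ids
  out
}

#' Compute factor scores
#'
#' The score of a respondent on a factor aggregates that respondent's
#' (reverse-scored) responses over the factor's item cluster. The default
#' aggregator is the mean, which keeps factors on the common Likert scale
#' regardless of cluster size; `"sum"` is available as a literal alternative.
#' Factor identifiers follow the scale-prefix convention, e.g. `"C-c1"` for
#' the first cluster of a scale with prefix `"C"`.
#'
#' @param dataset A reverse-scored `survey_dataset`.
#' @param solutions Named list of `factor_solution`s (from
#'   [extract_factors()]); scales with `chosen_k = NA` are skipped.
#' @param aggregator `"mean"` (default) or `"sum"`.
#' @param labels Optional named character vector mapping factor ids to
#'   human-readable labels, stored as an attribute.
#' @return Numeric matrix respondents x factors with attribute
#'   `"factor_items"` (named list factor id -> item ids).
#' @export
compute_factor_scores <- function(dataset, solutions, aggregator = c("mean", "sum"),
                                  labels = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "mean") rowMeans else rowSums
  cols <- list(); items_map <- list()
  for (sid in names(solutions)) {
    sol <- solutions[[sid]]
    if (is.na(sol$chosen_k) || is.null(sol$assignment)) next
    prefix <- dataset$scales[[sid]]$prefix
    for (cl in sort(unique(sol$assignment))) {
      items <- names(sol$assignment)[sol$assignment == cl]
      fid <- paste0(prefix, "-c", cl)
      cols[[fid]] <- agg(dataset$responses[, items, drop = FALSE])
      items_map[[fid]] <- items
    }
  }
  if (!length(cols)) stop("no admissible factor solution in any scale")
  scores <- do.call(cbind, cols)
  rownames(scores) <- dataset$respondent_ids
  attr(scores, "factor_items") <- items_map
  if (!is.null(labels)) attr(scores, "factor_labels") <- labels
  scores
}
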