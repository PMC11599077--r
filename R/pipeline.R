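#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the method's
#' standard settings: silhouette floor 0.25, per-scale within-cluster PCC
#' floors, candidate k in 2..8, grid step 0.5, smoothing scale 1, ROI cutoff
#' at 34% of the surface maximum with contour levels at 0/17/34/51%,
#' correlation-screen cutoff 0.2, significance level 0.05, 70/30 split with
#' 10-fold cross-validation, and ten resampling seeds for the predictor
#' ranking.
#'
#' @param pcc_floor Named or scalar within-cluster PCC floor(s); the default
#'   applies 0.7/0.6/0.5/0.6 to scales named CoVaH, T-DiG, TRUST-Ph, TiPHA
#'   and 0.5 otherwise.
#' @param sc_min,k_range,floor_stat Factor-selection settings ([select_k()]).
#' @param aggregator Factor-score aggregator, `"mean"` or `"sum"`.
#' @param embedding_method,n_neighbors,min_dist,embed_seed Embedding
#'   settings ([embed_points()]).
#' @param grid_step,sigma,min_cell_members,cutoff_fraction,min_roi_members,contour_fractions
#'   Spatial-signal settings ([compute_sig()]).
#' @param screen_cutoff,alpha Profiling settings.
#' @param train_frac,cv_folds,split_seed,ranking_seeds Regression settings.
#' @param labels Optional named factor-label map (user-supplied annotation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(pcc_floor = c(CoVaH = 0.7, `T-DiG` = 0.6,
                                          `TRUST-Ph` = 0.5, TiPHA = 0.6),
                            sc_min = 0.25, k_range = 2:8,
                            floor_stat = "mean", aggregator = "mean",
                            embedding_method = "umap", n_neighbors = 15L,
                            min_dist = 0.1, embed_seed = 42L,
                            grid_step = 0.5, sigma = 1,
                            min_cell_members = 5L, cutoff_fraction = 0.34,
                            min_roi_members = 10L,
                            contour_fractions = c(0, 0.17, 0.34, 0.51),
                            screen_cutoff = 0.2, alpha = 0.05,
                            train_frac = 0.7, cv_folds = 10L,
                            split_seed = 1L, ranking_seeds = 1:10,
                            labels = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

# internal: per-scale floor lookup tolerant of unnamed scalar configs
floor_for_scales <- function(pcc_floor, scale_ids, default = 0.5) {
  if (is.null(names(pcc_floor))) return(rep_len(pcc_floor, length(scale_ids)))
  out <- pcc_floor[scale_ids]
  out[is.na(out)] <- default
  stats::setNames(as.numeric(out), scale_ids)
}

#' Run the full subgroup-discovery pipeline
#'
#' Executes every stage in order — ingestion/reverse scoring, cohort
#' summary, factor extraction, factor scoring, 2D embedding, spatial
#' information gain and ROI extraction, per-ROI profiling, and the
#' regression benchmark — and (optionally) writes each stage's tables plus a
#' run manifest under `output_dir`. Scales with no admissible cluster count
#' are excluded from scoring with a recorded warning, and the pipeline
#' continues. Given equal configuration (all seeds live in the config), two
#' runs produce identical outputs.
#'
#' @param input A `survey_dataset`, a `synthetic_config` (the dataset is
#'   generated first), or a file path plus `schema`.
#' @param config A [pipeline_config()].
#' @param schema A [survey_schema()], required when `input` is a path.
#' @param output_dir Optional directory for CSV/JSON outputs and the
#'   manifest.
#' @return A `pipeline_result` list with all stage objects and a `manifest`
#'   (files written, parameters, warnings, timestamp).
#' @export
run_pipeline <- function(input, config = pipeline_config(), schema = NULL,
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  truth <- NULL
  dataset <- if (inherits(input, "survey_dataset")) input
  else if (inherits(input, "synthetic_config")) {
    gen <- generate_dataset(input)
    truth <- gen$truth
    gen$dataset
  } else if (is.character(input)) {
    if (is.null(schema)) stop("loading from a file requires a schema")
    load_survey(input, schema)
  } else stop("unsupported input type")

  scored <- reverse_score(dataset)
  cohort <- summarize_cohort(scored)

  floors <- floor_for_scales(config$pcc_floor, names(dataset$scales))
  solutions <- extract_factors(scored, sc_min = config$sc_min,
                               pcc_floor = floors, k_range = config$k_range,
                               floor_stat = config$floor_stat)
  for (sid in names(solutions))
    if (is.na(solutions[[sid]]$chosen_k))
      note(paste0("scale '", sid, "': no admissible k; items excluded"))

  scores <- compute_factor_scores(scored, solutions,
                                  aggregator = config$aggregator,
                                  labels = config$labels)
  embedding <- embed_points(scores, method = config$embedding_method,
                            n_neighbors = config$n_neighbors,
                            min_dist = config$min_dist,
                            seed = config$embed_seed)
  sig <- compute_sig(embedding, scores, scored$dose,
                     step = config$grid_step, sigma = config$sigma,
                     min_cell_members = config$min_cell_members,
                     cutoff_fraction = config$cutoff_fraction,
                     min_roi_members = config$min_roi_members,
                     contour_fractions = config$contour_fractions)

  profiles <- list(); screens <- list(); disparities <- list()
  for (roi in sig$rois) {
    scr <- correlation_screen(roi, scores, scored$dose,
                              cutoff = config$screen_cutoff)
    dsp <- lapply(colnames(scored$demographics), function(v)
      chi_square_disparity(roi, scored$demographics, v, alpha = config$alpha))
    profiles[[roi$roi_id]] <- profile_roi(roi, scr, dsp, scored$demographics)
    screens[[roi$roi_id]] <- scr
    disparities[[roi$roi_id]] <- dsp
  }

  regression <- fit_suite(scores, scored$dose, split_seed = config$split_seed,
                          train_frac = config$train_frac,
                          cv_folds = config$cv_folds)
  ranking <- rank_predictors(scores, scored$dose, seeds = config$ranking_seeds,
                             train_frac = config$train_frac)

  result <- structure(
    list(dataset = scored, cohort = cohort, solutions = solutions,
         scores = scores, embedding = embedding, sig = sig,
         screens = screens, disparities = disparities, profiles = profiles,
         regression = regression, ranking = ranking, truth = truth,
         config = config, manifest = NULL),
    class = "pipeline_result")
  result$manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_respondents = length(dataset$respondent_ids),
    n_factors = ncol(scores), n_rois = length(sig$rois),
    seeds = list(embed = config$embed_seed, split = config$split_seed,
                 ranking = config$ranking_seeds),
    warnings = warnings_log, files = character())
  if (!is.null(output_dir)) result <- write_outputs(result, output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$cohort$n); cat(" factors:", ncol(x$scores),
                         "| ROIs:", length(x$sig$rois), "\n")
  invisible(x)
}

# internal: write all stage tables + manifest under output_dir; records the
# file list in the manifest. CSVs are written deterministically.
write_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put_csv <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
  }
  put_json <- function(obj, name) {
    path <- file.path(output_dir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }
  quality <- do.call(rbind, lapply(result$solutions, function(s)
    cbind(scale_id = s$scale_id, s$quality)))
  put_csv(quality, "factor_quality.csv")
  put_json(lapply(result$solutions, function(s)
    as.list(s$assignment)), "factor_partition.json")
  put_csv(data.frame(respondent_id = rownames(result$scores),
                     result$scores, check.names = FALSE), "factor_scores.csv")
  put_csv(data.frame(respondent_id = rownames(result$embedding$coords),
                     result$embedding$coords), "embedding.csv")
  put_json(unclass(result$sig$grid), "grid.json")
  put_csv(as.data.frame(result$sig$aggregated), "sig_aggregated.csv")
  put_csv(as.data.frame(result$sig$smoothed), "sig_smoothed.csv")
  roi_tab <- if (length(result$sig$rois)) do.call(rbind, lapply(result$sig$rois,
    function(r) data.frame(roi_id = r$roi_id, n = r$n, dose_mean = r$dose_mean,
                           dose_sd = r$dose_sd, peak_signal = r$peak_signal)))
  else data.frame(roi_id = character(), n = integer(), dose_mean = numeric(),
                  dose_sd = numeric(), peak_signal = numeric())
  put_csv(roi_tab, "roi_table.csv")
  membership <- do.call(rbind, c(list(
    data.frame(respondent_id = character(), roi_id = character())),
    lapply(result$sig$rois, function(r)
      data.frame(respondent_id = r$member_ids, roi_id = r$roi_id))))
  put_csv(membership, "roi_members.csv")
  if (length(result$screens))
    put_csv(do.call(rbind, result$screens), "roi_screen.csv")
  if (length(result$disparities)) {
    dt <- do.call(rbind, lapply(result$disparities, function(ds)
      do.call(rbind, lapply(ds, function(d)
        data.frame(roi_id = d$roi_id, variable = d$variable, chi2 = d$chi2,
                   df = d$df, p_value = d$p_value, stars = d$stars,
                   testable = d$testable)))))
    put_csv(dt, "roi_disparity.csv")
  }
  put_json(lapply(result$profiles, unclass), "roi_profiles.json")
  put_csv(as.data.frame(result$regression), "regression_report.csv")
  put_json(list(importance = result$ranking$importance,
                shapley = result$ranking$shapley,
                stability = result$ranking$stability),
           "predictor_ranking.json")
  put_json(cohort_json_obj(result$cohort), "cohort_summary.json")
  result$manifest$files <- files
  result$manifest$output_dir <- output_dir
  put_json(result$manifest, "manifest.json")
  result$manifest$files <- c(files, "manifest.json")
  result
}

cohort_json_obj <- function(cohort) unclass(cohort)

#' Render report figures from a pipeline result
#'
#' Produces the functional figure set from already computed outputs (no
#' recomputation): a PCC heatmap with cluster frames per scale, the
#' embedding scatter colored by dose, the smoothed SIG surface with dashed
#' contour lines at the configured fractions of the maximum, and per-ROI
#' pie-chart panels of the significant demographic variables.
#'
#' @param result A `pipeline_result`.
#' @param output_dir Directory for the PNG files.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(result, output_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  save <- function(plot, name, w = 7, h = 6) {
    path <- file.path(output_dir, name)
    ggplot2::ggsave(path, plot, width = w, height = h, dpi = 120)
    files <<- c(files, path)
  }
  for (sid in names(result$solutions)) {
    sol <- result$solutions[[sid]]
    if (is.na(sol$chosen_k)) next
    save(plot_pcc_heatmap(pcc_matrix(result$dataset, sid), sol),
         paste0("pcc_", gsub("[^A-Za-z0-9]", "_", sid), ".png"))
  }
  save(plot_embedding(result$embedding, result$dataset$dose), "embedding_dose.png")
  save(plot_sig_contours(result$sig), "sig_contours.png")
  for (pid in names(result$profiles)) {
    pr <- result$profiles[[pid]]
    if (length(pr$pies))
      save(plot_roi_pies(pr), paste0("pies_", pid, ".png"), w = 8, h = 5)
  }
  invisible(files)
}
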