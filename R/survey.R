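#' Construct a survey dataset
#'
#' Low-level constructor validating a respondent-by-item response matrix,
#' encoded doses, and demographics against a set of scale definitions. Most
#' users will call [load_survey()] (from a delimited file) or
#' [generate_dataset()] (synthetic) instead.
#'
#' @param responses Integer matrix, respondents x items, with column names
#'   covering every item declared in `scales` and row names giving respondent
#'   ids.
#' @param dose Integer vector in 0..5, one per respondent.
#' @param demographics Data frame of categorical variables, one row per
#'   respondent (may have zero columns).
#' @param scales List of [scale_definition()] objects (or a `survey_schema`).
#' @return A `survey_dataset` object.
#' @export
survey_dataset <- function(responses, dose, demographics = NULL, scales) {
  if (inherits(scales, "survey_schema")) scales <- scales$scales
  if (inherits(scales, "scale_definition")) scales <- list(scales)
  names(scales) <- vapply(scales, `[[`, character(1), "scale_id")
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (is.null(rownames(responses))) rownames(responses) <- as.character(seq_len(n))
  if (anyDuplicated(rownames(responses))) stop("duplicate respondent ids")
  all_items <- unlist(lapply(scales, `[[`, "item_ids"), use.names = FALSE)
  missing <- setdiff(all_items, colnames(responses))
  if (length(missing))
    stop("schema error: missing item columns: ", paste(missing, collapse = ", "))
  responses <- responses[, all_items, drop = FALSE]
  if (anyNA(responses)) stop("missing item responses are not allowed")
  for (s in scales) {
    block <- responses[, s$item_ids, drop = FALSE]
    if (any(block < s$likert_min | block > s$likert_max))
      stop("validation error: scale '", s$scale_id, "' has responses outside [",
           s$likert_min, ",", s$likert_max, "]")
  }
  dose <- as.integer(dose)
  if (length(dose) != n) stop("dose length != number of respondents")
  if (anyNA(dose) || any(dose < 0L | dose > 5L)) stop("dose must lie in 0..5")
  if (is.null(demographics)) demographics <- data.frame(row.names = rownames(responses))
  if (nrow(demographics) != n) stop("demographics rows != number of respondents")
  rownames(demographics) <- rownames(responses)
  structure(
    list(respondent_ids = rownames(responses),
         responses = responses, dose = stats::setNames(dose, rownames(responses)),
         demographics = demographics, scales = scales),
    class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("survey_dataset:", length(x$respondent_ids), "respondents,",
      ncol(x$responses), "items across", length(x$scales), "scales,",
      ncol(x$demographics), "demographic variables\n")
  cat("  mean dose:", round(mean(x$dose), 2), "\n")
  invisible(x)
}

#' Encode dose labels to integer counts
#'
#' Maps the questionnaire's dose categories to integers 0 through 5, with the
#' open-ended top category ("5 or more") capped at 5.
#'
#' @param raw_label Character (or numeric) vector of dose labels.
#' @param synonyms Named character vector of extra label -> canonical-label
#'   mappings (e.g. `c("5+" = "5 or more")`).
#' @return Integer vector in 0..5.
#' @export
#' @examples
#' encode_dose(c("0", "2", "5 or more"))
encode_dose <- function(raw_label, synonyms = c("5+" = "5 or more")) {
  lab <- trimws(as.character(raw_label))
  hit <- lab %in% names(synonyms)
  lab[hit] <- synonyms[lab[hit]]
  map <- c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L,
           "5" = 5L, "5 or more" = 5L)
  out <- unname(map[lab])
  if (anyNA(out))
    stop("encoding error: unrecognized dose label(s): ",
         paste(unique(lab[is.na(out)]), collapse = ", "))
  out
}

#' Load a survey from a delimited file
#'
#' Reads a CSV/TSV file with one row per respondent, validates it against the
#' schema, encodes the dose column, and drops (reporting them) any rows with
#' missing or out-of-range item responses — the analysis operates on complete
#' responses only, mirroring the typical survey-vendor quality filter.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema A [survey_schema()].
#' @param sep Field separator; guessed from the file extension by default.
#' @return A `survey_dataset`; rejected row indices (if any) are attached as
#'   attribute `"rejected"` and reported via a warning.
#' @export
load_survey <- function(path, schema, sep = NULL) {
  stopifnot(inherits(schema, "survey_schema"))
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  all_items <- unlist(lapply(schema$scales, `[[`, "item_ids"), use.names = FALSE)
  need <- c(all_items, schema$dose_column, schema$demographic_columns,
            schema$id_column)
  absent <- setdiff(need, colnames(df))
  if (length(absent))
    stop("schema error: file lacks column(s): ", paste(absent, collapse = ", "))
  ids <- if (is.null(schema$id_column)) as.character(seq_len(nrow(df)))
         else as.character(df[[schema$id_column]])
  if (anyDuplicated(ids))
    stop("validation error: duplicate respondent id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  resp <- as.matrix(df[, all_items, drop = FALSE])
  storage.mode(resp) <- "integer"
  ok <- !apply(resp, 1L, anyNA)
  for (s in schema$scales) {
    block <- resp[, s$item_ids, drop = FALSE]
    inr <- block >= s$likert_min & block <= s$likert_max
    inr[is.na(inr)] <- FALSE
    ok <- ok & apply(inr, 1L, all)
  }
  if (!any(ok)) stop("no complete, in-range rows in ", path)
  if (any(!ok))
    warning(sum(!ok), " row(s) rejected (missing or out-of-range item values): rows ",
            paste(utils::head(which(!ok), 20L), collapse = ", "))
  resp <- resp[ok, , drop = FALSE]
  rownames(resp) <- ids[ok]
  dose <- encode_dose(df[[schema$dose_column]][ok])
  demo <- df[ok, schema$demographic_columns, drop = FALSE]
  demo[] <- lapply(demo, as.character)
  out <- survey_dataset(resp, dose, demo, schema$scales)
  attr(out, "rejected") <- which(!ok)
  out
}

#' Reverse-score oppositely phrased items
#'
#' Reflects each declared reverse item onto the scale's common direction:
#' a response `v` becomes `likert_min + likert_max - v`. The map is an
#' involution — applying it twice restores the original dataset.
#'
#' @param dataset A `survey_dataset`.
#' @return The dataset with reverse items reflected.
#' @export
reverse_score <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  resp <- dataset$responses
  for (s in dataset$scales) {
    if (!length(s$reverse_items)) next
    resp[, s$reverse_items] <-
      s$likert_min + s$likert_max - resp[, s$reverse_items, drop = FALSE]
  }
  dataset$responses <- resp
  dataset
}

#' Summarize the cohort
#'
#' Computes the descriptives usually reported in a cohort table: dose-category
#' counts, mean dose, the ever-vaccinated percentage (dose >= 1), and
#' per-variable demographic frequency tables with one-decimal percentages.
#'
#' @param dataset A `survey_dataset`.
#' @return A `cohort_summary` object.
#' @export
summarize_cohort <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  n <- length(dataset$respondent_ids)
  if (n == 0L) stop("empty dataset")
  counts <- table(factor(dataset$dose, levels = 0:5))
  ds <- dose_summary(as.integer(counts))
  demo_freq <- lapply(dataset$demographics, function(v) {
    tab <- table(v)
    data.frame(category = names(tab), count = as.integer(tab),
               pct = round(100 * as.integer(tab) / n, 1L),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(
    list(n = n, dose_counts = stats::setNames(as.integer(counts), 0:5),
         dose_mean = ds$dose_mean, dose_sd = stats::sd(dataset$dose),
         ever_vaccinated_pct = ds$ever_vaccinated_pct,
         demographic_frequencies = demo_freq),
    class = "cohort_summary")
}

#' Dose descriptives from a count table
#'
#' Computes the mean dose and the ever-vaccinated percentage directly from a
#' table of dose-category counts (doses 0 through 5, top category capped at
#' 5), as printed in a cohort characteristics table.
#'
#' @param counts Integer vector of counts for doses 0,1,2,3,4,5 (in that
#'   order, or named by dose).
#' @return List with `n`, `dose_mean`, and `ever_vaccinated_pct` (in percent).
#' @export
#' @examples
#' dose_summary(c(447, 80, 248, 123, 65, 57)) # mean 1.5, ever-vaccinated 56.2%
dose_summary <- function(counts) {
  if (!is.null(names(counts))) counts <- counts[as.character(0:5)]
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 6L, all(counts >= 0), !anyNA(counts))
  n <- sum(counts)
  if (n == 0) stop("empty count table")
  list(n = n,
       dose_mean = sum((0:5) * counts) / n,
       ever_vaccinated_pct = 100 * (n - counts[1L]) / n)
}

#' @export
print.cohort_summary <- function(x, digits = 1L, ...) {
  cat(sprintf("Cohort (n = %d)\n", x$n))
  cat(sprintf("  Mean dose: %.1f (SD %.1f)\n", x$dose_mean, x$dose_sd))
  cat(sprintf("  Ever vaccinated: %.1f%%\n", x$ever_vaccinated_pct))
  cat("  Doses received, N (%):\n")
  for (d in 0:5)
    cat(sprintf("    %-9s %5d (%.1f)\n", if (d == 5L) "5 or more" else d,
                x$dose_counts[[as.character(d)]],
                100 * x$dose_counts[[as.character(d)]] / x$n))
  for (v in names(x$demographic_frequencies)) {
    cat(" ", v, "\n")
    f <- x$demographic_frequencies[[v]]
    for (i in seq_len(nrow(f)))
      cat(sprintf("    %-28s %5d (%.1f)\n", f$category[i], f$count[i], f$pct[i]))
  }
  invisible(x)
}

#' Serialize a cohort summary to JSON
#'
#' @param x A `cohort_summary`.
#' @param path Optional file path; when given, writes and returns invisibly.
#' @return JSON string (or the path, invisibly).
#' @export
cohort_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cohort_summary"))
  obj <- unclass(x)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
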