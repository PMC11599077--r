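#' Define a questionnaire scale
#'
#' A scale is a named block of Likert items sharing one response range, e.g.
#' a COVID-19 vaccine-hesitancy scale scored 1 ("strongly disagree") to
#' 5 ("strongly agree"), or a trust-in-public-health-authorities scale scored
#' 1 to 4. Items phrased against the scale's common direction are declared in
#' `reverse_items` and reflected by [reverse_score()] before any correlation
#' analysis.
#'
#' @param scale_id Character scalar naming the scale.
#' @param item_ids Character vector of item (column) identifiers; non-empty,
#'   unique.
#' @param likert_min,likert_max Integer response bounds (`likert_min <
#'   likert_max`).
#' @param reverse_items Character vector, subset of `item_ids`, of
#'   oppositely-phrased items.
#' @param prefix Short prefix used to build factor identifiers such as
#'   `"C-c1"`; defaults to the first character of `scale_id`.
#' @return A `scale_definition` object.
#' @export
#' @examples
#' scale_definition("CoVaH", paste0("cv", 1:8), 1, 5, reverse_items = "cv3")
scale_definition <- function(scale_id, item_ids, likert_min = 1L,
                             likert_max = 5L, reverse_items = character(),
                             prefix = NULL) {
  stopifnot(is.character(scale_id), length(scale_id) == 1L, nzchar(scale_id))
  item_ids <- as.character(item_ids)
  if (length(item_ids) == 0L) stop("scale '", scale_id, "': item_ids is empty")
  if (anyDuplicated(item_ids))
    stop("scale '", scale_id, "': duplicated item ids")
  likert_min <- as.integer(likert_min); likert_max <- as.integer(likert_max)
  if (!(likert_min < likert_max))
    stop("scale '", scale_id, "': likert_min must be < likert_max")
  reverse_items <- as.character(reverse_items)
  bad <- setdiff(reverse_items, item_ids)
  if (length(bad))
    stop("scale '", scale_id, "': reverse_items not in item_ids: ",
         paste(bad, collapse = ", "))
  if (is.null(prefix)) prefix <- substr(scale_id, 1L, 1L)
  structure(
    list(scale_id = scale_id, item_ids = item_ids,
         likert_min = likert_min, likert_max = likert_max,
         reverse_items = reverse_items, prefix = prefix),
    class = "scale_definition")
}

#' Assemble a survey schema
#'
#' Bundles the scale definitions with the names of the dose and demographic
#' columns, for use by [load_survey()]. Item identifiers must be unique
#' across scales.
#'
#' @param scales List of [scale_definition()] objects.
#' @param dose_column Name of the column holding the dose outcome.
#' @param demographic_columns Character vector of demographic column names.
#' @param id_column Optional name of a respondent-id column; when `NULL`,
#'   row numbers are used.
#' @return A `survey_schema` object.
#' @export
survey_schema <- function(scales, dose_column = "dose",
                          demographic_columns = character(),
                          id_column = NULL) {
  if (inherits(scales, "scale_definition")) scales <- list(scales)
  stopifnot(length(scales) >= 1L,
            all(vapply(scales, inherits, logical(1), "scale_definition")))
  names(scales) <- vapply(scales, `[[`, character(1), "scale_id")
  all_items <- unlist(lapply(scales, `[[`, "item_ids"), use.names = FALSE)
  if (anyDuplicated(all_items))
    stop("item ids duplicated across scales: ",
         paste(unique(all_items[duplicated(all_items)]), collapse = ", "))
  if (anyDuplicated(names(scales))) stop("duplicated scale ids")
  structure(
    list(scales = scales, dose_column = dose_column,
         demographic_columns = as.character(demographic_columns),
         id_column = id_column),
    class = "survey_schema")
}

#' @export
print.survey_schema <- function(x, ...) {
  cat("survey_schema:", length(x$scales), "scales,",
      sum(vapply(x$scales, function(s) length(s$item_ids), integer(1))),
      "items\n")
  for (s in x$scales)
    cat(sprintf("  %-10s %3d items, range %d-%d, %d reverse\n", s$scale_id,
                length(s$item_ids), s$likert_min, s$likert_max,
                length(s$reverse_items)))
  cat("  dose column:", x$dose_column, "\n")
  if (length(x$demographic_columns))
    cat("  demographics:", paste(x$demographic_columns, collapse = ", "), "\n")
  invisible(x)
}

# internal: scale definition owning an item id
scale_of_item <- function(scales, item) {
  for (s in scales) if (item %in% s$item_ids) return(s)
  stop("item '", item, "' not declared in any scale")
}
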