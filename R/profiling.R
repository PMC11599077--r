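#' Factor-dose correlation screen within an ROI
#'
#' For each factor, computes the Pearson correlation between the factor score
#' and the dose over the ROI's members, flagging factors with
#' `|pcc| >= cutoff` (default 0.2, the customary "at least weak correlation"
#' threshold). Factors that are constant within the ROI (or a constant dose)
#' are reported as not computable and never flagged.
#'
#' @param roi A `roi_subgroup` (or a character vector of member ids).
#' @param scores Factor-score matrix (all respondents).
#' @param dose Named integer dose vector (all respondents).
#' @param cutoff Absolute-correlation flag threshold.
#' @return Data frame with columns `roi_id`, `factor_id`, `pcc`, `flagged`,
#'   `computable`.
#' @export
correlation_screen <- function(roi, scores, dose, cutoff = 0.2) {
  members <- if (inherits(roi, "roi_subgroup")) roi$member_ids else as.character(roi)
  roi_id <- if (inherits(roi, "roi_subgroup")) roi$roi_id else NA_character_
  if (length(members) < 3L) stop("ROI has fewer than 3 members")
  s <- scores[members, , drop = FALSE]
  d <- dose[members]
  const_dose <- stats::sd(d) == 0
  res <- lapply(colnames(s), function(f) {
    computable <- !const_dose && stats::sd(s[, f]) > 0
    pcc <- if (computable) stats::cor(s[, f], d) else NA_real_
    data.frame(roi_id = roi_id, factor_id = f, pcc = pcc,
               flagged = isTRUE(abs(pcc) >= cutoff), computable = computable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# internal: pool categories with expected count < min_expected into "other".
# If the pooled bucket itself stays below the floor, it absorbs the
# smallest-expectation remaining category, repeatedly. Returns NULL when
# fewer than 2 categories survive.
pool_categories <- function(observed, expected, min_expected = 5) {
  stopifnot(length(observed) == length(expected))
  small <- expected < min_expected
  if (any(small)) {
    o_other <- sum(observed[small]); e_other <- sum(expected[small])
    observed <- observed[!small]; expected <- expected[!small]
    while (e_other < min_expected && length(expected) > 1L) {
      j <- which.min(expected)
      o_other <- o_other + observed[j]; e_other <- e_other + expected[j]
      observed <- observed[-j]; expected <- expected[-j]
    }
    if (e_other < min_expected) return(NULL)
    observed <- c(observed, other = unname(o_other))
    expected <- c(expected, other = unname(e_other))
  }
  if (length(observed) < 2L) return(NULL)
  list(observed = observed, expected = expected)
}

#' Chi-square demographic disparity test for an ROI
#'
#' Tests whether the ROI's distribution over one categorical variable departs
#' from the whole cohort's. The null frequencies come from the cohort
#' (including the ROI members); the expected count of category i is the
#' cohort proportion times the ROI size. Categories with expected count
#' below `min_expected` are pooled into an "other" bucket (the chi-square
#' approximation's validity condition), the statistic is
#' `sum_i (O_i - E_i)^2 / E_i`, and the p-value uses the chi-square
#' distribution with `k - 1` degrees of freedom over the `k` post-pooling
#' categories.
#'
#' @param roi A `roi_subgroup` or character vector of member ids.
#' @param demographics Cohort demographics data frame (rownames = ids).
#' @param variable Column of `demographics` to test.
#' @param alpha Significance level (default 0.05).
#' @param min_expected Pooling floor for expected counts (default 5).
#' @return A `disparity_result`: list with `roi_id`, `variable`,
#'   `categories`, `observed`, `expected`, `chi2`, `df`, `p_value`,
#'   `significant`, `testable`, and `stars` (`"-"`, `"*"`, `"**"`, `"***"`
#'   at p >= 0.05, < 0.05, < 0.01, < 0.001).
#' @export
chi_square_disparity <- function(roi, demographics, variable, alpha = 0.05,
                                 min_expected = 5) {
  members <- if (inherits(roi, "roi_subgroup")) roi$member_ids else as.character(roi)
  roi_id <- if (inherits(roi, "roi_subgroup")) roi$roi_id else NA_character_
  if (!variable %in% colnames(demographics))
    stop("unknown demographic variable '", variable, "'")
  cohort <- as.character(demographics[[variable]])
  lev <- sort(unique(cohort))
  if (length(lev) < 2L)
    stop("variable '", variable, "' has fewer than 2 categories in the cohort")
  p0 <- as.numeric(table(factor(cohort, levels = lev))) / length(cohort)
  obs <- as.numeric(table(factor(demographics[members, variable], levels = lev)))
  names(obs) <- lev
  expected <- stats::setNames(p0 * length(members), lev)
  pooled <- pool_categories(obs, expected, min_expected)
  base <- list(roi_id = roi_id, variable = variable, n = length(members))
  if (is.null(pooled)) {
    out <- c(base, list(categories = lev, observed = obs, expected = expected,
                        chi2 = NA_real_, df = NA_integer_, p_value = NA_real_,
                        significant = FALSE, testable = FALSE, stars = "-"))
    return(structure(out, class = "disparity_result"))
  }
  chi2 <- sum((pooled$observed - pooled$expected)^2 / pooled$expected)
  df <- length(pooled$observed) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  out <- c(base, list(categories = names(pooled$observed),
                      observed = pooled$observed, expected = pooled$expected,
                      chi2 = chi2, df = df, p_value = p,
                      significant = p < alpha, testable = TRUE,
                      stars = significance_stars(p)))
  structure(out, class = "disparity_result")
}

# internal: map a p-value to the conventional star annotation
significance_stars <- function(p) {
  if (is.na(p)) "-" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "-"
}

#' @export
print.disparity_result <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("%s / %s: untestable (fewer than 2 adequate categories)\n",
                x$roi_id, x$variable))
  } else {
    cat(sprintf("%s / %s: chi2 = %.3f, df = %d, p = %.4g %s\n", x$roi_id,
                x$variable, x$chi2, x$df, x$p_value, x$stars))
  }
  invisible(x)
}

#' Profile an ROI subgroup
#'
#' Bundles an ROI's headline statistics: dose mean +/- SD, the factors that
#' pass the correlation screen, and the demographic variables with a
#' significant disparity, each carrying ROI-vs-cohort category proportions
#' (pie-chart data) and significance stars.
#'
#' @param roi A `roi_subgroup`.
#' @param screen Output of [correlation_screen()] for this ROI.
#' @param disparities List of `disparity_result`s for this ROI.
#' @param demographics Cohort demographics data frame.
#' @return An `roi_profile` list.
#' @export
profile_roi <- function(roi, screen, disparities, demographics) {
  stopifnot(inherits(roi, "roi_subgroup"))
  flagged <- screen[screen$flagged %in% TRUE, , drop = FALSE]
  sig <- Filter(function(d) isTRUE(d$significant), disparities)
  pies <- lapply(sig, function(d) {
    v <- d$variable
    lev <- sort(unique(as.character(demographics[[v]])))
    cohort_p <- as.numeric(table(factor(demographics[[v]], levels = lev))) /
      nrow(demographics)
    roi_p <- as.numeric(table(factor(demographics[roi$member_ids, v],
                                     levels = lev))) / roi$n
    list(variable = v, categories = lev,
         cohort = stats::setNames(cohort_p, lev),
         roi = stats::setNames(roi_p, lev),
         p_value = d$p_value, stars = d$stars)
  })
  names(pies) <- vapply(sig, `[[`, character(1), "variable")
  structure(
    list(roi_id = roi$roi_id, n = roi$n,
         dose_mean = roi$dose_mean, dose_sd = roi$dose_sd,
         flagged_factors = flagged[, c("factor_id", "pcc")],
         significant_variables = vapply(sig, `[[`, character(1), "variable"),
         pies = pies),
    class = "roi_profile")
}

#' @export
print.roi_profile <- function(x, ...) {
  cat(sprintf("%s (n = %d): dose %.1f +/- %.1f\n", x$roi_id, x$n,
              x$dose_mean, x$dose_sd))
  if (nrow(x$flagged_factors)) {
    cat("  correlated factors:\n")
    for (i in seq_len(nrow(x$flagged_factors)))
      cat(sprintf("    %-8s pcc = %+.2f\n", x$flagged_factors$factor_id[i],
                  x$flagged_factors$pcc[i]))
  } else cat("  no factor passed the correlation screen\n")
  if (length(x$significant_variables))
    cat("  significant demographics:",
        paste(x$significant_variables, collapse = ", "), "\n")
  else cat("  no significant demographic disparity\n")
  invisible(x)
}
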