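# Correlation screen and chi-square disparity profiling.

fake_roi <- function(ids, dose) {
  structure(list(roi_id = "ROI-1", member_ids = ids, n = length(ids),
                 dose_mean = mean(dose[ids]), dose_sd = stats::sd(dose[ids]),
                 cells = cbind(ix = 1L, iy = 1L), peak_signal = 1),
            class = "roi_subgroup")
}

test_that("correlation screen flags at the absolute cutoff", {
  set.seed(12)
  n <- 60
  ids <- paste0("r", 1:n)
  dose <- stats::setNames(sample(0:5, n, TRUE), ids)
  f_strong <- -as.numeric(scale(dose)) # exactly linear in dose: pcc = -1
  f_zero <- stats::rnorm(n)
  f_const <- rep(2, n)
  scores <- cbind(strong = f_strong, noise = f_zero, flat = f_const)
  rownames(scores) <- ids
  roi <- fake_roi(ids, dose)
  scr <- correlation_screen(roi, scores, dose, cutoff = 0.2)
  expect_equal(scr$pcc[scr$factor_id == "strong"], -1)
  expect_true(scr$flagged[scr$factor_id == "strong"])
  expect_false(scr$computable[scr$factor_id == "flat"])
  expect_false(scr$flagged[scr$factor_id == "flat"])
  # flagging tracks the absolute cutoff on every computable factor
  comp <- scr$computable
  expect_identical(unname(abs(scr$pcc[comp]) >= 0.2), scr$flagged[comp])
})

test_that("constant dose within an ROI makes all factors non-computable", {
  ids <- paste0("r", 1:10)
  dose <- stats::setNames(rep(3L, 10), ids)
  scores <- matrix(stats::rnorm(20), 10, 2,
                   dimnames = list(ids, c("f1", "f2")))
  scr <- correlation_screen(ids, scores, dose)
  expect_false(any(scr$computable))
  expect_false(any(scr$flagged))
  expect_error(correlation_screen(ids[1:2], scores, dose), "fewer than 3")
})

test_that("chi-square matches the hand-evaluated worked example", {
  # ROI n = 40, observed (30, 10), cohort proportions (0.5, 0.5)
  demo <- data.frame(g = rep(c("a", "b"), each = 500),
                     row.names = sprintf("p%04d", 1:1000))
  roi_ids <- c(sprintf("p%04d", 1:30), sprintf("p%04d", 501:510))
  d <- chi_square_disparity(roi_ids, demo, "g")
  expect_equal(d$chi2, 10)
  expect_identical(d$df, 1L)
  expect_equal(d$p_value, stats::pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(d$p_value, 0.00157, tolerance = 1e-2)
  expect_true(d$significant)
  expect_identical(d$stars, "**")
})

test_that("observed equal to expected gives chi2 = 0 and p = 1", {
  demo <- data.frame(g = rep(c("a", "b"), each = 500),
                     row.names = sprintf("p%04d", 1:1000))
  roi_ids <- c(sprintf("p%04d", 1:20), sprintf("p%04d", 501:520))
  d <- chi_square_disparity(roi_ids, demo, "g")
  expect_equal(d$chi2, 0)
  expect_equal(d$p_value, 1)
  expect_false(d$significant)
})

test_that("chi-square agrees with the textbook oracle on random configs", {
  set.seed(55)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    p <- as.numeric(stats::rmultinom(1, 200, rep(1, k))) + 10
    p <- p / sum(p)
    n_cohort <- 2000L
    cohort <- sample(letters[1:k], n_cohort, TRUE, prob = p)
    demo <- data.frame(g = cohort, row.names = sprintf("p%05d", 1:n_cohort))
    m <- sample(60:150, 1)
    roi_ids <- sample(rownames(demo), m)
    d <- chi_square_disparity(roi_ids, demo, "g")
    # oracle: formula + distribution tail on the same pooled categories
    p0 <- table(factor(cohort, levels = sort(unique(cohort)))) / n_cohort
    obs <- table(factor(demo[roi_ids, "g"], levels = names(p0)))
    exp_counts <- as.numeric(p0) * m
    keep <- exp_counts >= 5
    o <- c(as.numeric(obs)[keep], sum(as.numeric(obs)[!keep]))
    e <- c(exp_counts[keep], sum(exp_counts[!keep]))
    if (sum(!keep) == 0) { o <- as.numeric(obs); e <- exp_counts }
    if (length(o) >= 2 && all(e >= 5)) {
      chi2 <- sum((o - e)^2 / e)
      expect_equal(d$chi2, chi2, tolerance = 1e-10)
      expect_equal(d$p_value,
                   stats::pchisq(chi2, length(o) - 1, lower.tail = FALSE),
                   tolerance = 1e-10)
      # cross-check against the stock goodness-of-fit test
      suppressWarnings(
        expect_equal(d$p_value,
                     stats::chisq.test(o, p = e / sum(e))$p.value,
                     tolerance = 1e-10))
    }
  }
})

test_that("pooling leaves no expected count under the floor", {
  set.seed(9)
  # 6-category variable with 3 rare categories in a small ROI
  p <- c(0.4, 0.3, 0.2, 0.04, 0.03, 0.03)
  cohort <- sample(letters[1:6], 3000, TRUE, prob = p)
  demo <- data.frame(g = cohort, row.names = sprintf("p%05d", 1:3000))
  roi_ids <- sample(rownames(demo), 50)
  d <- chi_square_disparity(roi_ids, demo, "g")
  expect_true(d$testable)
  expect_true(all(d$expected >= 5))
  expect_true("other" %in% d$categories)
  expect_identical(d$df, length(d$observed) - 1L)
  expect_gte(d$df, 1L)
  expect_equal(sum(d$observed), 50)
  expect_equal(sum(d$expected), 50, tolerance = 1e-9)
})

test_that("variables that cannot support a test are marked untestable", {
  demo <- data.frame(g = c(rep("a", 990), rep("b", 10)),
                     row.names = sprintf("p%04d", 1:1000))
  d <- chi_square_disparity(sprintf("p%04d", 1:20), demo, "g")
  expect_false(d$testable)
  expect_true(is.na(d$chi2))
  expect_identical(d$stars, "-")
})

test_that("type-I rate under the cohort null is near nominal", {
  set.seed(202)
  n <- 2000
  demo <- data.frame(v = sample(c("a", "b", "c", "d"), n, TRUE,
                                prob = c(0.4, 0.3, 0.2, 0.1)),
                     row.names = sprintf("r%04d", 1:n))
  rej <- mean(replicate(1000, {
    roi <- sample(rownames(demo), 80)
    isTRUE(chi_square_disparity(roi, demo, "v")$significant)
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("ROI profiles bundle screen hits, disparities and pie data", {
  set.seed(21)
  n <- 1000
  ids <- sprintf("r%04d", 1:n)
  demo <- data.frame(g = sample(c("a", "b"), n, TRUE),
                     h = sample(c("x", "y", "z"), n, TRUE),
                     row.names = ids)
  dose <- stats::setNames(sample(0:5, n, TRUE), ids)
  scores <- matrix(stats::rnorm(2 * n), n, 2, dimnames = list(ids, c("f1", "f2")))
  # an ROI enriched for category "a" whose f1 tracks dose
  roi_ids <- c(sample(ids[demo$g == "a"], 70), sample(ids[demo$g == "b"], 10))
  scores[roi_ids, "f1"] <- as.numeric(scale(dose[roi_ids])) +
    stats::rnorm(80, sd = 0.5)
  roi <- fake_roi(roi_ids, dose)
  scr <- correlation_screen(roi, scores, dose)
  dsp <- lapply(c("g", "h"), function(v) chi_square_disparity(roi, demo, v))
  pr <- profile_roi(roi, scr, dsp, demo)
  expect_true("f1" %in% pr$flagged_factors$factor_id)
  expect_true("g" %in% pr$significant_variables)
  for (pie in pr$pies) {
    expect_equal(sum(pie$cohort), 1, tolerance = 1e-9)
    expect_equal(sum(pie$roi), 1, tolerance = 1e-9)
  }
  # an ROI drawn at random has (usually) nothing flagged; empty lists allowed
  roi2 <- fake_roi(sample(ids, 60), dose)
  pr2 <- profile_roi(roi2, correlation_screen(roi2, scores, dose),
                     list(), demo)
  expect_identical(length(pr2$pies), 0L)
})
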