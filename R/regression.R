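#' Regression evaluation metrics
#'
#' The six metrics conventionally reported for dose regression benchmarks:
#' coefficient of determination (R^2, relative to the test-set mean), MAE,
#' MSE, RMSE, RMSLE, and MAPE. RMSLE clips predictions at zero before
#' `log1p` (the logarithmic error is undefined for negative predictions).
#' MAPE is computed over observations with dose >= 1 only — the percentage
#' error is undefined at dose 0, which is a large share of any hesitant
#' cohort; this convention is documented prominently because it affects
#' comparability across reports. With `mape_symmetric = TRUE` the symmetric
#' variant `mean(2|o - p| / (|o| + |p|))` over all observations is used
#' instead.
#'
#' @param obs Observed numeric outcomes.
#' @param pred Predictions, same length.
#' @param mape_symmetric Use symmetric MAPE over all observations.
#' @return Named list: `r2`, `mae`, `mse`, `rmse`, `rmsle`, `mape`.
#' @export
#' @examples
#' reg_metrics(c(0, 2, 4), c(0.5, 2, 3.5))
reg_metrics <- function(obs, pred, mape_symmetric = FALSE) {
  stopifnot(length(obs) == length(pred), length(obs) > 1L)
  err <- obs - pred
  mse <- mean(err^2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("degenerate outcome: constant observed values")
  mape <- if (mape_symmetric) {
    denom <- (abs(obs) + abs(pred))
    mean(ifelse(denom > 0, 2 * abs(err) / denom, 0))
  } else {
    pos <- obs >= 1
    if (any(pos)) mean(abs(err[pos] / obs[pos])) else NA_real_
  }
  list(r2 = 1 - sum(err^2) / sst,
       mae = mean(abs(err)),
       mse = mse,
       rmse = sqrt(mse),
       rmsle = sqrt(mean((log1p(pmax(pred, 0)) - log1p(obs))^2)),
       mape = mape)
}

# internal: model registry. Each entry is fit(x_train, y_train, seed) ->
# object with a predict(newx) closure. Tunable settings (glmnet lambda,
# rpart cp) are chosen by 10-fold cross-validation on the training split.
suite_models <- function(cv_folds = 10L) {
  glmnet_model <- function(alpha) function(x, y, seed) {
    fit <- withr::with_seed(seed,
      glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = cv_folds))
    list(predict = function(newx)
      as.numeric(stats::predict(fit, newx = newx, s = "lambda.min")))
  }
  list(
    dummy = function(x, y, seed) {
      mu <- mean(y)
      list(predict = function(newx) rep(mu, nrow(newx)))
    },
    linear = function(x, y, seed) {
      df <- data.frame(y = y, x)
      fit <- stats::lm(y ~ ., data = df)
      list(predict = function(newx)
        as.numeric(stats::predict(fit, newdata = data.frame(newx))))
    },
    ridge = glmnet_model(0),
    lasso = glmnet_model(1),
    elastic_net = glmnet_model(0.5),
    huber = function(x, y, seed) {
      fit <- MASS::rlm(x = cbind(1, x), y = y, maxit = 100)
      list(predict = function(newx) as.numeric(cbind(1, newx) %*% fit$coefficients))
    },
    decision_tree = function(x, y, seed) {
      df <- data.frame(y = y, x)
      fit <- withr::with_seed(seed,
        rpart::rpart(y ~ ., data = df,
                     control = rpart::rpart.control(xval = cv_folds, cp = 0.001)))
      cp <- fit$cptable[which.min(fit$cptable[, "xerror"]), "CP"]
      fit <- rpart::prune(fit, cp = cp)
      list(predict = function(newx)
        as.numeric(stats::predict(fit, newdata = data.frame(newx))))
    },
    knn = function(x, y, seed) {
      list(predict = function(newx)
        FNN::knn.reg(train = x, test = newx, y = y, k = 5L)$pred)
    },
    random_forest = function(x, y, seed) {
      # dose is an ordinal count treated as numeric by design; silence the
      # forest's few-unique-values advisory
      fit <- withr::with_seed(seed, suppressWarnings(
        randomForest::randomForest(x = x, y = y, ntree = 500L)))
      list(predict = function(newx) as.numeric(stats::predict(fit, newx)),
           fit = fit)
    },
    extra_trees = function(x, y, seed) {
      df <- data.frame(y = y, x)
      fit <- ranger::ranger(y ~ ., data = df, num.trees = 500L,
                            splitrule = "extratrees", seed = seed)
      list(predict = function(newx)
        stats::predict(fit, data = data.frame(newx))$predictions)
    },
    xgboost = function(x, y, seed) {
      fit <- withr::with_seed(seed,
        xgboost::xgboost(x, y, nrounds = 100L, max_depth = 3L,
                         learning_rate = 0.1, nthreads = 1L))
      list(predict = function(newx) as.numeric(stats::predict(fit, newx)))
    })
}

#' Benchmark a suite of dose-regression models
#'
#' Splits the respondents 70/30 into training and test sets, fits each model
#' of the suite on the training split (10-fold cross-validation is used for
#' tunable settings such as the penalized models' lambda and the tree's
#' pruning), and reports the six metrics of [reg_metrics()] on the held-out
#' test set, sorted by R^2. A mean-prediction dummy baseline is always
#' included. Models that fail to fit are skipped with a warning.
#'
#' @param scores Factor-score matrix (respondents x factors).
#' @param dose Integer dose vector aligned with `scores` rows.
#' @param split_seed Seed controlling the train/test split and any model
#'   randomness.
#' @param train_frac Training fraction (default 0.7).
#' @param models Character vector of model names to run (default: the whole
#'   registry).
#' @param cv_folds Cross-validation folds for tunable settings (default 10).
#' @return A `regression_report` data frame (`model`, `r2`, `mae`, `mse`,
#'   `rmse`, `rmsle`, `mape`), sorted by decreasing `r2`, with the split
#'   sizes and seed as attributes.
#' @export
fit_suite <- function(scores, dose, split_seed = 1L, train_frac = 0.7,
                      models = NULL, cv_folds = 10L) {
  x <- as.matrix(scores)
  y <- as.numeric(dose)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 50L) stop("need at least 50 respondents for the benchmark")
  if (stats::sd(y) == 0) stop("degenerate dose: constant outcome")
  registry <- suite_models(cv_folds = cv_folds)
  if (is.null(models)) models <- names(registry)
  unknown <- setdiff(models, names(registry))
  if (length(unknown)) stop("unknown model(s): ", paste(unknown, collapse = ", "))
  models <- union(models, "dummy") # the baseline is always reported

  n <- nrow(x)
  idx_train <- withr::with_seed(split_seed,
                                sample.int(n, size = round(train_frac * n)))
  x_tr <- x[idx_train, , drop = FALSE]; y_tr <- y[idx_train]
  x_te <- x[-idx_train, , drop = FALSE]; y_te <- y[-idx_train]

  rows <- list()
  for (m in models) {
    res <- tryCatch({
      fitted <- registry[[m]](x_tr, y_tr, seed = split_seed)
      pred <- fitted$predict(x_te)
      c(list(model = m), reg_metrics(y_te, pred))
    }, error = function(e) {
      warning("model '", m, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[m]] <- as.data.frame(res, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  report <- report[order(-report$r2), ]
  rownames(report) <- NULL
  attr(report, "split") <- list(n_train = length(y_tr), n_test = length(y_te),
                                train_frac = train_frac, cv_folds = cv_folds,
                                seed = split_seed)
  class(report) <- c("regression_report", "data.frame")
  report
}

#' @export
print.regression_report <- function(x, digits = 3L, ...) {
  sp <- attr(x, "split")
  cat(sprintf("regression_report: %d train / %d test (seed %d)\n",
              sp$n_train, sp$n_test, sp$seed))
  print.data.frame(x, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Monte-Carlo Shapley values for a prediction function
#'
#' Permutation-sampling estimator of Shapley feature attributions: for each
#' explained row and feature, the marginal effect of revealing that feature
#' is averaged over random permutations of the feature set, with unrevealed
#' features imputed from rows of the background data. All model evaluations
#' are batched into a single predict call.
#'
#' @param predict_fun Function taking a numeric matrix and returning numeric
#'   predictions.
#' @param x_background Background data matrix (the training set, typically).
#' @param x_explain Rows to explain.
#' @param nsim Monte-Carlo draws per (row, feature) pair (default 30).
#' @param seed RNG seed.
#' @return Matrix `nrow(x_explain)` x `ncol` of attributions.
#' @export
shapley_values <- function(predict_fun, x_background, x_explain, nsim = 30L,
                           seed = 1L) {
  xb <- as.matrix(x_background); xe <- as.matrix(x_explain)
  p <- ncol(xb)
  stopifnot(ncol(xe) == p, nsim >= 1L)
  withr::with_seed(seed, {
    n_pairs <- nrow(xe) * p * nsim
    plus <- matrix(0, n_pairs, p); minus <- matrix(0, n_pairs, p)
    row <- 0L
    for (i in seq_len(nrow(xe))) {
      for (j in seq_len(p)) {
        for (s in seq_len(nsim)) {
          z <- xb[sample.int(nrow(xb), 1L), ]
          perm <- sample.int(p)
          pos <- match(j, perm)
          from_x <- perm[seq_len(pos)]        # j and its predecessors
          row <- row + 1L
          v <- z
          v[from_x] <- xe[i, from_x]
          plus[row, ] <- v
          v[j] <- z[j]
          minus[row, ] <- v
        }
      }
    }
    colnames(plus) <- colnames(minus) <- colnames(xb)
    diffs <- predict_fun(plus) - predict_fun(minus)
    phi <- matrix(colMeans(matrix(diffs, nsim)), nrow(xe), p, byrow = TRUE)
    colnames(phi) <- colnames(xb)
    phi
  })
}

#' Rank dose predictors by feature importance and Shapley values
#'
#' Fits a random-forest regressor on `n_seeds` resampled 70/30 splits and
#' ranks the factors two ways per seed: by the forest's impurity-reduction
#' feature importance, and by mean absolute Monte-Carlo Shapley attribution
#' over a sample of test rows. Stability is summarized as each factor's
#' frequency of appearing in the top 5 across seeds.
#'
#' @param scores Factor-score matrix.
#' @param dose Integer dose vector.
#' @param seeds Integer vector of resampling seeds (default 1:10).
#' @param train_frac Training fraction per resample.
#' @param shap_points Number of test rows explained per seed (default 50).
#' @param shap_nsim Monte-Carlo draws per (row, feature) (default 20).
#' @param ntree Forest size (default 500).
#' @return A `predictor_ranking`: list with `importance` and `shapley` data
#'   frames (mean attribution and mean rank across seeds, sorted), a
#'   `stability` data frame of top-5 frequencies, and the seeds used.
#' @export
rank_predictors <- function(scores, dose, seeds = 1:10, train_frac = 0.7,
                            shap_points = 50L, shap_nsim = 20L, ntree = 500L) {
  x <- as.matrix(scores); y <- as.numeric(dose)
  p <- ncol(x); fids <- colnames(x)
  imp_mat <- matrix(NA_real_, length(seeds), p, dimnames = list(NULL, fids))
  shap_mat <- imp_mat
  for (si in seq_along(seeds)) {
    seed <- seeds[si]
    idx <- withr::with_seed(seed, sample.int(nrow(x), round(train_frac * nrow(x))))
    x_tr <- x[idx, , drop = FALSE]; y_tr <- y[idx]
    x_te <- x[-idx, , drop = FALSE]
    fit <- withr::with_seed(seed, suppressWarnings(
      randomForest::randomForest(x = x_tr, y = y_tr, ntree = ntree,
                                 importance = FALSE)))
    imp_mat[si, ] <- randomForest::importance(fit, type = 2L)[fids, 1L]
    take <- withr::with_seed(seed,
      sample.int(nrow(x_te), min(shap_points, nrow(x_te))))
    phi <- shapley_values(function(m) as.numeric(stats::predict(fit, m)),
                          x_background = x_tr, x_explain = x_te[take, , drop = FALSE],
                          nsim = shap_nsim, seed = seed)
    shap_mat[si, ] <- colMeans(abs(phi))
  }
  summarize <- function(mat, method) {
    ranks <- t(apply(-mat, 1L, rank, ties.method = "first"))
    df <- data.frame(factor_id = fids, method = method,
                     mean_value = colMeans(mat), mean_rank = colMeans(ranks),
                     top5_freq = colMeans(ranks <= 5L),
                     stringsAsFactors = FALSE)
    df[order(df$mean_rank), ]
  }
  imp <- summarize(imp_mat, "feature_importance")
  shp <- summarize(shap_mat, "shapley")
  stability <- data.frame(factor_id = fids,
                          importance_top5_freq = imp$top5_freq[match(fids, imp$factor_id)],
                          shapley_top5_freq = shp$top5_freq[match(fids, shp$factor_id)],
                          stringsAsFactors = FALSE)
  structure(list(importance = imp, shapley = shp, stability = stability,
                 seeds = seeds),
            class = "predictor_ranking")
}

#' @export
print.predictor_ranking <- function(x, ...) {
  cat("predictor_ranking over", length(x$seeds), "seeds\n")
  cat(" top by Shapley:\n")
  print(utils::head(x$shapley[, c("factor_id", "mean_value", "mean_rank", "top5_freq")], 5L),
        row.names = FALSE, digits = 3)
  cat(" top by feature importance:\n")
  print(utils::head(x$importance[, c("factor_id", "mean_value", "mean_rank", "top5_freq")], 5L),
        row.names = FALSE, digits = 3)
  invisible(x)
}
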