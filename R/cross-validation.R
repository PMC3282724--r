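#' All leave-two-out validation splits
#'
#' @param n Number of plots (>= 4).
#' @return A `2 x choose(n, 2)` matrix; each column holds the indices of
#'   one validation pair, in deterministic (lexicographic) order. Every
#'   index appears in exactly `n - 1` columns.
#' @export
l2o_splits <- function(n) {
  if (n < 4) stop("leave-two-out requires n >= 4")
  utils::combn(n, 2)
}

#' Leave-two-out cross-validation of one candidate model
#'
#' For every pair of plots, the model is refitted on the remaining `n - 2`
#' calibration plots and used to predict the two held-out plots, on the
#' transformed response scale. Two summaries are returned: `ass`, the
#' average over splits of the two-plot validation sum of squares (the
#' predictive ranking criterion), and `r2_cv`, the cross-validated
#' R-squared `1 - SSE / SST` where SSE pools the squared errors of all
#' `n(n-1)` predictions and SST pools `(y_i - mean(y))^2` over the same
#' predictions (each plot is predicted `n - 1` times, so
#' `SST = (n - 1) * sum((y - mean(y))^2)`). `r2_cv` ranges from `-Inf`
#' (over-fitted: worse than predicting the mean) to 1 (perfect prediction).
#' Splits with a singular calibration design are excluded and counted.
#'
#' @param features Texture feature table.
#' @param y Transformed response vector.
#' @param predictors Character vector (1-3) of feature column names.
#' @return A `cv_result` list: `predictors`, `n`, `n_splits`, `excluded`,
#'   `ass`, `r2_cv`, `scale` (`"transformed"`), and `predictions` (data
#'   frame `split`, `plot`, `observed`, `predicted`).
#' @export
cross_validate <- function(features, y, predictors) {
  X <- feature_matrix(features)
  miss <- setdiff(predictors, colnames(X))
  if (length(miss) > 0) stop("unknown predictors: ", paste(miss, collapse = ", "))
  X <- X[, predictors, drop = FALSE]
  keep <- stats::complete.cases(cbind(X, y))
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  kk <- length(predictors)
  if (n <= kk + 2 + 2) stop("too few plots for leave-two-out with k = ", kk)
  splits <- l2o_splits(n)
  sse <- 0
  ss_split <- numeric(0)
  excluded <- 0L
  pred_rows <- vector("list", ncol(splits))
  for (m in seq_len(ncol(splits))) {
    out <- splits[, m]
    fit <- stats::lm.fit(cbind(1, X[-out, , drop = FALSE]), y[-out])
    if (fit$rank < kk + 1) {
      excluded <- excluded + 1L
      next
    }
    pred <- drop(cbind(1, X[out, , drop = FALSE]) %*% fit$coefficients)
    err2 <- (y[out] - pred)^2
    sse <- sse + sum(err2)
    ss_split <- c(ss_split, sum(err2))
    pred_rows[[m]] <- data.frame(split = m, plot = out,
                                 observed = y[out], predicted = pred)
  }
  if (length(ss_split) == 0) stop("all splits had singular calibration designs")
  preds <- do.call(rbind, pred_rows[!vapply(pred_rows, is.null, logical(1))])
  # each retained prediction contributes (y_i - ybar)^2 to the pooled SST
  ybar <- mean(y)
  sst <- sum((preds$observed - ybar)^2)
  structure(list(
    predictors = predictors,
    n = n,
    n_splits = ncol(splits),
    excluded = excluded,
    ass = mean(ss_split),
    r2_cv = 1 - sse / sst,
    scale = "transformed",
    predictions = preds
  ), class = "cv_result")
}

#' Select the most predictive model per candidate set
#'
#' Ranks cross-validation results by the average validation sum of squares
#' (smaller is better); ties are broken by higher cross-validated
#' R-squared, then by lexicographic predictor names.
#'
#' @param results A list of `cv_result` objects (see [cross_validate()]).
#' @return The best `cv_result`.
#' @export
select_predictive <- function(results) {
  if (length(results) == 0) stop("no cross-validation results supplied")
  ass <- vapply(results, `[[`, numeric(1), "ass")
  best <- which(ass <= min(ass) + 1e-12)
  if (length(best) > 1) {
    r2 <- vapply(results[best], `[[`, numeric(1), "r2_cv")
    best <- best[r2 >= max(r2) - 1e-12]
    labs <- vapply(results[best], function(r) {
      paste(sort(r$predictors), collapse = "+")
    }, character(1))
    best <- best[order(labs)]
  }
  results[[best[1]]]
}

#' Cross-validate all k-subsets for one response
#'
#' Convenience wrapper running [cross_validate()] over every predictor
#' subset of size `k` and returning the list of results plus the
#' most predictive one.
#'
#' @inheritParams cross_validate
#' @param k Model size (1-3).
#' @return List with `results` (all `cv_result`s) and `best`.
#' @export
cross_validate_all <- function(features, y, k) {
  X <- feature_matrix(features)
  cols <- colnames(X)[!apply(X, 2, anyNA)]
  subsets <- utils::combn(cols, k)
  results <- lapply(seq_len(ncol(subsets)), function(m) {
    cross_validate(features, y, subsets[, m])
  })
  list(results = results, best = select_predictive(results))
}
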