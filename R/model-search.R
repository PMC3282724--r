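#' Transform a response variable before model fitting
#'
#' Attributes are fitted on a transformed scale: natural log by default
#' (guaranteeing positive back-transformed estimates and stabilizing
#' variance), `log-offset` `ln(y + c)` for attributes that can be exactly
#' zero (e.g. Shannon diversity of a one-species stand), and `logit`
#' `ln(y / (1 - y))` as an alternative for proportions such as Simpson
#' dominance.
#'
#' @param values Numeric response vector.
#' @param method `"log"`, `"log-offset"` or `"logit"`.
#' @param offset Offset c for `"log-offset"` (default 1).
#' @return Transformed numeric vector.
#' @export
transform_response <- function(values, method = c("log", "log-offset", "logit"),
                               offset = 1) {
  method <- match.arg(method)
  switch(method,
    "log" = {
      bad <- which(!is.na(values) & values <= 0)
      if (length(bad) > 0) {
        stop("log transform of non-positive value at position ",
             paste(bad, collapse = ", "), "; use log-offset")
      }
      log(values)
    },
    "log-offset" = {
      bad <- which(!is.na(values) & values + offset <= 0)
      if (length(bad) > 0) {
        stop("log-offset transform undefined at position ",
             paste(bad, collapse = ", "))
      }
      log(values + offset)
    },
    "logit" = {
      bad <- which(!is.na(values) & (values <= 0 | values >= 1))
      if (length(bad) > 0) {
        stop("logit transform requires values in (0, 1); violated at position ",
             paste(bad, collapse = ", "))
      }
      log(values / (1 - values))
    }
  )
}

#' Enumerate candidate models
#'
#' All unordered predictor subsets of size `k` from `n_texture` texture
#' features, for each of `n_attributes` response attributes; no interaction
#' terms. With 40 features and 14 attributes this gives 560, 10,920 and
#' 138,320 candidate models for k = 1, 2, 3.
#'
#' @param n_texture Number of texture features (default 40).
#' @param n_attributes Number of response attributes (default 14).
#' @param k Model size (1, 2 or 3).
#' @return List with `count` (total candidates) and `subsets`
#'   (`k x choose(n_texture, k)` matrix of predictor indices).
#' @export
enumerate_models <- function(n_texture = 40L, n_attributes = 14L, k) {
  if (length(k) != 1 || !k %in% 1:3) stop("k must be 1, 2 or 3")
  subsets <- utils::combn(n_texture, k)
  list(count = n_attributes * ncol(subsets), subsets = subsets)
}

#' Small-sample corrected AIC for a least-squares fit
#'
#' `AICc = n log(RSS / n) + 2p + 2p(p + 1) / (n - p - 1)` with
#' `p = k + 2` parameters (k slopes, intercept, error variance).
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param k Number of predictors.
#' @return AICc value (`Inf` when `n - p - 1 <= 0`).
#' @export
aicc <- function(rss, n, k) {
  p <- k + 2
  if (n - p - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

#' Ordinary least-squares fit of one candidate model
#'
#' Fits `y ~ X` by least squares and packages the quantities used in model
#' selection: coefficients, R-squared, residual sum of squares and AICc.
#' Rank-deficient designs are flagged (`ok = FALSE`) and excluded from
#' selection by the search functions.
#'
#' @param X Numeric matrix or data.frame of predictor columns (1-3).
#' @param y Numeric response (already transformed).
#' @return A `model_fit` list: `predictors`, `coefficients` (intercept
#'   first), `n`, `k`, `r_squared`, `rss`, `aicc`, `ok`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 2) stop("need n > k + 2 observations")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  ok <- fit$rank == k + 1
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    predictors = colnames(X),
    coefficients = fit$coefficients,
    n = n,
    k = k,
    r_squared = 1 - rss / tss,
    rss = rss,
    aicc = aicc(rss, n, k),
    ok = ok
  ), class = "model_fit")
}

# Exhaustive R^2 over all k-subsets via centered normal equations:
# for subset S, R^2 = t(b) %*% Xty[S] / TSS with b = solve(XtX[S,S], Xty[S]).
all_subset_r2 <- function(X, y, k) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  tss <- sum(yc^2)
  subsets <- utils::combn(ncol(X), k)
  r2 <- rep(NA_real_, ncol(subsets))
  for (m in seq_len(ncol(subsets))) {
    S <- subsets[, m]
    xty <- Xty[S]
    if (anyNA(xty)) next
    b <- tryCatch(solve(XtX[S, S, drop = FALSE], xty),
                  error = function(e) NULL)
    if (is.null(b)) next
    r2[m] <- sum(b * xty) / tss
  }
  list(subsets = subsets, r2 = r2, tss = tss)
}

#' Best k-predictor model for one response
#'
#' Exhaustively fits every `choose(ncol(features), k)` predictor subset and
#' returns the fit with the largest R-squared. Ties (to within 1e-12) are
#' broken by lower AICc, then by lexicographic predictor names. Subsets with
#' missing or collinear predictors are excluded.
#'
#' @param features Data.frame or matrix of texture features (numeric
#'   columns only; a `plot_id` column is dropped automatically).
#' @param y Transformed response vector, aligned with the feature rows.
#' @param k Model size (1-3).
#' @return A `model_fit` (see [fit_ols()]) with an added `n_candidates`
#'   element.
#' @export
search_models <- function(features, y, k) {
  X <- feature_matrix(features)
  if (nrow(X) != length(y)) stop("features and y must have matching rows")
  keep <- stats::complete.cases(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  res <- all_subset_r2(X, y, k)
  if (all(is.na(res$r2))) stop("no valid candidate model")
  best <- which(res$r2 >= max(res$r2, na.rm = TRUE) - 1e-12)
  if (length(best) > 1) {
    # equal R^2 at equal k implies equal AICc; order predictor names
    labs <- vapply(best, function(m) {
      paste(sort(colnames(X)[res$subsets[, m]]), collapse = "+")
    }, character(1))
    best <- best[order(labs)]
  }
  S <- res$subsets[, best[1]]
  fit <- fit_ols(X[, S, drop = FALSE], y)
  fit$n_candidates <- ncol(res$subsets)
  fit
}

#' Exhaustive best-subset search over attributes and model sizes
#'
#' Runs [search_models()] for every response attribute at every model size,
#' and compares sizes per attribute through AICc: model sizes whose best
#' fit lies within `delta_aicc` (default 2) of the attribute's minimum AICc
#' are flagged as equally well supported.
#'
#' @param features Texture feature table (`plot_id` + 40 columns).
#' @param attributes Data.frame of response attributes (already transformed;
#'   rows aligned with `features`).
#' @param k Vector of model sizes (subset of 1:3).
#' @param delta_aicc Equal-support threshold on the AICc difference.
#' @return Data.frame with one row per (attribute, k): `attribute`, `k`,
#'   `predictors` (joined by `+`), `signs` (slope signs), `r_squared`,
#'   `aicc`, `delta_aicc`, `equally_good`, `n_candidates`. The underlying
#'   `model_fit` objects are in `attr(, "fits")`.
#' @export
select_best <- function(features, attributes, k = 1:3, delta_aicc = 2) {
  stopifnot(all(k %in% 1:3))
  rows <- list()
  fits <- list()
  for (a in names(attributes)) {
    y <- attributes[[a]]
    for (kk in k) {
      fit <- search_models(features, y, kk)
      slopes <- fit$coefficients[-1]
      rows[[length(rows) + 1]] <- data.frame(
        attribute = a,
        k = kk,
        predictors = paste(fit$predictors, collapse = "+"),
        signs = paste(ifelse(slopes >= 0, "+", "-"), collapse = ""),
        r_squared = fit$r_squared,
        aicc = fit$aicc,
        n_candidates = fit$n_candidates
      )
      fits[[paste(a, kk, sep = ".")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  out$delta_aicc <- stats::ave(out$aicc, out$attribute,
                               FUN = function(x) x - min(x))
  out$equally_good <- out$delta_aicc < delta_aicc
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Paired t-test between two sets of model R-squared values
#'
#' Used to compare the fit quality obtained for total-community versus
#' upper-canopy attribute sets across matched (attribute, model size)
#' pairs.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `t`, `p`, `df`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("need >= 2 pairs of equal length")
  }
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1))
    return(list(t = Inf * sign(mean(d)), p = 0, df = length(d) - 1))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Published model-fit reference values
#'
#' Path to the bundled table of best-model R-squared values reported for
#' the reference chronosequence, for total (T) and upper-canopy (U)
#' attribute sets at model sizes 1-3.
#'
#' @return File path of the bundled CSV.
#' @export
model_r2_reference_path <- function() {
  system.file("extdata", "model_r2_reference.csv",
              package = "glcmveg", mustWork = TRUE)
}

# Drop a plot_id column and coerce the rest to a numeric matrix.
feature_matrix <- function(features) {
  df <- as.data.frame(features)
  df$plot_id <- NULL
  as.matrix(df)
}
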