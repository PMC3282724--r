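#' Permutation null distribution of the maximal R-squared
#'
#' When hundreds to thousands of candidate models are screened on a handful
#' of plots, large R-squared values arise by chance. This builds the null
#' distribution of the *maximum* R-squared over all `choose(p, k)` candidate
#' models under no texture-attribute association: in each replicate the row
#' order of the entire feature table is permuted as a block relative to the
#' response (preserving the features' correlation structure), all candidate
#' models are refitted, and the largest R-squared is recorded. The observed
#' maximum is compared to this distribution: the empirical p-value is the
#' fraction of replicates strictly exceeding it (so p = 0 is possible), and
#' the null median measures the R-squared expected under a completely
#' random scenario.
#'
#' @param features Texture feature table (`plot_id` column ignored).
#' @param y Transformed response vector.
#' @param k Model size (1-3).
#' @param reps Number of permutation replicates (default 1000).
#' @param seed Integer seed; the distribution is reproducible given the
#'   seed.
#' @return A `null_distribution` list: `k`, `reps`, `seed`, `values`
#'   (per-replicate maximal R-squared), `median`, `observed`, `p`.
#' @export
null_max_r2 <- function(features, y, k, reps = 1000L, seed = 1L) {
  if (length(k) != 1 || !k %in% 1:3) stop("k must be 1, 2 or 3")
  if (reps < 1) stop("reps must be >= 1")
  X <- feature_matrix(features)
  keep <- stats::complete.cases(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(X)
  if (n != length(y)) stop("features and y must have matching rows")
  drop_cols <- apply(X, 2, anyNA)
  Xn <- X[, !drop_cols, drop = FALSE]
  observed <- max_r2(Xn, y, k)
  values <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      perm <- sample.int(n)
      max_r2(Xn[perm, , drop = FALSE], y, k)
    }, numeric(1))
  })
  dist <- structure(list(
    k = k, reps = as.integer(reps), seed = as.integer(seed),
    values = values, median = stats::median(values), observed = observed,
    p = NA_real_
  ), class = "null_distribution")
  dist$p <- p_value(dist, observed)
  dist
}

# Maximal R^2 over all k-subsets. k = 1 reduces to the largest squared
# correlation, computed in one matrix product.
max_r2 <- function(X, y, k) {
  if (k == 1) {
    yc <- y - mean(y)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    num <- drop(crossprod(Xc, yc))^2
    den <- colSums(Xc^2) * sum(yc^2)
    return(max(num / den, na.rm = TRUE))
  }
  max(all_subset_r2(X, y, k)$r2, na.rm = TRUE)
}

#' Empirical p-value against a null distribution
#'
#' The fraction of null replicates whose maximal R-squared strictly exceeds
#' the observed value.
#'
#' @param dist A `null_distribution` (see [null_max_r2()]).
#' @param observed Observed maximal R-squared.
#' @return p in \[0, 1\].
#' @export
p_value <- function(dist, observed) {
  if (length(dist$values) == 0) stop("empty null distribution")
  mean(dist$values > observed)
}
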