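#' Quantize a layer to discrete gray levels
#'
#' Maps the layer's global (whole-image, unmasked) minimum-maximum range
#' linearly onto integer levels `0 .. levels - 1`, flooring to integers with
#' the maximum assigned to the top level. Quantizing globally rather than
#' per window keeps gray levels, and hence all co-occurrence statistics,
#' comparable across plots. A constant layer maps to level 0 everywhere.
#' Because the mapping depends only on the min-max range, multiplying a
#' layer by any positive constant leaves the quantized image unchanged.
#'
#' @param layer Numeric matrix; masked pixels `NA`.
#' @param levels Number of gray levels (default 64).
#' @return Integer matrix with values in `0 .. levels - 1` (`NA` preserved).
#' @export
quantize <- function(layer, levels = 64L) {
  v <- layer[!is.na(layer)]
  if (length(v) == 0) stop("cannot quantize an all-masked layer")
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) {
    q <- layer
    q[!is.na(q)] <- 0
    storage.mode(q) <- "integer"
    return(q)
  }
  q <- floor((layer - lo) / (hi - lo) * levels)
  q[!is.na(q) & q >= levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' First-order texture of a window
#'
#' Distributional statistics of the raw (unquantized) values in a window:
#' the data range `DR = max - min` and the Fisher-Pearson moment skewness
#' `SKEW = m3 / m2^(3/2)` (taken as 0 for a constant window).
#'
#' @param values Numeric vector or matrix of window values.
#' @return Named numeric vector `c(DR = , SKEW = )`.
#' @export
first_order <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0) stop("window is empty")
  if (anyNA(v)) stop("window contains masked pixels")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  c(DR = max(v) - min(v),
    SKEW = if (m2 == 0) 0 else m3 / m2^1.5)
}

glcm_offsets <- list(
  "0"   = c(0L, 1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L)
)

#' Gray-level co-occurrence matrix of a quantized window
#'
#' Counts co-occurrences of gray levels for pixel pairs separated by
#' `distance` in the given direction, accumulated symmetrically (each pair
#' contributes in both orders) and normalized to a probability matrix whose
#' entries sum to 1. Directions follow the usual image convention with rows
#' increasing downward: 0 degrees is the horizontal neighbor to the right,
#' 45 up-right, 90 up, 135 up-left.
#'
#' @param window Integer matrix with values in `0 .. levels - 1`.
#' @param direction One of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param levels Number of gray levels.
#' @param distance Pixel offset distance (default 1).
#' @return A `levels x levels` symmetric probability matrix.
#' @export
glcm <- function(window, direction = "0", levels = 64L, distance = 1L) {
  off <- glcm_offsets[[as.character(direction)]]
  if (is.null(off)) stop("direction must be one of 0, 45, 90, 135")
  off <- off * as.integer(distance)
  nr <- nrow(window)
  nc <- ncol(window)
  rows <- seq_len(nr)
  cols <- seq_len(nc)
  r1 <- rows[rows + off[1] >= 1 & rows + off[1] <= nr]
  c1 <- cols[cols + off[2] >= 1 & cols + off[2] <= nc]
  if (length(r1) == 0 || length(c1) == 0) {
    stop("window too small for any pixel pair in this direction")
  }
  a <- window[r1, c1, drop = FALSE]
  b <- window[r1 + off[1], c1 + off[2], drop = FALSE]
  if (anyNA(a) || anyNA(b)) stop("window contains masked pixels")
  counts <- tabulate(a * levels + b + 1L, nbins = levels * levels) +
    tabulate(b * levels + a + 1L, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE) # row = first pixel value
  P / sum(P)
}

#' Haralick statistics of a co-occurrence matrix
#'
#' With gray levels indexed `i, j = 0 .. L-1`, marginal mean
#' `mu = sum(i * P_ij)` and variance `sigma2 = sum((i - mu)^2 * P_ij)`
#' (row and column marginals coincide for a symmetric matrix), the eight
#' statistics are: `MEAN = mu`; `VAR = sigma2`; correlation
#' `CORR = sum(P_ij (i - mu)(j - mu)) / sigma2`; contrast
#' `CONT = sum(P_ij (i - j)^2)`; dissimilarity `DISS = sum(P_ij |i - j|)`;
#' homogeneity `HOM = sum(P_ij / (1 + (i - j)^2))`; angular second moment
#' `ASM = sum(P_ij^2)`; entropy `ENT = -sum(P_ij log P_ij)` over nonzero
#' cells, in natural-log units. `CORR` is undefined (`NA`) when the matrix
#' has zero variance, as for a constant window.
#'
#' @param P A symmetric co-occurrence probability matrix.
#' @return Named numeric vector with elements `MEAN`, `VAR`, `CORR`, `CONT`,
#'   `DISS`, `HOM`, `ASM`, `ENT`.
#' @export
glcm_stats <- function(P) {
  L <- nrow(P)
  idx <- seq_len(L) - 1
  i <- matrix(idx, L, L)
  j <- t(i)
  mu <- sum(i * P)
  sigma2 <- sum((i - mu)^2 * P)
  d <- i - j
  pos <- P > 0
  c(
    MEAN = mu,
    VAR = sigma2,
    CORR = if (sigma2 == 0) NA_real_ else sum(P * (i - mu) * (j - mu)) / sigma2,
    CONT = sum(P * d^2),
    DISS = sum(P * abs(d)),
    HOM = sum(P / (1 + d^2)),
    ASM = sum(P^2),
    ENT = -sum(P[pos] * log(P[pos]))
  )
}

texture_stat_names <- c("DR", "SKEW", "MEAN", "VAR", "CORR",
                        "CONT", "DISS", "HOM", "ASM", "ENT")
texture_layer_names <- c("RED", "IR", "NDVI", "EVI")

#' Names of the 40 texture features
#'
#' The feature space is the cross of 4 layers (RED, IR, NDVI, EVI) and 10
#' statistics (DR, SKEW from first-order texture; MEAN, VAR, CORR, CONT,
#' DISS, HOM, ASM, ENT from the direction-averaged GLCM), named
#' `LAYER_STAT`.
#'
#' @return Character vector of length 40.
#' @export
texture_feature_names <- function() {
  as.vector(t(outer(texture_layer_names, texture_stat_names, paste, sep = "_")))
}

#' Extract plot-level texture features from a layer stack
#'
#' For each plot centre, takes the `window x window` neighborhood in each of
#' the four layers and computes the 10 texture statistics: DR and SKEW on
#' the raw layer values, and the 8 GLCM statistics averaged over the four
#' directions (0, 45, 90, 135 degrees) at the given distance, using
#' gray levels quantized over the layer's global range. Plots whose window
#' crosses the image edge or contains a masked pixel are skipped with a
#' warning and recorded in the `skipped` attribute of the result. A plot's
#' `CORR` is `NA` if any directional matrix has zero variance.
#'
#' @param stack A named list of layer matrices (see [layer_stack()]).
#' @param plots Data.frame with columns `plot_id`, `row`, `col` (window
#'   centres, 1-based).
#' @param window Odd window side length in pixels (default 15, matching a
#'   30 x 30 m field plot at 2.6 m pixels).
#' @param levels Gray levels for quantization (default 64).
#' @param distance Co-occurrence offset in pixels (default 1).
#' @return Data.frame with `plot_id` plus the 40 feature columns of
#'   [texture_feature_names()]; skipped plot ids in `attr(, "skipped")`.
#' @export
extract_features <- function(stack, plots, window = 15L, levels = 64L,
                             distance = 1L) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  stack <- stack[texture_layer_names]
  if (any(vapply(stack, is.null, logical(1)))) {
    stop("stack must contain layers ",
         paste(texture_layer_names, collapse = ", "))
  }
  qstack <- lapply(stack, quantize, levels = levels)
  half <- (window - 1L) %/% 2L
  nr <- nrow(stack[[1]])
  nc <- ncol(stack[[1]])
  feats <- texture_feature_names()
  rows <- vector("list", nrow(plots))
  skipped <- integer(0)
  for (p in seq_len(nrow(plots))) {
    r <- plots$row[p]
    c <- plots$col[p]
    if (r - half < 1 || r + half > nr || c - half < 1 || c + half > nc) {
      warning("plot ", plots$plot_id[p], " skipped: window crosses image edge")
      skipped <- c(skipped, plots$plot_id[p])
      next
    }
    ri <- (r - half):(r + half)
    ci <- (c - half):(c + half)
    if (any(vapply(stack, function(l) anyNA(l[ri, ci]), logical(1)))) {
      warning("plot ", plots$plot_id[p], " skipped: window contains masked pixels")
      skipped <- c(skipped, plots$plot_id[p])
      next
    }
    vals <- numeric(0)
    for (layer in texture_layer_names) {
      fo <- first_order(stack[[layer]][ri, ci])
      qw <- qstack[[layer]][ri, ci]
      stats4 <- vapply(names(glcm_offsets), function(dir) {
        glcm_stats(glcm(qw, dir, levels = levels, distance = distance))
      }, numeric(8))
      vals <- c(vals, fo, rowMeans(stats4))
    }
    row <- as.data.frame(as.list(vals))
    names(row) <- feats
    rows[[p]] <- cbind(plot_id = plots$plot_id[p], row)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no plot could be extracted")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
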