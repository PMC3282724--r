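# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: the GLCM oracle enumerates pixel pairs with
# explicit loops, and the R^2 oracle projects through lm().

# Brute-force symmetric GLCM by double loop over all pixels.
oracle_glcm <- function(window, direction, levels, distance = 1L) {
  off <- switch(as.character(direction),
    "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L),
    "135" = c(-1L, -1L))
  off <- off * distance
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(window))) {
    for (c in seq_len(ncol(window))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(window) && c2 >= 1 && c2 <= ncol(window)) {
        a <- window[r, c] + 1L; b <- window[r2, c2] + 1L
        P[a, b] <- P[a, b] + 1
        P[b, a] <- P[b, a] + 1
      }
    }
  }
  P / sum(P)
}

# Haralick statistics recomputed by direct summation over matrix cells.
oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  mu <- 0; for (i in 1:L) for (j in 1:L) mu <- mu + (i - 1) * P[i, j]
  s2 <- 0; for (i in 1:L) for (j in 1:L) s2 <- s2 + (i - 1 - mu)^2 * P[i, j]
  cor <- 0; cont <- 0; diss <- 0; hom <- 0; asm <- 0; ent <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]; d <- (i - 1) - (j - 1)
    cor <- cor + p * (i - 1 - mu) * (j - 1 - mu)
    cont <- cont + p * d^2
    diss <- diss + p * abs(d)
    hom <- hom + p / (1 + d^2)
    asm <- asm + p^2
    if (p > 0) ent <- ent - p * log(p)
  }
  c(MEAN = mu, VAR = s2, CORR = if (s2 == 0) NA_real_ else cor / s2,
    CONT = cont, DISS = diss, HOM = hom, ASM = asm, ENT = ent)
}

# Reference GLCM statistics from scikit-image (graycomatrix/graycoprops),
# averaged over the four standard directions at distance 1.
skimage_glcm_stats <- function(window, levels) {
  win_csv <- tempfile(fileext = ".csv")
  out_json <- tempfile(fileext = ".json")
  utils::write.table(window, win_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json, numpy as np",
    "from skimage.feature import graycomatrix, graycoprops",
    "w = np.loadtxt(sys.argv[1], delimiter=',').astype(np.uint8)",
    "L = int(sys.argv[2])",
    "angles = [0.0, np.pi/4, np.pi/2, 3*np.pi/4]",
    "P = graycomatrix(w, [1], angles, levels=L, symmetric=True, normed=True)",
    "props = ['mean','variance','correlation','contrast','dissimilarity',",
    "         'homogeneity','ASM','entropy']",
    "out = {p: float(np.mean(graycoprops(P, p)[0])) for p in props}",
    "json.dump(out, open(sys.argv[3], 'w'))"
  ), script)
  status <- system2("python", c(script, win_csv, levels, out_json),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_json)) {
    stop("scikit-image oracle failed: ", paste(status, collapse = "\n"))
  }
  v <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  c(MEAN = v$mean, VAR = v$variance, CORR = v$correlation, CONT = v$contrast,
    DISS = v$dissimilarity, HOM = v$homogeneity, ASM = v$ASM, ENT = v$entropy)
}

# R^2 via lm(): the reference for the normal-equations search path.
oracle_r2 <- function(X, y) summary(stats::lm(y ~ ., data = as.data.frame(X)))$r.squared

# A small hand-built stem community: one plot, species and sizes chosen to
# make every attribute computable by hand.
make_stems <- function(dbh, species = seq_along(dbh), crown1 = rep(2, length(dbh)),
                       crown2 = crown1, height = rep(5, length(dbh)),
                       quadrat = rep_len(1:16, length(dbh)), plot_id = 1L) {
  cls <- ifelse(dbh >= 5, "large", ifelse(dbh >= 2.5, "medium", "small"))
  plot_id <- rep_len(plot_id, length(dbh))
  data.frame(plot_id = plot_id, quadrat = quadrat, species = species,
             dbh_cm = dbh, crown1_m = crown1, crown2_m = crown2,
             height_m = height, sampling_class = cls)
}

# Random feature table with the package's 40 standard column names.
random_features <- function(n, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * 40), n, 40,
                dimnames = list(NULL, texture_feature_names()))
  })
  cbind(plot_id = seq_len(n), as.data.frame(X))
}
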