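test_that("quantization maps the global range onto 0..levels-1", {
  expect_true(all(quantize(matrix(2.5, 4, 4)) == 0L))
  x <- matrix(c(0.1, 0.5, 0.9, 0.3), 2, 2)
  q <- quantize(x, 64)
  expect_equal(q[x == 0.1], 0L)
  expect_equal(q[x == 0.9], 63L)
  # ramp of exactly 64 equally spaced values: one pixel per level, ordered
  ramp <- matrix(seq(0, 1, length.out = 64), 8, 8)
  qr <- quantize(ramp, 64)
  expect_equal(sort(unique(as.vector(qr))), 0:63)
  expect_equal(tabulate(qr + 1, 64), rep(1L, 64))
  expect_equal(as.vector(qr), 0:63)  # order preserved along the ramp
  expect_error(quantize(matrix(NA_real_, 2, 2)), "all-masked")
})

test_that("quantization is invariant to positive rescaling of the layer", {
  withr::with_seed(8, x <- matrix(runif(225), 15, 15))
  expect_identical(quantize(x), quantize(3.7 * x))
  expect_identical(quantize(x), quantize(x / 42))
})

test_that("first-order statistics match direct moment evaluation", {
  expect_equal(first_order(matrix(5, 3, 3)), c(DR = 0, SKEW = 0))
  expect_equal(first_order(c(1, 2, 3, 4, 5))[["SKEW"]], 0)
  v <- c(1, 2, 10)
  mo <- mean(v)
  g1 <- mean((v - mo)^3) / mean((v - mo)^2)^1.5
  expect_equal(first_order(v), c(DR = 9, SKEW = g1))
  expect_error(first_order(c(1, NA)), "masked")
})

test_that("co-occurrence matrices are normalized, symmetric and exact", {
  # constant window: single nonzero diagonal cell
  P <- glcm(matrix(3L, 5, 5), "0", levels = 8)
  expect_equal(P[4, 4], 1)
  expect_equal(sum(P), 1)

  # 1x2 window (0, 1), horizontal: the pair is counted in both orders
  P2 <- glcm(matrix(c(0L, 1L), 1, 2), "0", levels = 2)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  # normalization and symmetry on random windows, all directions
  for (seed in 1:5) {
    withr::with_seed(seed, w <- matrix(sample(0:15, 49, TRUE), 7, 7))
    for (dir in c("0", "45", "90", "135")) {
      P <- glcm(w, dir, levels = 16)
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P))
      expect_true(all(P >= 0))
    }
  }
  expect_error(glcm(matrix(0L, 1, 1), "0", levels = 2), "too small")
  expect_error(glcm(matrix(0L, 2, 2), "30", levels = 2), "direction")
})

test_that("glcm matches the brute-force pair-enumeration oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, w <- matrix(sample(0:31, 81, TRUE), 9, 9))
    for (dir in c("0", "45", "90", "135")) {
      expect_equal(glcm(w, dir, levels = 32), oracle_glcm(w, dir, 32))
    }
  }
})

test_that("Haralick statistics agree with closed forms and the oracle", {
  # constant window
  s <- glcm_stats(glcm(matrix(2L, 4, 4), "0", levels = 4))
  expect_equal(s[c("CONT", "DISS", "ENT")], c(CONT = 0, DISS = 0, ENT = 0))
  expect_equal(s[c("HOM", "ASM")], c(HOM = 1, ASM = 1))
  expect_true(is.na(s["CORR"]))

  # 0/63 checkerboard at 0 degrees: every horizontal pair differs by 63
  cb <- matrix((outer(1:16, 1:16, `+`) %% 2) * 63L, 16, 16)
  s2 <- glcm_stats(glcm(cb, "0", levels = 64))
  expect_equal(s2[["CONT"]], 63^2)
  expect_equal(s2[["DISS"]], 63)
  expect_equal(s2[["HOM"]], 1 / (1 + 63^2))

  # uniform GLCM over k^2 cells
  k <- 5
  U <- matrix(1 / k^2, k, k)
  su <- glcm_stats(U)
  expect_equal(su[["ENT"]], log(k^2))
  expect_equal(su[["ASM"]], 1 / k^2)

  # random windows against the loop-based oracle
  for (seed in 1:5) {
    withr::with_seed(seed, w <- matrix(sample(0:15, 64, TRUE), 8, 8))
    P <- glcm(w, "135", levels = 16)
    expect_equal(glcm_stats(P), oracle_glcm_stats(P), tolerance = 1e-12)
  }
})

test_that("entropy-order relations and the dissimilarity bound hold", {
  for (seed in 1:10) {
    withr::with_seed(seed, w <- matrix(sample(0:7, 36, TRUE), 6, 6))
    s <- glcm_stats(glcm(w, "90", levels = 8))
    # Cauchy-Schwarz: DISS = E|i-j| <= sqrt(E (i-j)^2) = sqrt(CONT)
    expect_lte(s[["DISS"]], sqrt(s[["CONT"]]) + 1e-12)
    expect_equal(s[["ENT"]] == 0, s[["ASM"]] == 1)
    expect_true(s[["ENT"]] >= 0 && s[["ASM"]] <= 1 && s[["ASM"]] > 0)
  }
})

test_that("feature extraction yields 40 named features per plot", {
  scene <- generate_scene(scenario_config(seed = 3))
  fe <- extract_features(layer_stack(scene), scene$plot_registry)
  expect_equal(names(fe), c("plot_id", texture_feature_names()))
  expect_equal(ncol(fe) - 1, 40)
  expect_equal(nrow(fe), nrow(scene$plot_registry))
  expect_true(all(fe$RED_ENT >= 0))
  expect_true(all(fe$RED_ASM > 0 & fe$RED_ASM <= 1))
  expect_true(all(fe$NDVI_HOM > 0 & fe$NDVI_HOM <= 1))
  expect_true(all(fe[, paste0(c("RED", "IR", "NDVI", "EVI"), "_VAR")] >= 0))
})

test_that("plots at the edge or over masked pixels are skipped", {
  scene <- generate_scene(scenario_config(seed = 3))
  plots <- data.frame(plot_id = c(1L, 2L), row = c(3L, 30L), col = c(3L, 30L))
  expect_warning(fe <- extract_features(layer_stack(scene), plots),
                 "crosses image edge")
  expect_equal(fe$plot_id, 2L)
  expect_equal(attr(fe, "skipped"), 1L)

  st <- layer_stack(scene)
  st$NDVI[30, 30] <- NA
  plots2 <- data.frame(plot_id = c(2L, 3L), row = c(30L, 60L), col = c(30L, 60L))
  expect_warning(fe2 <- extract_features(st, plots2), "masked")
  expect_equal(fe2$plot_id, 3L)
  expect_error(suppressWarnings(extract_features(st, plots2[1, , drop = FALSE])),
               "no plot")
})

test_that("direction-averaged features are invariant to 180-degree rotation", {
  scene <- generate_scene(scenario_config(seed = 6))
  stack <- layer_stack(scene)
  rot <- lapply(stack, function(x) x[nrow(x):1, ncol(x):1])
  reg <- scene$plot_registry[3, , drop = FALSE]
  reg_rot <- reg
  reg_rot$row <- nrow(stack$RED) + 1L - reg$row
  reg_rot$col <- ncol(stack$RED) + 1L - reg$col
  f1 <- extract_features(stack, reg)
  f2 <- extract_features(rot, reg_rot)
  expect_equal(f1[, -1], f2[, -1], tolerance = 1e-10)
})

test_that("features match the reference GLCM implementation", {
  # direction-averaged statistics vs scikit-image on random 15x15 windows
  withr::with_seed(42, {
    windows <- lapply(1:10, function(i) matrix(sample(0:63, 225, TRUE), 15, 15))
  })
  for (w in windows) {
    ours <- rowMeans(vapply(c("0", "45", "90", "135"), function(dir) {
      glcm_stats(glcm(w, dir, levels = 64))
    }, numeric(8)))
    ref <- skimage_glcm_stats(w, 64)
    expect_equal(ours, ref[names(ours)], tolerance = 1e-8)
  }
})

test_that("GLCM mean and variance of RED decline with stand age", {
  # the inverse texture-age relation the whole analysis rests on
  wins_var <- 0
  wins_mean <- 0
  for (seed in 1:10) {
    cfg <- scenario_config(ages = c(3, 50), image_height = 60,
                           image_width = 120, seed = seed)
    scene <- generate_scene(cfg)
    fe <- extract_features(layer_stack(scene), scene$plot_registry)
    if (fe$RED_VAR[2] < fe$RED_VAR[1]) wins_var <- wins_var + 1
    if (fe$RED_MEAN[2] < fe$RED_MEAN[1]) wins_mean <- wins_mean + 1
  }
  expect_gte(wins_var, 9)
  expect_gte(wins_mean, 9)
})
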