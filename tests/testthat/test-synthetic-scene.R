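test_that("scene generation is deterministic and bounded", {
  cfg <- scenario_config(seed = 11)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$bands, s2$bands)
  for (b in s1$bands) {
    expect_true(all(b >= 0 & b <= 1))
  }
  expect_equal(nrow(s1$plot_registry), nrow(cfg$stand_layout))
  # every plot's 15x15 window fits inside the image
  half <- 7
  reg <- s1$plot_registry
  expect_true(all(reg$row - half >= 1 & reg$row + half <= cfg$image_height))
  expect_true(all(reg$col - half >= 1 & reg$col + half <= cfg$image_width))
})

test_that("noiseless uniform-cover scene equals the mixed endmembers", {
  cfg <- scenario_config(
    ages = c(10, 10), noise_sd = 0, cover_base_var = 1e-12,
    image_height = 60, image_width = 120, seed = 5
  )
  # cover variance ~ 0 so every stand pixel sits at the mean cover
  scene <- generate_scene(cfg)
  m <- cfg$cover_asymptote * (1 - exp(-cfg$cover_rate * 10))
  lay <- cfg$stand_layout
  px <- scene$bands$RED[lay$row0[1] + 2, lay$col0[1] + 2]
  expect_equal(px, m * cfg$canopy[["RED"]] + (1 - m) * cfg$soil[["RED"]],
               tolerance = 1e-4)
  # background is pure soil
  expect_equal(scene$bands$IR[1, 1], cfg$soil[["IR"]], tolerance = 1e-9)
})

test_that("within-stand spectral variance declines with stand age", {
  wins <- 0
  for (seed in 1:20) {
    cfg <- scenario_config(ages = c(2, 60), image_height = 60,
                           image_width = 120, seed = seed)
    scene <- generate_scene(cfg)
    lay <- cfg$stand_layout
    v <- vapply(1:2, function(s) {
      rows <- lay$row0[s]:(lay$row0[s] + lay$height[s] - 1)
      cols <- lay$col0[s]:(lay$col0[s] + lay$width[s] - 1)
      stats::var(as.vector(scene$bands$RED[rows, cols]))
    }, numeric(1))
    if (v[2] < v[1]) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("stand layouts outside the image are rejected", {
  lay <- data.frame(stand_id = 1, row0 = 110, col0 = 1, height = 20,
                    width = 20, age = 10)
  expect_error(scenario_config(stand_layout = lay), "bounds")
  expect_error(scenario_config(ages = numeric(0)), "at least one")
})

test_that("stem communities gain basal area with age and are deterministic", {
  wins <- 0
  for (seed in 1:20) {
    cfg <- scenario_config(ages = c(2, 60), image_height = 60,
                           image_width = 120, seed = seed)
    st <- generate_stem_table(cfg)
    st <- scale_to_hectare(st)
    ba <- tapply(st$expansion * pi * (st$dbh_cm / 200)^2, st$plot_id, sum)
    if (ba[["1"]] < ba[["2"]]) wins <- wins + 1  # plot 1 = 2 yr, plot 2 = 60 yr
  }
  expect_gte(wins, 18)
  cfg <- scenario_config(seed = 3)
  expect_identical(generate_stem_table(cfg), generate_stem_table(cfg))
  expect_error(generate_stem_table(cfg, ages = numeric(0)), "non-empty")
})

test_that("a one-species pool forces monodominant communities", {
  cfg <- scenario_config(ages = c(5, 30), species_pool_size = 1,
                         image_height = 60, image_width = 120, seed = 9)
  st <- generate_stem_table(cfg)
  expect_true(all(st$species == 1))
  at <- attribute_table(st, c(5, 30))
  expect_true(all(at$S_T == 1))
  expect_true(all(at$H_T == 0))
  expect_true(all(at$D_T == 1))
})

test_that("stem tables respect DBH-class consistency", {
  cfg <- scenario_config(seed = 21)
  st <- generate_stem_table(cfg)
  expect_true(all(st$dbh_cm > 0))
  expect_true(all(st$dbh_cm[st$sampling_class == "large"] >= 5))
  with_m <- st$dbh_cm[st$sampling_class == "medium"]
  expect_true(all(with_m >= 2.5 & with_m < 5))
  with_s <- st$dbh_cm[st$sampling_class == "small"]
  expect_true(all(with_s >= 1 & with_s < 2.5))
  expect_true(all(st$crown1_m >= 0 & st$crown2_m >= 0))
  expect_true(all(st$quadrat %in% 1:16))
})

test_that("ground truth exposes the latent parameters", {
  cfg <- scenario_config(seed = 2)
  gt <- ground_truth(cfg)
  expect_equal(nrow(gt), nrow(cfg$stand_layout))
  # saturating cover limit: asymptote 1, huge rate
  cfg2 <- scenario_config(ages = 60, cover_asymptote = 1, cover_rate = 5,
                          image_height = 60, image_width = 60, seed = 1)
  expect_equal(ground_truth(cfg2)$mean_cover, 1, tolerance = 1e-6)
  # round-trips through CSV unchanged (to write/read precision)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(gt, f, row.names = FALSE)
  gt2 <- utils::read.csv(f)
  expect_equal(gt2, gt, tolerance = 1e-12)
  # monotone construction: cover variance non-increasing in age
  cfg3 <- scenario_config(ages = c(2, 10, 25, 60), image_height = 60,
                          image_width = 120, seed = 1)
  expect_true(all(diff(ground_truth(cfg3)$cover_var) <= 0))
})

test_that("scenes round-trip through TIFF and CSV", {
  cfg <- scenario_config(ages = c(3, 40), image_height = 60,
                         image_width = 120, seed = 13)
  scene <- generate_scene(cfg)
  img <- tempfile(fileext = ".tif")
  reg <- tempfile(fileext = ".csv")
  write_scene(scene, img, reg)
  back <- read_scene(img, reg)
  for (b in c("BLUE", "RED", "IR")) {
    expect_equal(back$bands[[b]], scene$bands[[b]], tolerance = 1e-6)
  }
  expect_equal(back$plot_registry$age, scene$plot_registry$age)
})
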