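#' Scenario configuration for synthetic successional landscapes
#'
#' Builds the parameter set from which a synthetic scene (multiband
#' reflectance image) and matching stem communities are generated. The
#' generator emulates a mosaic of differently-aged fallows: each stand is an
#' axis-aligned rectangle whose pixels mix a soil and a canopy spectral
#' endmember according to a per-pixel canopy-cover fraction. Mean cover
#' follows a saturating curve of stand age, `cover(age) = A * (1 - exp(-r *
#' age))`, and the pixel-to-pixel variance of cover decays exponentially with
#' age, so young stands are spectrally heterogeneous (soil shows through) and
#' old stands are smooth. This is the structure under which image texture is
#' expected to carry information about stand development.
#'
#' @param image_height,image_width Image dimensions in pixels.
#' @param pixel_size Ground pixel size in metres (default 2.6, a typical
#'   very-high-resolution multispectral pixel).
#' @param stand_layout A data.frame with columns `stand_id`, `row0`, `col0`
#'   (1-based top-left pixel), `height`, `width` (pixels) and `age` (years).
#'   If `NULL`, a regular grid layout is built from `ages` via
#'   [default_layout()].
#' @param ages Stand ages in years, used when `stand_layout` is `NULL`.
#' @param cover_asymptote,cover_rate Parameters A (in \[0,1\]) and r (> 0,
#'   per year) of the saturating cover-vs-age curve.
#' @param heterogeneity_decay Rate (per year, >= 0) at which within-stand
#'   cover variance declines with age.
#' @param cover_base_var Cover variance of a hypothetical age-0 stand
#'   (variance units of a \[0,1\] fraction).
#' @param soil,canopy Named numeric vectors of endmember reflectance with
#'   elements `BLUE`, `RED`, `IR`, all in \[0,1\]. Defaults are illustrative
#'   dry-season values: bright soil, dark-red / bright-infrared canopy.
#' @param noise_sd Additive Gaussian sensor noise, reflectance units.
#' @param species_pool_size Number of species available to the community
#'   generator.
#' @param seed Integer seed; all randomness in scene and stem generation
#'   flows from it, and identical configurations give bit-identical output.
#'
#' @return An object of class `scenario_config` (a list of validated
#'   parameters).
#' @seealso [generate_scene()], [generate_stem_table()], [ground_truth()]
#' @export
scenario_config <- function(image_height = 120L,
                            image_width = 120L,
                            pixel_size = 2.6,
                            stand_layout = NULL,
                            ages = c(2, 5, 9, 13, 18, 25, 32, 42, 60),
                            cover_asymptote = 0.95,
                            cover_rate = 0.12,
                            heterogeneity_decay = 0.05,
                            cover_base_var = 0.04,
                            soil = c(BLUE = 0.12, RED = 0.25, IR = 0.30),
                            canopy = c(BLUE = 0.04, RED = 0.05, IR = 0.45),
                            noise_sd = 0.01,
                            species_pool_size = 40L,
                            seed = 1L) {
  if (is.null(stand_layout)) {
    stand_layout <- default_layout(ages, image_height, image_width)
  }
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    pixel_size = pixel_size,
    stand_layout = stand_layout,
    cover_asymptote = cover_asymptote,
    cover_rate = cover_rate,
    heterogeneity_decay = heterogeneity_decay,
    cover_base_var = cover_base_var,
    soil = soil,
    canopy = canopy,
    noise_sd = noise_sd,
    species_pool_size = as.integer(species_pool_size),
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  bands <- c("BLUE", "RED", "IR")
  if (!all(bands %in% names(cfg$soil)) || !all(bands %in% names(cfg$canopy))) {
    stop("endmembers must be named vectors with BLUE, RED and IR elements")
  }
  if (any(cfg$soil < 0 | cfg$soil > 1) || any(cfg$canopy < 0 | cfg$canopy > 1)) {
    stop("endmember reflectance must lie in [0, 1]")
  }
  if (cfg$cover_asymptote < 0 || cfg$cover_asymptote > 1) {
    stop("cover_asymptote must lie in [0, 1]")
  }
  if (cfg$cover_rate <= 0) stop("cover_rate must be strictly positive")
  if (cfg$cover_base_var <= 0) stop("cover_base_var must be strictly positive")
  if (cfg$heterogeneity_decay < 0) stop("heterogeneity_decay must be >= 0")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  lay <- cfg$stand_layout
  need <- c("stand_id", "row0", "col0", "height", "width", "age")
  if (!is.data.frame(lay) || !all(need %in% names(lay))) {
    stop("stand_layout must be a data.frame with columns ",
         paste(need, collapse = ", "))
  }
  if (any(lay$age <= 0)) stop("stand ages must be positive")
  if (any(lay$row0 < 1) || any(lay$col0 < 1) ||
      any(lay$row0 + lay$height - 1 > cfg$image_height) ||
      any(lay$col0 + lay$width - 1 > cfg$image_width)) {
    stop("stand layout exceeds image bounds")
  }
  invisible(cfg)
}

#' Regular grid layout of square stands
#'
#' Places one square stand per age on a regular grid, centred so that a full
#' 15x15 analysis window around each stand centre stays inside the image
#' *and inside the stand itself*. Default stand side is 20 pixels (about
#' 52 m at 2.6 m pixels, i.e. ~2700 m2, the upper end of typical smallholder
#' fallow sizes): a window that spills over a stand edge would mix the
#' stand's canopy with bare background soil, and that edge contrast, not the
#' stand's internal heterogeneity, would then dominate its texture.
#'
#' @param ages Stand ages in years, one stand per element.
#' @param image_height,image_width Image dimensions in pixels.
#' @param stand_size Stand side length in pixels.
#' @return A stand-layout data.frame (see [scenario_config()]).
#' @export
default_layout <- function(ages, image_height = 120L, image_width = 120L,
                           stand_size = 20L) {
  n <- length(ages)
  if (n == 0) stop("at least one stand age is required")
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  row_step <- floor(image_height / nrows)
  col_step <- floor(image_width / ncols)
  if (row_step < stand_size || col_step < stand_size) {
    stop("image too small for ", n, " stands of side ", stand_size)
  }
  idx <- seq_len(n) - 1L
  r <- idx %/% ncols
  c <- idx %% ncols
  row0 <- r * row_step + floor((row_step - stand_size) / 2) + 1L
  col0 <- c * col_step + floor((col_step - stand_size) / 2) + 1L
  data.frame(
    stand_id = seq_len(n),
    row0 = as.integer(row0),
    col0 = as.integer(col0),
    height = as.integer(stand_size),
    width = as.integer(stand_size),
    age = ages
  )
}

mean_cover <- function(age, asymptote, rate) asymptote * (1 - exp(-rate * age))

cover_variance <- function(age, base_var, decay, m) {
  v <- base_var * exp(-decay * age)
  # a Beta variate cannot exceed m(1-m); keep strictly inside the bound
  pmin(v, 0.9 * m * (1 - m))
}

#' Generate a synthetic multiband reflectance scene
#'
#' Renders the stand mosaic described by a [scenario_config()]: each pixel's
#' reflectance in each band is `cover * canopy + (1 - cover) * soil + noise`,
#' where the per-pixel cover fraction is Beta-distributed around the stand's
#' age-dependent mean with variance decaying with age. Pixels outside any
#' stand are bare soil (cover 0). Output reflectance is clipped to \[0,1\].
#'
#' @param config A [scenario_config()] object.
#' @return An object of class `reflectance_scene`: a list with `bands` (named
#'   list of BLUE, RED, IR matrices), `plot_registry` (data.frame `plot_id`,
#'   `row`, `col`, `age` of stand-centre plots) and the originating `config`.
#' @export
generate_scene <- function(config) {
  validate_scenario_config(config)
  h <- config$image_height
  w <- config$image_width
  lay <- config$stand_layout
  withr::with_seed(config$seed, {
    cover <- matrix(0, h, w)
    for (s in seq_len(nrow(lay))) {
      rows <- lay$row0[s]:(lay$row0[s] + lay$height[s] - 1L)
      cols <- lay$col0[s]:(lay$col0[s] + lay$width[s] - 1L)
      m <- mean_cover(lay$age[s], config$cover_asymptote, config$cover_rate)
      v <- cover_variance(lay$age[s], config$cover_base_var,
                          config$heterogeneity_decay, m)
      npix <- length(rows) * length(cols)
      if (m <= 0 || m >= 1 || v <= 0) {
        cover[rows, cols] <- m
      } else {
        conc <- m * (1 - m) / v - 1
        cover[rows, cols] <- stats::rbeta(npix, m * conc, (1 - m) * conc)
      }
    }
    bands <- list()
    for (b in c("BLUE", "RED", "IR")) {
      refl <- cover * config$canopy[[b]] + (1 - cover) * config$soil[[b]]
      if (config$noise_sd > 0) {
        refl <- refl + stats::rnorm(h * w, sd = config$noise_sd)
      }
      bands[[b]] <- matrix(pmin(pmax(refl, 0), 1), h, w)
    }
  })
  registry <- data.frame(
    plot_id = lay$stand_id,
    row = as.integer(lay$row0 + floor(lay$height / 2)),
    col = as.integer(lay$col0 + floor(lay$width / 2)),
    age = lay$age
  )
  structure(list(bands = bands, plot_registry = registry, config = config),
            class = "reflectance_scene")
}

# Latent community parameters for one stand age; single source of truth
# shared by generate_stem_table() and ground_truth().
community_params <- function(age, config) {
  g <- 1 - exp(-0.08 * age)            # structural development, saturating
  list(
    age = age,
    lambda_large = 40 * g,             # expected large stems in 400 m2
    lambda_medium = 5 + 20 * g,        # expected medium stems in 200 m2
    lambda_small = 5 + 15 * (1 - g),   # expected small stems in 100 m2
    dbh_shape = 2,
    dbh_scale = 1 + 0.08 * age,        # large-stem DBH ~ 5 + Gamma, in cm
    evenness_theta = 0.65 * exp(-0.04 * age) + 0.05,
    height_slope = 0.35                # m of height per cm DBH
  )
}

#' Generate synthetic stem inventories for a set of stand ages
#'
#' Produces one sampled stem community per age, mimicking a nested
#' inventory design: large stems (DBH >= 5 cm) censused over 400 m2, medium
#' stems (2.5-5 cm) over 200 m2 and small stems (1-2.5 cm) over 100 m2.
#' Expected basal area and species richness increase with age while species
#' dominance decreases: stem counts and diameters grow along a saturating
#' development curve, and species identities are drawn from a geometric
#' rank-abundance series whose evenness increases with age.
#'
#' @param config A [scenario_config()]; supplies the species pool and seed.
#' @param ages Stand ages (years), one plot per element.
#' @return A `stem_table` data.frame with columns `plot_id`, `quadrat`
#'   (1-16), `species`, `dbh_cm`, `crown1_m`, `crown2_m`, `height_m`,
#'   `sampling_class` (`"large"`, `"medium"`, `"small"`).
#' @export
generate_stem_table <- function(config, ages = config$stand_layout$age) {
  validate_scenario_config(config)
  if (length(ages) == 0) stop("ages must be a non-empty vector")
  if (any(ages <= 0)) stop("ages must be positive")
  pool <- config$species_pool_size
  out <- withr::with_seed(config$seed + 1000L, {
    plots <- lapply(seq_along(ages), function(p) {
      pars <- community_params(ages[p], config)
      n_l <- stats::rpois(1, pars$lambda_large)
      n_m <- stats::rpois(1, pars$lambda_medium)
      n_s <- stats::rpois(1, pars$lambda_small)
      dbh <- c(
        5 + stats::rgamma(n_l, shape = pars$dbh_shape, scale = pars$dbh_scale),
        stats::runif(n_m, 2.5, 5),
        stats::runif(n_s, 1, 2.5)
      )
      cls <- rep(c("large", "medium", "small"), c(n_l, n_m, n_s))
      n <- length(dbh)
      if (n == 0) return(NULL)
      # geometric rank-abundance; per-plot permutation of the pool so that
      # different plots are not dominated by the same species label
      theta <- pars$evenness_theta
      pr <- theta * (1 - theta)^(seq_len(pool) - 1)
      pr <- pr / sum(pr)
      ranks <- sample.int(pool, n, replace = TRUE, prob = pr)
      relabel <- sample.int(pool)
      height <- pmax(1.3,
                     1 + pars$height_slope * dbh + stats::rnorm(n, sd = 0.5))
      crown1 <- pmax(0.2, 0.25 * dbh * exp(stats::rnorm(n, sd = 0.15)))
      crown2 <- pmax(0.2, crown1 * exp(stats::rnorm(n, sd = 0.10)))
      data.frame(
        plot_id = p,
        quadrat = sample.int(16L, n, replace = TRUE),
        species = relabel[ranks],
        dbh_cm = dbh,
        crown1_m = crown1,
        crown2_m = crown2,
        height_m = height,
        sampling_class = cls
      )
    })
    do.call(rbind, plots)
  })
  rownames(out) <- NULL
  class(out) <- c("stem_table", "data.frame")
  out
}

#' Latent parameters of a scenario, for parameter-recovery tests
#'
#' Returns, per stand, the generator's own ground truth: age, mean canopy
#' cover, cover variance, expected band reflectance, and the expected values
#' of the key community attributes implied by the stem-community model
#' (expected basal area over 400 m2 large-stem sampling, expected stem
#' counts, and the rank-abundance evenness parameter).
#'
#' @param config A [scenario_config()].
#' @return A data.frame with one row per stand.
#' @export
ground_truth <- function(config) {
  validate_scenario_config(config)
  lay <- config$stand_layout
  m <- mean_cover(lay$age, config$cover_asymptote, config$cover_rate)
  v <- cover_variance(lay$age, config$cover_base_var,
                      config$heterogeneity_decay, m)
  pars <- lapply(lay$age, community_params, config = config)
  # E[BA] per ha from large stems: 25 stems-to-ha factor, DBH = 5 + Gamma
  exp_ba <- vapply(pars, function(p) {
    mu <- p$dbh_shape * p$dbh_scale
    ex2 <- (5 + mu)^2 + p$dbh_shape * p$dbh_scale^2   # E[DBH^2], cm^2
    25 * p$lambda_large * pi * ex2 / 4 / 1e4          # m2/ha
  }, numeric(1))
  data.frame(
    stand_id = lay$stand_id,
    age = lay$age,
    mean_cover = m,
    cover_var = v,
    exp_red = m * config$canopy[["RED"]] + (1 - m) * config$soil[["RED"]],
    exp_ir = m * config$canopy[["IR"]] + (1 - m) * config$soil[["IR"]],
    exp_ba_large = exp_ba,
    lambda_large = vapply(pars, `[[`, numeric(1), "lambda_large"),
    evenness_theta = vapply(pars, `[[`, numeric(1), "evenness_theta")
  )
}

#' Write and read a reflectance scene
#'
#' The image is stored as a 3-channel 32-bit float TIFF (band order BLUE,
#' RED, IR) and the plot registry as a CSV with columns `plot_id`, `row`,
#' `col`, `age`.
#'
#' @param scene A `reflectance_scene`.
#' @param image_path Path of the TIFF to write/read.
#' @param registry_path Path of the plot-registry CSV.
#' @return `write_scene()` returns the paths invisibly; `read_scene()`
#'   returns a `reflectance_scene` (without the generating config).
#' @export
write_scene <- function(scene, image_path, registry_path) {
  arr <- array(0, dim = c(nrow(scene$bands$BLUE), ncol(scene$bands$BLUE), 3L))
  arr[, , 1] <- scene$bands$BLUE
  arr[, , 2] <- scene$bands$RED
  arr[, , 3] <- scene$bands$IR
  tiff::writeTIFF(arr, image_path, bits.per.sample = 32L)
  utils::write.csv(scene$plot_registry, registry_path, row.names = FALSE)
  invisible(c(image = image_path, registry = registry_path))
}

#' @rdname write_scene
#' @export
read_scene <- function(image_path, registry_path) {
  arr <- tiff::readTIFF(image_path)
  registry <- utils::read.csv(registry_path)
  structure(
    list(
      bands = list(BLUE = arr[, , 1], RED = arr[, , 2], IR = arr[, , 3]),
      plot_registry = registry,
      config = NULL
    ),
    class = "reflectance_scene"
  )
}
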