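#' Per-hectare expansion factors for nested inventory sampling
#'
#' Stems are sampled over areas that depend on their size class: large stems
#' (DBH >= 5 cm) over 400 m2, medium stems (2.5 <= DBH < 5 cm) over 200 m2
#' and small stems (1 <= DBH < 2.5 cm) over 100 m2. Scaling to one hectare
#' therefore weights each stem by 10000 / sampled area: 25, 50 and 100
#' respectively.
#'
#' @param stems A `stem_table` data.frame (see [generate_stem_table()]).
#' @return The table with an added `expansion` column (stems/ha represented
#'   by each sampled stem).
#' @export
scale_to_hectare <- function(stems) {
  areas <- c(large = 400, medium = 200, small = 100)
  cls <- as.character(stems$sampling_class)
  unknown <- setdiff(unique(cls), names(areas))
  if (length(unknown) > 0) {
    stop("unknown sampling class: ", paste(unknown, collapse = ", "))
  }
  stems$expansion <- 10000 / areas[cls]
  stems
}

crown_area <- function(d1, d2) pi * (d1 / 2) * (d2 / 2)

#' Upper-canopy subset of a stem community
#'
#' Selects the stems that make up the upper half of cumulative canopy cover:
#' stems are sorted by individual crown area (descending, ties broken by
#' larger DBH, then by input order) and the minimal prefix whose cumulative
#' expansion-weighted crown area reaches at least 50% of the plot's total
#' canopy cover is retained. This subset approximates the part of the
#' community actually visible to a nadir-viewing sensor.
#'
#' @param stems A `stem_table` for a single plot; an `expansion` column is
#'   added via [scale_to_hectare()] if absent.
#' @return The subset of rows forming the upper set, in the sorted order.
#' @export
upper_set <- function(stems) {
  if (is.null(stems$expansion)) stems <- scale_to_hectare(stems)
  ca <- crown_area(stems$crown1_m, stems$crown2_m)
  if (all(ca == 0)) stop("degenerate input: all crown areas are zero")
  ord <- order(-ca, -stems$dbh_cm)
  wca <- (stems$expansion * ca)[ord]
  cum <- cumsum(wca)
  k <- which(cum >= 0.5 * sum(wca))[1]
  stems[ord[seq_len(k)], , drop = FALSE]
}

shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

simpson <- function(p) sum(p^2)

attribute_set <- function(stems) {
  ca <- crown_area(stems$crown1_m, stems$crown2_m)
  ba <- pi * (stems$dbh_cm / 200)^2            # m2 per stem
  w <- stems$expansion
  ab <- tapply(w, stems$species, sum)          # expansion-weighted abundance
  p <- ab / sum(ab)
  list(
    Dn = sum(w),
    CC = sum(w * ca),
    BA = sum(w * ba),
    S = length(unique(stems$species)),
    H = shannon(p),
    D = simpson(p)
  )
}

#' Stand structural and diversity attributes from a stem inventory
#'
#' Computes, for one plot, the attribute record used throughout the
#' analysis: mean canopy height (Hgt) plus, for both the total community (T)
#' and its upper-canopy subset (U): stem density Dn (individuals/ha), canopy
#' cover CC (m2/ha, sum of elliptical crown areas), basal area BA (m2/ha),
#' species richness S, Shannon diversity H' (natural-log units) and Simpson
#' dominance D' (sum of squared abundance shares, 1 when a single species
#' is present). Abundance shares are expansion-weighted, consistent with the
#' per-hectare scaling. Hgt is the mean of eight values, each the tallest
#' stem within one of the 8 zones formed by two adjacent quadrats (quadrats
#' 1-2, 3-4, ..., 15-16); zones without stems are dropped from the mean.
#'
#' @param stems A `stem_table` for a single plot.
#' @param age Stand age in years (or `NA` for stands of unknown age).
#' @return A one-row data.frame with columns `Age`, `Hgt`, `S_T`, `S_U`,
#'   `Dn_T`, `Dn_U`, `BA_T`, `BA_U`, `CC_T`, `CC_U`, `H_T`, `H_U`, `D_T`,
#'   `D_U`.
#' @export
compute_attributes <- function(stems, age = NA) {
  if (nrow(stems) == 0) stop("stems must be non-empty")
  if (is.null(stems$expansion)) stems <- scale_to_hectare(stems)
  if (any(is.na(stems$height_m))) stop("missing heights: Hgt not computable")
  total <- attribute_set(stems)
  upper <- attribute_set(upper_set(stems))
  zone <- ceiling(stems$quadrat / 2)
  hgt <- mean(tapply(stems$height_m, zone, max))
  data.frame(
    Age = age, Hgt = hgt,
    S_T = total$S, S_U = upper$S,
    Dn_T = total$Dn, Dn_U = upper$Dn,
    BA_T = total$BA, BA_U = upper$BA,
    CC_T = total$CC, CC_U = upper$CC,
    H_T = total$H, H_U = upper$H,
    D_T = total$D, D_U = upper$D
  )
}

#' Attribute table for a multi-plot stem inventory
#'
#' Applies [compute_attributes()] to each plot of a stem table.
#'
#' @param stems A `stem_table` covering one or more plots.
#' @param ages Named or positional vector of stand ages matching the
#'   distinct `plot_id` values.
#' @return A data.frame with `plot_id` and the attribute columns.
#' @export
attribute_table <- function(stems, ages) {
  ids <- sort(unique(stems$plot_id))
  if (length(ages) != length(ids)) {
    stop("ages must supply one value per plot")
  }
  rows <- lapply(seq_along(ids), function(i) {
    rec <- compute_attributes(stems[stems$plot_id == ids[i], , drop = FALSE],
                              age = ages[i])
    cbind(plot_id = ids[i], rec)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

attribute_columns <- c("Age", "Hgt", "S_T", "S_U", "Dn_T", "Dn_U",
                       "BA_T", "BA_U", "CC_T", "CC_U",
                       "H_T", "H_U", "D_T", "D_U")

#' Read and validate an attribute table
#'
#' Reads a CSV with the standard attribute column set (see
#' [compute_attributes()]). The `Age` column may contain the code `"M"` for
#' a mature-forest reference plot; it is parsed to `NA` years and reported
#' in the `mature` column. Row-level invariants are checked: upper-set
#' values cannot exceed total-set values, Shannon diversity is non-negative,
#' Simpson dominance lies in (0, 1], and a single-species plot (S = 1) must
#' have H' = 0 and D' = 1.
#'
#' @param path CSV file path.
#' @return A validated data.frame with numeric `Age` and logical `mature`.
#' @export
read_attribute_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(attribute_columns, names(df))
  if (length(missing) > 0) {
    stop("attribute table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  mature <- df$Age %in% c("M", "m")
  age <- suppressWarnings(as.numeric(as.character(df$Age)))
  if (any(is.na(age) & !mature)) {
    stop("non-numeric Age in rows: ",
         paste(which(is.na(age) & !mature), collapse = ", "))
  }
  df$Age <- age
  df$mature <- mature
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    bad <- character(0)
    if (r$BA_U > r$BA_T) bad <- c(bad, "BA_U > BA_T")
    if (r$CC_U > r$CC_T) bad <- c(bad, "CC_U > CC_T")
    if (r$S_U > r$S_T) bad <- c(bad, "S_U > S_T")
    if (r$Dn_U > r$Dn_T) bad <- c(bad, "Dn_U > Dn_T")
    if (r$H_T < 0 || r$H_U < 0) bad <- c(bad, "H' < 0")
    if (r$D_T <= 0 || r$D_T > 1 || r$D_U <= 0 || r$D_U > 1) {
      bad <- c(bad, "D' outside (0, 1]")
    }
    if (r$S_U == 1 && (r$H_U != 0 || r$D_U != 1)) {
      bad <- c(bad, "S_U = 1 requires H'_U = 0 and D'_U = 1")
    }
    if (r$S_T == 1 && (r$H_T != 0 || r$D_T != 1)) {
      bad <- c(bad, "S_T = 1 requires H'_T = 0 and D'_T = 1")
    }
    if (length(bad) > 0) {
      stop("invalid attribute row ", i, ": ", paste(bad, collapse = "; "))
    }
  }
  df
}

#' Reference chronosequence attribute table
#'
#' Path to the bundled attribute table for a 15-plot dry-forest
#' chronosequence (14 fallows aged 2-60 years plus one mature stand, coded
#' `"M"`), used as a realistic response dataset in examples and tests.
#'
#' @return File path of the bundled CSV.
#' @export
chronosequence_path <- function() {
  system.file("extdata", "chronosequence_attributes.csv",
              package = "glcmveg", mustWork = TRUE)
}
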