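#' Normalized difference vegetation index
#'
#' `NDVI = (IR - RED) / (IR + RED)`, computed per pixel. Pixels where the
#' denominator is zero, or where either input is missing, are masked (`NA`).
#'
#' @param ir,red Reflectance matrices in \[0,1\] with identical dimensions.
#' @return A matrix of NDVI values in \[-1, 1\] with `NA` where undefined.
#' @export
ndvi <- function(ir, red) {
  if (!all(dim(ir) == dim(red))) stop("ir and red must share dimensions")
  den <- ir + red
  out <- (ir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Enhanced vegetation index
#'
#' `EVI = G * (IR - RED) / (IR + C1*RED - C2*BLUE + L)` with the standard
#' coefficients C1 = 6, C2 = 7.5, soil-adjustment L = 1 and gain G = 2.5.
#' Pixels with a non-positive denominator are masked rather than clipped, so
#' that spurious extremes never enter the texture quantization; masked input
#' pixels propagate to the output.
#'
#' @param ir,red,blue Reflectance matrices with identical dimensions.
#' @param g Gain factor (default 2.5). Because texture statistics are
#'   computed after per-layer min-max quantization, any fixed positive gain
#'   leaves all GLCM features unchanged.
#' @param c1,c2,l Aerosol-resistance coefficients and canopy background
#'   adjustment.
#' @return A matrix of EVI values with `NA` where undefined.
#' @export
evi <- function(ir, red, blue, g = 2.5, c1 = 6, c2 = 7.5, l = 1) {
  if (!all(dim(ir) == dim(red)) || !all(dim(ir) == dim(blue))) {
    stop("ir, red and blue must share dimensions")
  }
  den <- ir + c1 * red - c2 * blue + l
  out <- g * (ir - red) / den
  out[!is.na(den) & den <= 0] <- NA_real_
  out
}

#' Build the four-layer analysis stack
#'
#' Assembles the layers from which all texture features are extracted: the
#' raw RED and near-infrared (IR) reflectance bands plus the NDVI and EVI
#' index layers.
#'
#' @param scene A `reflectance_scene` (see [generate_scene()]).
#' @return A named list of matrices `RED`, `IR`, `NDVI`, `EVI`; masked
#'   (undefined) pixels are `NA`.
#' @export
layer_stack <- function(scene) {
  b <- scene$bands
  list(
    RED = b$RED,
    IR = b$IR,
    NDVI = ndvi(b$IR, b$RED),
    EVI = evi(b$IR, b$RED, b$BLUE)
  )
}
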