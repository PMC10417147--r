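#' Piecewise-linear HU calibration tables
#'
#' Default mass-density calibration: air (-1000 HU -> 0.001 g/cm3), water
#' (0 HU -> 1.0), dense bone (1500 HU -> 1.85), linear between anchors and
#' continued with the terminal slopes. The stopping-power calibration uses
#' the same shape with bone at 1.55 relative to water.
#'
#' @param hu Numeric anchor HU values, strictly increasing.
#' @param value Numeric anchor outputs, strictly increasing.
#' @return A list of class `hu_calibration`.
#' @export
hu_calibration <- function(hu, value) {
  if (length(hu) != length(value) || length(hu) < 2L) {
    stop("need >= 2 calibration anchors", call. = FALSE)
  }
  if (is.unsorted(hu, strictly = TRUE) || is.unsorted(value, strictly = TRUE)) {
    stop("calibration table must be strictly monotone", call. = FALSE)
  }
  structure(list(hu = as.numeric(hu), value = as.numeric(value)),
            class = "hu_calibration")
}

#' @rdname hu_calibration
#' @export
density_calibration <- function() {
  hu_calibration(c(-1000, 0, 1500), c(0.001, 1.0, 1.85))
}

#' @rdname hu_calibration
#' @export
spr_calibration <- function() {
  hu_calibration(c(-1000, 0, 1500), c(0.001, 1.0, 1.55))
}

apply_calibration <- function(hu_values, calibration, floor = 1e-4) {
  pmax(pwl_interp(calibration$hu, calibration$value, hu_values), floor)
}

#' Convert an HU image to mass density
#'
#' @param img HU `volume_image`.
#' @param calibration An [hu_calibration()]; default [density_calibration()].
#' @return `volume_image` of mass density (g/cm3), kind `"DENSITY"`.
#' @export
to_density <- function(img, calibration = density_calibration()) {
  stopifnot_volume(img)
  if (!inherits(calibration, "hu_calibration")) {
    stop("`calibration` must be an hu_calibration", call. = FALSE)
  }
  rho <- apply_calibration(as.vector(img$voxels), calibration)
  volume_image(array(rho, dim = dim(img$voxels)), img$spacing, img$origin,
               "DENSITY")
}

#' Convert an HU image to relative stopping power
#'
#' @param img HU `volume_image`.
#' @param calibration An [hu_calibration()]; default [spr_calibration()].
#' @return `volume_image` of stopping-power ratio (water = 1), kind
#'   `"DENSITY"` repurposed as unitless SPR.
#' @export
hu_to_spr <- function(img, calibration = spr_calibration()) {
  stopifnot_volume(img)
  if (!inherits(calibration, "hu_calibration")) {
    stop("`calibration` must be an hu_calibration", call. = FALSE)
  }
  spr <- apply_calibration(as.vector(img$voxels), calibration)
  volume_image(array(spr, dim = dim(img$voxels)), img$spacing, img$origin,
               "DENSITY")
}
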