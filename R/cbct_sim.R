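#' Specification of CBCT acquisition degradations
#'
#' Emulates, in image space, the ways cone-beam gray values differ from
#' calibrated CT numbers: a monotone gray-value distortion (gain/offset plus
#' optional mild quadratic nonlinearity), a smooth low-frequency shading
#' field (cupping / scatter-like artifacts), an optional localized negative
#' streak bias between the shoulders (photon starvation / beam hardening
#' surrogate), white noise, and truncation to a cylindrical field of view
#' (default diameter 260 mm, the clinical CBCT FOV).
#'
#' @param fov_diameter_mm Axial FOV diameter in mm (`Inf` = no truncation).
#' @param gain,offset,quad Gray map `g(h) = gain * h + offset + quad * h^2`;
#'   must be strictly monotone over HU `[-1000, 3000]`.
#' @param shading_amplitude Peak shading magnitude, gray units.
#' @param shading_wavelength_mm Spatial wavelength of the shading field;
#'   the default 400 mm gives a cupping-like bowl varying across the whole
#'   field of view, the regime the low-pass artifact correction targets.
#' @param noise_sd White-noise standard deviation, gray units.
#' @param shoulder_streak_amplitude Peak negative bias between the shoulder
#'   surrogates, gray units.
#' @param seed Integer seed (phases and noise are pure functions of it).
#' @return An object of class `cbct_degradation_spec`.
#' @export
cbct_degradation_spec <- function(fov_diameter_mm = 260,
                                  gain = 0.8, offset = 40, quad = 0,
                                  shading_amplitude = 60,
                                  shading_wavelength_mm = 400,
                                  noise_sd = 15,
                                  shoulder_streak_amplitude = 0,
                                  seed = 1L) {
  spec <- structure(list(fov_diameter_mm = fov_diameter_mm, gain = gain,
                         offset = offset, quad = quad,
                         shading_amplitude = shading_amplitude,
                         shading_wavelength_mm = shading_wavelength_mm,
                         noise_sd = noise_sd,
                         shoulder_streak_amplitude = shoulder_streak_amplitude,
                         seed = as.integer(seed)),
                    class = "cbct_degradation_spec")
  dg <- gray_map_derivative(spec, c(-1000, 3000))
  if (any(dg <= 0)) {
    stop("gray map is not strictly monotone over [-1000, 3000] HU", call. = FALSE)
  }
  spec
}

gray_map_derivative <- function(spec, h) spec$gain + 2 * spec$quad * h

apply_gray_map <- function(spec, h) spec$gain * h + spec$offset + spec$quad * h^2

#' Simulate a CBCT from a CT-class image
#'
#' `CBCT = gray_map(HU) + shading + shoulder_streaks + noise`, truncated to
#' the cylindrical field of view (outside-FOV voxels carry the gray value of
#' air). The exact inverse of the planted gray map is returned as a
#' [conversion_function()] so downstream conversion recovery can be scored.
#' Deterministic given `deg$seed`.
#'
#' @param ct `volume_image` in HU (typically the treatment-day CT).
#' @param deg A [cbct_degradation_spec()].
#' @param structures Optional `structure_set` with a `shoulders` mask; only
#'   needed when `shoulder_streak_amplitude > 0`.
#' @return `list(cbct = volume_image (CBCT_GRAY), fov = logical mask,
#'   true_inverse = conversion_function)`.
#' @export
simulate_cbct <- function(ct, deg = cbct_degradation_spec(), structures = NULL) {
  stopifnot_volume(ct)
  if (ct$kind != "HU") stop("`ct` must be an HU image", call. = FALSE)
  if (!inherits(deg, "cbct_degradation_spec")) {
    stop("`deg` must be a cbct_degradation_spec", call. = FALSE)
  }
  g <- grid_of(ct)
  if (deg$shading_wavelength_mm < 10 * max(g$spacing)) {
    stop("shading wavelength must be well above the voxel size", call. = FALSE)
  }
  co <- grid_coords(g)
  gray <- apply_gray_map(deg, as.vector(ct$voxels))

  with_seed(deg$seed, {
    if (deg$shading_amplitude > 0) {
      ph <- stats::runif(3, 0, 2 * pi)
      lam <- deg$shading_wavelength_mm
      shading <- deg$shading_amplitude *
        (0.7 * cos(2 * pi * co[, 1] / lam + ph[1]) *
           cos(2 * pi * co[, 2] / lam + ph[2]) +
           0.3 * cos(2 * pi * co[, 3] / (1.5 * lam) + ph[3]))
      gray <- gray + shading
    }
    if (deg$shoulder_streak_amplitude > 0) {
      if (is.null(structures) || is.null(structures$masks[["shoulders"]])) {
        stop("shoulder streaks need `structures` with a 'shoulders' mask", call. = FALSE)
      }
      ctr <- mask_centroid(structures$masks[["shoulders"]], g)
      streak <- -deg$shoulder_streak_amplitude *
        exp(-((co[, 3] - ctr[3]) / 22)^2) * exp(-((co[, 2] - ctr[2]) / 28)^2) *
        taper_weight(abs(co[, 1]), 130, 175)
      gray <- gray + streak
    }
    if (deg$noise_sd > 0) {
      gray <- gray + stats::rnorm(length(gray), sd = deg$noise_sd)
    }
  })

  center_xy <- g$origin[1:2] + (g$shape[1:2] - 1) * g$spacing[1:2] / 2
  if (is.finite(deg$fov_diameter_mm)) {
    fov <- (co[, 1] - center_xy[1])^2 + (co[, 2] - center_xy[2])^2 <=
      (deg$fov_diameter_mm / 2)^2
  } else {
    fov <- rep(TRUE, nrow(co))
  }
  air_gray <- apply_gray_map(deg, -1000)
  gray[!fov] <- air_gray

  hu_anchors <- c(-1000, -200, 0, 100, 300, 700, 1500, 3000)
  inv <- conversion_function(apply_gray_map(deg, hu_anchors), hu_anchors)

  list(cbct = volume_image(array(gray, dim = g$shape), g$spacing, g$origin,
                           "CBCT_GRAY"),
       fov = array(fov, dim = g$shape),
       true_inverse = inv)
}
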