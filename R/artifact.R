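#' Estimate the low-frequency artifact correction map
#'
#' Difference-map artifact identification: the converted CBCT minus the
#' deformed planning CT, low-pass filtered with a physical-units Gaussian
#' (mask-normalized so values outside the mask do not bleed in), then
#' smoothly feathered to zero at the mask edge. Subtracting the resulting
#' map from the converted CBCT removes shading/cupping-style artifacts
#' while leaving sharp anatomical detail untouched.
#'
#' @param converted_cbct CBCT already converted to HU (`volume_image`).
#' @param pct_deformed Planning CT deformed to the CBCT (`volume_image`).
#' @param mask Logical mask over which the difference is trusted (normally
#'   the CBCT field of view).
#' @param sigma_mm Gaussian low-pass standard deviation, mm (default 15 mm:
#'   structure varying over less than a couple of centimetres is treated as
#'   anatomy, not artifact, while field-of-view-scale shading passes nearly
#'   unattenuated).
#' @param feather_mm Feather band at the mask edge, mm.
#' @param clip_hu Robustness gate: voxels whose absolute difference exceeds
#'   this are genuine anatomical change (filled cavities, misregistered
#'   bone) and are excluded from the difference map rather than smeared
#'   into the correction.
#' @return An object of class `artifact_map`: `map` (HU array, zero outside
#'   the mask), `sigma_mm`, `feather_mm`.
#' @export
estimate_artifact_map <- function(converted_cbct, pct_deformed, mask,
                                  sigma_mm = 15, feather_mm = 10,
                                  clip_hu = 200) {
  stopifnot_volume(converted_cbct); stopifnot_volume(pct_deformed)
  if (!same_grid(converted_cbct, pct_deformed)) {
    stop("images must share a grid", call. = FALSE)
  }
  if (is_volume_image(mask)) mask <- mask$voxels > 0.5
  g <- grid_of(converted_cbct)
  diffmap <- converted_cbct$voxels - pct_deformed$voxels
  trust <- mask & (abs(diffmap) < clip_hu)
  if (!any(trust)) trust <- mask
  # two-pass robust estimate: voxels deviating strongly from the first-pass
  # low-frequency field are residual anatomy mismatch, not artifact
  lp <- masked_gaussian_smooth(diffmap, trust, sigma_mm, g$spacing)
  trust2 <- trust & (abs(diffmap - lp) < clip_hu / 2)
  if (any(trust2)) {
    lp <- masked_gaussian_smooth(diffmap, trust2, sigma_mm, g$spacing)
  }
  w <- feather_weight(mask, feather_mm, g$spacing)
  structure(list(map = lp * w, sigma_mm = sigma_mm, feather_mm = feather_mm,
                 grid = g),
            class = "artifact_map")
}

#' @export
print.artifact_map <- function(x, ...) {
  cat(sprintf("<artifact_map> sigma %.4g mm, feather %.4g mm, range [%.4g, %.4g] HU\n",
              x$sigma_mm, x$feather_mm, min(x$map), max(x$map)))
  invisible(x)
}

#' Fraction of spatial spectral power below a cutoff frequency
#'
#' Diagnostic for the artifact map's low-frequency invariant: the share of
#' (non-DC) power at spatial frequencies below `cutoff_per_mm`.
#'
#' @param a 3D array.
#' @param spacing Voxel spacing, mm.
#' @param cutoff_per_mm Cutoff spatial frequency (cycles/mm).
#' @return Scalar in `[0, 1]`.
#' @export
spectral_low_fraction <- function(a, spacing, cutoff_per_mm = 1 / 50) {
  d <- dim(a)
  p <- Mod(stats::fft(a))^2
  fr <- lapply(1:3, function(ax) {
    n <- d[ax]
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * spacing[ax])
    f[seq_len(n)]
  })
  f2 <- outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+")
  p[1] <- 0  # drop DC
  tot <- sum(p)
  if (tot == 0) return(1)
  sum(p[f2 <= cutoff_per_mm^2]) / tot
}
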