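#' Squared Euclidean distance transform
#'
#' Exact squared distance (mm2) from each voxel centre to the nearest
#' background (`FALSE`) voxel centre, computed by separable min-convolution
#' with squared-distance parabolas along each axis. Anisotropic spacing is
#' respected, which matters for thick-slice geometries. `max_dist` truncates
#' the per-axis search radius: all returned values `<= max_dist^2` are exact,
#' larger values are lower-bounded by `max_dist^2`, which is sufficient (and
#' much faster) when the transform is only thresholded.
#'
#' @param mask Logical 3D array (`TRUE` = foreground).
#' @param spacing Numeric length-3, mm.
#' @param max_dist Optional truncation radius in mm (default exact everywhere).
#' @return Numeric 3D array of squared distances in mm2 (0 on background).
#' @export
sq_distance_transform <- function(mask, spacing, max_dist = Inf) {
  d <- dim(mask)
  f <- array(ifelse(mask, Inf, 0), dim = d)
  for (ax in 1:3) {
    f <- minconv_axis1(aperm(f, c(ax, setdiff(1:3, ax))), spacing[ax], max_dist)
    # undo the permutation: aperm with inverse ordering
    ord <- c(ax, setdiff(1:3, ax))
    f <- aperm(f, order(ord))
  }
  f
}

# exact 1D min-convolution with (k*s)^2 along the first axis, vectorized
# over all remaining lines; operates on the ORIGINAL values so a single
# pass over offsets k is exact.
minconv_axis1 <- function(a, s, max_dist = Inf) {
  d <- dim(a)
  n <- d[1]
  if (n == 1L) return(a)
  A <- matrix(a, nrow = n)
  D <- A
  kmax <- n - 1L
  if (is.finite(max_dist)) kmax <- min(kmax, ceiling(max_dist / s) + 1L)
  for (k in seq_len(kmax)) {
    c2 <- (k * s)^2
    lo <- 1:(n - k); hi <- (k + 1):n
    D[hi, ] <- pmin(D[hi, , drop = FALSE], A[lo, , drop = FALSE] + c2)
    D[lo, ] <- pmin(D[lo, , drop = FALSE], A[hi, , drop = FALSE] + c2)
  }
  array(D, dim = d)
}

#' Retract (erode) a field-of-view mask by a physical margin
#'
#' Morphological erosion of a binary region by a Euclidean ball of radius
#' `margin_mm`, implemented by thresholding the distance transform in
#' physical units so anisotropic slice spacing is handled correctly. Used to
#' build the focus region that keeps deformable registration away from the
#' CBCT field-of-view edge (default retraction 20 mm).
#'
#' @param fov_mask Logical 3D array, or a `volume_image` whose voxels are
#'   interpreted as a mask (`> 0.5`).
#' @param margin_mm Erosion margin in mm, `>= 0`.
#' @param spacing Numeric length-3 spacing in mm; required when `fov_mask`
#'   is a plain array.
#' @return Logical array of the eroded region (subset of the input).
#' @export
retract_fov <- function(fov_mask, margin_mm, spacing = NULL) {
  if (is_volume_image(fov_mask)) {
    spacing <- fov_mask$spacing
    fov_mask <- fov_mask$voxels > 0.5
  }
  if (is.null(spacing)) stop("`spacing` is required for a plain-array mask", call. = FALSE)
  if (!any(fov_mask)) stop("`fov_mask` is empty", call. = FALSE)
  if (margin_mm < 0) stop("`margin_mm` must be >= 0", call. = FALSE)
  if (margin_mm == 0) return(fov_mask & TRUE)
  d2 <- sq_distance_transform(fov_mask, spacing, max_dist = margin_mm + max(spacing))
  out <- fov_mask & (d2 > margin_mm^2)
  if (!any(out)) {
    stop(sprintf("empty focus region: erosion by %.1f mm removed the whole mask",
                 margin_mm), call. = FALSE)
  }
  out
}

#' Signed feather weight near a mask boundary
#'
#' Linear ramp from 0 at the mask edge to 1 at `band_mm` inside the mask;
#' exactly 0 outside the mask. Used for the corrected-CBCT transition band
#' at the field-of-view boundary.
#'
#' @inheritParams retract_fov
#' @param band_mm Feather width in mm.
#' @return Numeric array in `[0, 1]`.
#' @keywords internal
feather_weight <- function(fov_mask, band_mm, spacing) {
  if (band_mm <= 0) return(array(as.numeric(fov_mask), dim = dim(fov_mask)))
  d2 <- sq_distance_transform(fov_mask, spacing, max_dist = band_mm + max(spacing))
  w <- pmin(sqrt(d2) / band_mm, 1)
  array(w * fov_mask, dim = dim(fov_mask))
}

#' Signed distance function of a binary mask
#'
#' Positive inside the mask, negative outside, zero-crossing at the
#' boundary (half a voxel outside the outermost foreground centres).
#' Distances are capped at `cap_mm`, which is ample for boundary tracking.
#'
#' @param mask Logical 3D array.
#' @param spacing Numeric length-3, mm.
#' @param cap_mm Saturation distance, mm.
#' @return Numeric array of signed distances in mm.
#' @export
signed_distance <- function(mask, spacing, cap_mm = 12) {
  inside <- sqrt(sq_distance_transform(mask, spacing, max_dist = cap_mm))
  outside <- sqrt(sq_distance_transform(!mask, spacing, max_dist = cap_mm))
  d <- inside - outside
  array(pmin(pmax(d, -cap_mm), cap_mm), dim = dim(mask))
}

#' Number of 6-connected components of a mask
#'
#' Frontier-propagation flood fill (vectorized array shifts), adequate for
#' validation of moderate masks.
#'
#' @param mask Logical 3D array.
#' @return Integer component count.
#' @export
n_components <- function(mask) {
  remaining <- mask
  count <- 0L
  while (any(remaining)) {
    count <- count + 1L
    seed <- which(remaining)[1]
    comp <- array(FALSE, dim = dim(mask))
    comp[seed] <- TRUE
    repeat {
      grown <- dilate6(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    remaining <- remaining & !comp
  }
  count
}

dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}
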