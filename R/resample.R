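#' Sample a volume at arbitrary physical points
#'
#' Core interpolation primitive. Points outside the source extent receive the
#' padding value; with linear interpolation, corner samples falling outside
#' the grid also contribute the padding value, so the transition to the pad
#' level is continuous.
#'
#' @param img A `volume_image`.
#' @param pts n x 3 matrix of physical coordinates (mm).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param pad Value used outside the source extent. Defaults to -1000 for HU
#'   images (physical air surround) and 0 otherwise.
#' @return Numeric vector of sampled values, one per row of `pts`.
#' @export
sample_at <- function(img, pts, interpolation = c("linear", "nearest"),
                      pad = NULL) {
  stopifnot_volume(img)
  interpolation <- match.arg(interpolation)
  if (is.null(pad)) pad <- default_pad(img$kind)
  a <- img$voxels
  dims <- dim(a)
  # continuous 1-based array coordinates
  f1 <- (pts[, 1] - img$origin[1]) / img$spacing[1] + 1
  f2 <- (pts[, 2] - img$origin[2]) / img$spacing[2] + 1
  f3 <- (pts[, 3] - img$origin[3]) / img$spacing[3] + 1
  if (interpolation == "nearest") {
    i <- round(f1); j <- round(f2); k <- round(f3)
    return(gather3(a, i, j, k, pad))
  }
  i0 <- floor(f1); j0 <- floor(f2); k0 <- floor(f3)
  wx <- f1 - i0; wy <- f2 - j0; wz <- f3 - k0
  v000 <- gather3(a, i0,     j0,     k0,     pad)
  v100 <- gather3(a, i0 + 1, j0,     k0,     pad)
  v010 <- gather3(a, i0,     j0 + 1, k0,     pad)
  v110 <- gather3(a, i0 + 1, j0 + 1, k0,     pad)
  v001 <- gather3(a, i0,     j0,     k0 + 1, pad)
  v101 <- gather3(a, i0 + 1, j0,     k0 + 1, pad)
  v011 <- gather3(a, i0,     j0 + 1, k0 + 1, pad)
  v111 <- gather3(a, i0 + 1, j0 + 1, k0 + 1, pad)
  (v000 * (1 - wx) + v100 * wx) * (1 - wy) * (1 - wz) +
    (v010 * (1 - wx) + v110 * wx) * wy * (1 - wz) +
    (v001 * (1 - wx) + v101 * wx) * (1 - wy) * wz +
    (v011 * (1 - wx) + v111 * wx) * wy * wz
}

default_pad <- function(kind) if (kind == "HU") -1000 else 0

# TRUE where physical points fall inside the volume's voxel-centre extent
in_extent <- function(img, pts) {
  g <- if (is_volume_image(img)) grid_of(img) else img
  hi <- g$origin + (g$shape - 1) * g$spacing
  pts[, 1] >= g$origin[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= g$origin[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= g$origin[3] & pts[, 3] <= hi[3]
}

# gather with out-of-bounds -> pad
gather3 <- function(a, i, j, k, pad) {
  d <- dim(a)
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep.int(pad, length(i))
  if (any(ok)) {
    lin <- i[ok] + (j[ok] - 1) * d[1] + (k[ok] - 1) * (d[1] * d[2])
    out[ok] <- a[lin]
  }
  out
}

#' Resample a volume onto a target grid
#'
#' Values are taken at the target voxel centres by interpolation in the
#' source volume; target voxels outside the source extent get the padding
#' value. Use nearest-neighbour interpolation for masks and linear for
#' intensity images.
#'
#' @param img A `volume_image`.
#' @param target A `grid_spec` (or `volume_image` whose grid is used).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param pad Out-of-extent fill value; default -1000 HU for CT-class images.
#' @return A `volume_image` on the target grid with the same intensity kind.
#' @export
resample_to_grid <- function(img, target, interpolation = c("linear", "nearest"),
                             pad = NULL) {
  stopifnot_volume(img)
  interpolation <- match.arg(interpolation)
  if (is_volume_image(target)) target <- grid_of(target)
  if (!inherits(target, "grid_spec")) stop("`target` must be a grid_spec", call. = FALSE)
  if (same_grid(img, target)) {
    return(volume_image(img$voxels, img$spacing, img$origin, img$kind))
  }
  vals <- sample_at(img, grid_coords(target), interpolation, pad)
  volume_image(array(vals, dim = target$shape), target$spacing, target$origin,
               img$kind)
}

#' Resample a binary mask onto a target grid
#'
#' Nearest-neighbour resampling that preserves logical type.
#'
#' @param mask Logical 3D array.
#' @param source `grid_spec` of the mask.
#' @param target `grid_spec` to resample onto.
#' @return Logical array with the target shape.
#' @export
resample_mask <- function(mask, source, target) {
  img <- volume_image(array(as.numeric(mask), dim = dim(mask)),
                      source$spacing, source$origin, "DOSE")
  out <- resample_to_grid(img, target, "nearest", pad = 0)
  array(out$voxels > 0.5, dim = target$shape)
}
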