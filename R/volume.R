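#' Volumetric scalar image
#'
#' The basic container used throughout the package: a 3D scalar grid with
#' voxel spacing (mm), a physical origin (mm) and an intensity kind. Axes
#' follow the radiological convention X = right-left, Y = anterior-posterior,
#' Z = inferior-superior. Voxel indices are 0-based in physical terms:
#' the centre of voxel `[i, j, k]` (R's 1-based `[i+1, j+1, k+1]`) sits at
#' `origin + c(i, j, k) * spacing`.
#'
#' @param voxels 3D numeric array of voxel values.
#' @param spacing Numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin Numeric length-3, physical position (mm) of the first voxel
#'   centre.
#' @param kind Intensity kind: `"HU"` for CT-class images, `"CBCT_GRAY"` for
#'   uncalibrated cone-beam gray values, `"DOSE"` for relative dose,
#'   `"DENSITY"` for mass density (g/cm3).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing, origin = c(0, 0, 0), kind = "HU") {
  kind <- match.arg(kind, intensity_kinds())
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  if (any(!is.finite(voxels))) {
    stop("voxel values must all be finite", call. = FALSE)
  }
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, kind = kind),
    class = "volume_image"
  )
}

#' @export
#' @rdname volume_image
intensity_kinds <- function() c("HU", "CBCT_GRAY", "DOSE", "DENSITY")

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, kind %s\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$kind
  ))
  cat(sprintf(
    "  origin (%.4g, %.4g, %.4g) mm, value range [%.4g, %.4g]\n",
    x$origin[1], x$origin[2], x$origin[3], min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

is_volume_image <- function(x) inherits(x, "volume_image")

stopifnot_volume <- function(x, arg = deparse(substitute(x))) {
  if (!is_volume_image(x)) stop(sprintf("`%s` must be a volume_image", arg), call. = FALSE)
  invisible(x)
}

#' Grid geometry specification
#'
#' Shape, spacing and origin of a voxel grid, without voxel data.
#'
#' @param shape Integer length-3, voxels per axis.
#' @param spacing Numeric length-3, mm per axis.
#' @param origin Numeric length-3, mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    stop("`shape` must be three positive integers", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s voxels @ %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @rdname grid_spec
#' @param img A `volume_image`.
#' @export
grid_of <- function(img) {
  stopifnot_volume(img)
  grid_spec(dim(img$voxels), img$spacing, img$origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- if (is_volume_image(a)) grid_of(a) else a
  gb <- if (is_volume_image(b)) grid_of(b) else b
  all(ga$shape == gb$shape) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

#' Physical coordinates of every voxel centre
#'
#' @param grid A `grid_spec` (or `volume_image`).
#' @return An n-voxel x 3 matrix of mm coordinates in array (column-major)
#'   order.
#' @keywords internal
grid_coords <- function(grid) {
  if (is_volume_image(grid)) grid <- grid_of(grid)
  sh <- grid$shape
  ax <- lapply(1:3, function(a) grid$origin[a] + (seq_len(sh[a]) - 1) * grid$spacing[a])
  cbind(
    rep(ax[[1]], times = sh[2] * sh[3]),
    rep(rep(ax[[2]], each = sh[1]), times = sh[3]),
    rep(ax[[3]], each = sh[1] * sh[2])
  )
}

#' Centroid of a binary mask in physical coordinates
#'
#' @param mask Logical 3D array.
#' @param grid `grid_spec` describing the mask's grid.
#' @return Length-3 numeric, mm.
#' @export
mask_centroid <- function(mask, grid) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  sh <- grid$shape
  i <- (idx - 1L) %% sh[1]
  j <- ((idx - 1L) %/% sh[1]) %% sh[2]
  k <- (idx - 1L) %/% (sh[1] * sh[2])
  grid$origin + c(mean(i), mean(j), mean(k)) * grid$spacing
}

#' Physical volume of a binary mask
#'
#' @inheritParams mask_centroid
#' @return Volume in cm3.
#' @export
mask_volume_cc <- function(mask, grid) {
  sum(mask) * prod(grid$spacing) / 1000
}
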