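#' Dense deformation field
#'
#' Per-voxel displacement vectors in mm on a stated grid, in the pull-back
#' convention: warping samples the moving image at
#' `position + displacement(position)`. When a domain (focus) mask is
#' supplied the field is identity (zero) outside it.
#'
#' @param displacements 4D array `shape x 3` of mm displacements.
#' @param grid `grid_spec` the field lives on.
#' @param domain Optional logical focus mask; displacements outside are
#'   forced to exactly zero.
#' @return An object of class `deformation_field`.
#' @export
deformation_field <- function(displacements, grid, domain = NULL) {
  d <- dim(displacements)
  if (length(d) != 4L || d[4] != 3L || !all(d[1:3] == grid$shape)) {
    stop("`displacements` must be a shape x 3 array on `grid`", call. = FALSE)
  }
  if (any(!is.finite(displacements))) stop("displacements must be finite", call. = FALSE)
  if (!is.null(domain)) {
    keep <- as.numeric(domain)
    for (c3 in 1:3) {
      displacements[, , , c3] <- displacements[, , , c3] * array(keep, dim = d[1:3])
    }
  }
  structure(list(displacements = displacements, grid = grid, domain = domain),
            class = "deformation_field")
}

#' @rdname deformation_field
#' @param shape,spacing,origin Grid geometry (alternative to `grid`).
#' @export
identity_field <- function(grid) {
  deformation_field(array(0, dim = c(grid$shape, 3L)), grid)
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$displacements[, , , 1]^2 + x$displacements[, , , 2]^2 +
                x$displacements[, , , 3]^2)
  cat(sprintf("<deformation_field> on %s grid, |u| max %.2f mm, mean %.3f mm%s\n",
              paste(x$grid$shape, collapse = "x"), max(mag), mean(mag),
              if (!is.null(x$domain)) sprintf(", focus %d voxels", sum(x$domain)) else ""))
  invisible(x)
}

field_magnitude <- function(field) {
  sqrt(field$displacements[, , , 1]^2 + field$displacements[, , , 2]^2 +
         field$displacements[, , , 3]^2)
}

#' Warp an image with a deformation field (pull-back)
#'
#' Each output voxel is sampled from `img` at its own position plus the
#' field's displacement there. Use linear interpolation for intensities and
#' nearest for label images; binary masks are better served by
#' [map_contours()].
#'
#' @param img A `volume_image` on the field's grid (or resampled to it).
#' @param field A `deformation_field`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param pad Out-of-extent value (defaults by intensity kind).
#' @return Warped `volume_image` on the field's grid.
#' @export
warp_image <- function(img, field, interpolation = c("linear", "nearest"),
                       pad = NULL) {
  stopifnot_volume(img)
  interpolation <- match.arg(interpolation)
  if (!same_grid(img, field$grid)) {
    stop("image grid does not match the deformation-field grid", call. = FALSE)
  }
  pts <- grid_coords(field$grid)
  n <- nrow(pts)
  pts <- pts + cbind(as.vector(field$displacements[, , , 1]),
                     as.vector(field$displacements[, , , 2]),
                     as.vector(field$displacements[, , , 3]))
  vals <- sample_at(img, pts, interpolation, pad)
  volume_image(array(vals, dim = field$grid$shape), field$grid$spacing,
               field$grid$origin, img$kind)
}

#' Warp every mask of a structure set through a deformation field
#'
#' Masks are warped by linear interpolation of their signed distance
#' function followed by thresholding at zero. Unlike nearest-neighbour
#' lookup or indicator thresholding, this tracks sub-voxel boundary motion,
#' so small planted volume changes survive coarse voxelization; roles are
#' preserved. A mask that comes back empty raises a warning rather than
#' disappearing silently.
#'
#' @param structures A `structure_set` on the field's grid.
#' @param field A `deformation_field`.
#' @return A `structure_set` of warped masks.
#' @export
map_contours <- function(structures, field) {
  g <- field$grid
  if (!same_grid(structures$grid, g)) {
    stop("structure grid does not match the deformation-field grid", call. = FALSE)
  }
  pts <- grid_coords(g)
  pts <- pts + cbind(as.vector(field$displacements[, , , 1]),
                     as.vector(field$displacements[, , , 2]),
                     as.vector(field$displacements[, , , 3]))
  masks <- lapply(names(structures$masks), function(nm) {
    m <- structures$masks[[nm]]
    if (!any(m)) return(m)
    sd_img <- volume_image(signed_distance(m, g$spacing), g$spacing, g$origin,
                           "DOSE")
    out <- array(sample_at(sd_img, pts, "linear", pad = -1e6) > 0,
                 dim = g$shape)
    if (!any(out)) {
      warning(sprintf("mask '%s' is empty after warping", nm), call. = FALSE)
    }
    out
  })
  names(masks) <- names(structures$masks)
  structure_set(masks, structures$roles, g, check_fov_connectivity = FALSE)
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration `v_{k+1}(x) = -u(x + v_k(x))`, the standard
#' first-order inverse for moderate smooth fields. Used for
#' inverse-consistency reporting.
#'
#' @param field A `deformation_field`.
#' @param iters Fixed-point iterations.
#' @return A `deformation_field` approximating the inverse.
#' @export
invert_field <- function(field, iters = 10L) {
  g <- field$grid
  base <- grid_coords(g)
  v <- matrix(0, nrow(base), 3)
  u <- list(vol_from(field, 1), vol_from(field, 2), vol_from(field, 3))
  for (it in seq_len(iters)) {
    pts <- base + v
    v <- -cbind(sample_at(u[[1]], pts, "linear", pad = 0),
                sample_at(u[[2]], pts, "linear", pad = 0),
                sample_at(u[[3]], pts, "linear", pad = 0))
  }
  deformation_field(array(v, dim = c(g$shape, 3L)), g, domain = field$domain)
}

vol_from <- function(field, comp) {
  g <- field$grid
  volume_image(array(field$displacements[, , , comp], dim = g$shape),
               g$spacing, g$origin, "DOSE")
}

# mean |u(x) + v(x + u(x))| inside an optional mask: the inverse-consistency
# residual of a field and its numerical inverse
inverse_consistency_error <- function(field, inv = NULL, mask = NULL) {
  if (is.null(inv)) inv <- invert_field(field)
  g <- field$grid
  pts <- grid_coords(g)
  u <- cbind(as.vector(field$displacements[, , , 1]),
             as.vector(field$displacements[, , , 2]),
             as.vector(field$displacements[, , , 3]))
  at <- pts + u
  resid <- u + cbind(sample_at(vol_from(inv, 1), at, "linear", pad = 0),
                     sample_at(vol_from(inv, 2), at, "linear", pad = 0),
                     sample_at(vol_from(inv, 3), at, "linear", pad = 0))
  mag <- sqrt(rowSums(resid^2))
  if (!is.null(mask)) mag <- mag[as.vector(mask)]
  mean(mag)
}
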