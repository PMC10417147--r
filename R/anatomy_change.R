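#' Specification of mid-course anatomical change
#'
#' Captures the three change mechanisms the monitoring workflow must detect:
#' tumor/target shrinkage (default magnitude 16.4%, the mean early-course
#' GTV volume reduction reported for head-and-neck patients), a shoulder
#' setup shift, and filling of air cavities.
#'
#' @param target_shrink_fraction Fractional volume loss of the high-risk
#'   target, in `[0, 1)`.
#' @param shoulder_shift_mm Length-3 translation applied to the shoulder
#'   surrogates (mm); negative Z = inferior.
#' @param cavity_fill_fraction Fraction of air-cavity volume replaced by
#'   soft tissue, in `[0, 1]`.
#' @param seed Integer seed for the (small) stochastic components.
#' @return An object of class `anatomy_change_spec`.
#' @export
anatomy_change_spec <- function(target_shrink_fraction = 0.164,
                                shoulder_shift_mm = c(0, 0, 0),
                                cavity_fill_fraction = 0,
                                seed = 1L) {
  if (target_shrink_fraction < 0 || target_shrink_fraction >= 1) {
    stop("`target_shrink_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (cavity_fill_fraction < 0 || cavity_fill_fraction > 1) {
    stop("`cavity_fill_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (length(shoulder_shift_mm) != 3L || any(!is.finite(shoulder_shift_mm))) {
    stop("`shoulder_shift_mm` must be three finite values", call. = FALSE)
  }
  structure(list(target_shrink_fraction = target_shrink_fraction,
                 shoulder_shift_mm = as.numeric(shoulder_shift_mm),
                 cavity_fill_fraction = cavity_fill_fraction,
                 seed = as.integer(seed)),
            class = "anatomy_change_spec")
}

#' Apply anatomical change to a planning CT, returning the ground truth
#'
#' Builds an analytic pull-back deformation (exact local scaling about the
#' high-risk target centroid for shrinkage, exact local translation of the
#' shoulder surrogates, each with a smooth taper to identity), warps the
#' image and structures with it, and optionally fills air cavities. The
#' exact deformation field is returned so registration accuracy can be
#' scored against ground truth.
#'
#' @param pct Planning CT `volume_image` (HU).
#' @param structures `structure_set` from [generate_phantom()].
#' @param change An [anatomy_change_spec()].
#' @return `list(ct, structures, field)` where `field` is a
#'   [deformation_field()] in the pull-back convention used by
#'   [warp_image()].
#' @export
apply_anatomy_change <- function(pct, structures, change = anatomy_change_spec()) {
  stopifnot_volume(pct)
  if (!inherits(change, "anatomy_change_spec")) {
    stop("`change` must be an anatomy_change_spec", call. = FALSE)
  }
  g <- grid_of(pct)
  co <- grid_coords(g)
  u <- matrix(0, nrow = nrow(co), ncol = 3)

  if (change$target_shrink_fraction > 0) {
    ctv <- mask_by_role(structures, "CTV_HIGH")
    ctr <- mask_centroid(ctv, g)
    idx <- which(ctv)
    r_vox <- sqrt(rowSums((co[idx, , drop = FALSE] -
                             matrix(ctr, length(idx), 3, byrow = TRUE))^2))
    r_ctv <- max(r_vox)
    s <- (1 - change$target_shrink_fraction)^(1 / 3)
    r <- sqrt(rowSums((co - matrix(ctr, nrow(co), 3, byrow = TRUE))^2))
    r0 <- 1.25 * r_ctv; r1 <- r0 + 45
    w <- taper_weight(r, r0, r1)
    amp <- (1 / s - 1)
    u <- u + (co - matrix(ctr, nrow(co), 3, byrow = TRUE)) * (amp * w)
  }

  if (any(change$shoulder_shift_mm != 0)) {
    sh_mask <- structures$masks[["shoulders"]]
    if (is.null(sh_mask)) stop("structures lack a 'shoulders' surrogate mask", call. = FALSE)
    d2 <- sq_distance_transform(!sh_mask, g$spacing, max_dist = 55)
    dist_to_sh <- sqrt(as.vector(d2))  # distance from each voxel to the shoulder surface
    w <- taper_weight(dist_to_sh, 12, 50)
    u <- u - matrix(change$shoulder_shift_mm, nrow(co), 3, byrow = TRUE) * w
  }

  field <- deformation_field(array(u, dim = c(g$shape, 3L)), g)
  shrunk_empty <- FALSE
  if (change$target_shrink_fraction > 0 || any(change$shoulder_shift_mm != 0)) {
    ct <- warp_image(pct, field, "linear")
    new_structs <- map_contours(structures, field)
  } else {
    ct <- volume_image(pct$voxels, g$spacing, g$origin, pct$kind)
    new_structs <- structures
  }
  if (!any(mask_by_role(new_structs, "CTV_HIGH"))) {
    stop("target shrinkage emptied the high-risk CTV", call. = FALSE)
  }

  if (change$cavity_fill_fraction > 0) {
    cav <- new_structs$masks[["air_cavity"]]
    if (!is.null(cav) && any(cav)) {
      idx <- which(cav)
      kz <- (idx - 1L) %/% (g$shape[1] * g$shape[2])
      ord <- idx[order(kz)]  # fill from the inferior end upward
      n_fill <- round(change$cavity_fill_fraction * length(ord))
      if (n_fill > 0) {
        v <- ct$voxels
        fill_hu <- with_seed(change$seed, stats::rnorm(n_fill, 30, 8))
        v[ord[seq_len(n_fill)]] <- fill_hu
        ct <- volume_image(v, g$spacing, g$origin, ct$kind)
      }
    }
  }
  list(ct = ct, structures = new_structs, field = field)
}

# smooth plateau/taper: 1 for r <= r0, cosine ramp to 0 at r1
taper_weight <- function(r, r0, r1) {
  w <- numeric(length(r))
  w[r <= r0] <- 1
  mid <- r > r0 & r < r1
  w[mid] <- 0.5 * (1 + cos(pi * (r[mid] - r0) / (r1 - r0)))
  w
}
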