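#' Generate a virtual CT
#'
#' Deforms the planning CT to the CBCT (reusing the corrected-CBCT
#' registration) and then corrects low-density anatomical differences: a
#' voxel inside the field of view is overridden with the corrected-CBCT CT
#' number when the two images disagree in mass density by more than
#' `delta_rho` (default 0.3 g/cm3) AND at least one of the densities is
#' below `low_rho` (default 0.6 g/cm3). Both comparisons are strict, so a
#' difference of exactly 0.3 or a density of exactly 0.6 does not trigger
#' an override; the low-density gate keeps high-density structures from
#' being modified or duplicated. Outside the field of view the deformed
#' planning CT is kept.
#'
#' @param pct Planning CT `volume_image` (HU).
#' @param cbct CBCT `volume_image` (used for grid agreement checks).
#' @param corrcbct Corrected CBCT (HU `volume_image`), normally from
#'   [make_corrcbct()].
#' @param field [deformation_field()] from the same corrected-CBCT run.
#' @param fov Logical field-of-view mask.
#' @param calibration Density calibration applied to both sides of the
#'   comparison so the densities are commensurate.
#' @param delta_rho,low_rho Masking thresholds, g/cm3.
#' @return `list(virtct = volume_image, override = logical mask,
#'   base = deformed planning CT)`.
#' @export
make_virtct <- function(pct, cbct, corrcbct, field, fov,
                        calibration = density_calibration(),
                        delta_rho = 0.3, low_rho = 0.6) {
  stopifnot_volume(pct); stopifnot_volume(corrcbct)
  g <- field$grid
  if (!same_grid(corrcbct, g)) stop("corrcbct grid does not match the field", call. = FALSE)
  if (is_volume_image(fov)) fov <- fov$voxels > 0.5
  pct_r <- resample_to_grid(pct, g, "linear")
  base <- warp_image(pct_r, field, "linear")
  rho_v <- to_density(base, calibration)$voxels
  rho_c <- to_density(corrcbct, calibration)$voxels
  override <- fov & (abs(rho_v - rho_c) > delta_rho) &
    (pmin(rho_v, rho_c) < low_rho)
  v <- base$voxels
  v[override] <- corrcbct$voxels[override]
  list(virtct = volume_image(v, g$spacing, g$origin, "HU"),
       override = array(override, dim = g$shape),
       base = base)
}

#' Generate a ground-truth CT
#'
#' Deforms the same-day verification CT to the CBCT, producing the
#' dosimetric reference for the treatment position. The CBCT is first made
#' commensurate (joint-histogram conversion to HU and low-pass artifact
#' correction against the verification CT); the verification CT is then
#' rigidly aligned to it (bulk setup differences such as couch shifts are
#' rigid) before the deformable registration, which is restricted to the
#' retracted field-of-view focus region, resolves the residual.
#'
#' @param vfct Verification CT `volume_image` (HU).
#' @param cbct CBCT `volume_image` (gray values).
#' @param fov Logical field-of-view mask on the CBCT grid.
#' @param config A [corrcbct_config()] (conversion/registration settings are
#'   shared with the corrected-CBCT machinery).
#' @return `list(gtct = volume_image, field = deformation_field,
#'   conversion = conversion_function)`.
#' @export
make_gtct <- function(vfct, cbct, fov, config = corrcbct_config()) {
  stopifnot_volume(vfct); stopifnot_volume(cbct)
  g <- grid_of(cbct)
  if (is_volume_image(fov)) fov <- fov$voxels > 0.5
  vf_r <- resample_to_grid(vfct, g, "linear")
  focus <- retract_fov(fov, config$focus_margin_mm, g$spacing)
  hist <- build_joint_histogram(vf_r, cbct, focus, config$bins)
  classes <- identify_tissue_classes(hist, config$n_classes)
  conv <- fit_conversion_function(classes)
  converted <- convert_cbct(cbct, conv)
  artifact <- estimate_artifact_map(converted, vf_r, fov, config$sigma_mm,
                                    config$feather_mm)
  target <- volume_image(converted$voxels - artifact$map, g$spacing, g$origin,
                         "HU")
  rig <- rigid_align(vf_r, target, max_iter = 60, mask = focus)
  dir_field <- deform(rig$moved, target, focus, config$deform)
  # compose rigid and deformable into one pull-back field on the CBCT grid,
  # so image warping and contour mapping use the same total transform
  pts <- grid_coords(g)
  u <- cbind(as.vector(dir_field$displacements[, , , 1]),
             as.vector(dir_field$displacements[, , , 2]),
             as.vector(dir_field$displacements[, , , 3]))
  par <- c(rig$translation, rig$rotation_deg * pi / 180)
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  total <- rigid_points(pts + u, par, center, 6L) - pts
  field <- deformation_field(array(total, dim = c(g$shape, 3L)), g)
  gtct <- warp_image(vf_r, field, "linear")
  list(gtct = gtct, field = field, dir_field = dir_field, conversion = conv,
       rigid = rig)
}
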