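#' Configuration for corrected-CBCT generation
#'
#' @param bins Joint-histogram bins per axis.
#' @param n_classes Maximum tissue-class junctions (default 4: air, a
#'   fat/soft boundary, soft tissue, bone).
#' @param sigma_mm Artifact-map low-pass standard deviation, mm.
#' @param feather_mm Transition band between corrected CBCT and deformed
#'   planning CT at the field-of-view boundary, mm.
#' @param focus_margin_mm Field-of-view retraction for the registration
#'   focus region, mm.
#' @param tol_hu Convergence criterion: mean absolute HU change of the
#'   corrected image between iterations.
#' @param max_iter Iteration cap.
#' @param deform Registration settings for the first pass.
#' @param deform_refine Warm-started registration settings for later passes.
#' @return A list of class `corrcbct_config`.
#' @export
corrcbct_config <- function(bins = 96L, n_classes = 4L, sigma_mm = 15,
                            feather_mm = 10, focus_margin_mm = 20,
                            tol_hu = 2, max_iter = 5L,
                            deform = deform_config(),
                            deform_refine = deform_config(levels = c(2L, 1L),
                                                          iters = c(8L, 4L))) {
  structure(list(bins = bins, n_classes = n_classes, sigma_mm = sigma_mm,
                 feather_mm = feather_mm, focus_margin_mm = focus_margin_mm,
                 tol_hu = tol_hu, max_iter = as.integer(max_iter),
                 deform = deform, deform_refine = deform_refine),
            class = "corrcbct_config")
}

#' Generate a corrected CBCT
#'
#' Iterative intensity correction: deformable registration of the planning
#' CT to the CBCT (restricted to the retracted field-of-view focus region),
#' joint histogram, tissue-class identification, piecewise-linear gray-to-HU
#' conversion, then difference-map low-pass artifact correction; repeated
#' until the corrected image changes by less than `tol_hu` mean absolute HU
#' or the iteration cap is reached. Inside the field of view the output is
#' the converted and artifact-corrected CBCT; outside it the anatomy is
#' extended with the deformed planning CT, blended across a feather band at
#' the field-of-view boundary.
#'
#' @param pct Planning CT `volume_image` (HU), any grid.
#' @param cbct CBCT `volume_image` (gray values).
#' @param fov Logical field-of-view mask on the CBCT grid.
#' @param config A [corrcbct_config()].
#' @return An object of class `corrcbct_result`: `corrcbct` (HU
#'   `volume_image`), `conversion` ([conversion_function()]), `artifact`
#'   (`artifact_map`), `field` ([deformation_field()]), `converged`,
#'   `iterations`, `trace` (mean |dHU| per iteration), `focus`.
#' @export
make_corrcbct <- function(pct, cbct, fov, config = corrcbct_config()) {
  stopifnot_volume(pct); stopifnot_volume(cbct)
  g <- grid_of(cbct)
  if (is_volume_image(fov)) fov <- fov$voxels > 0.5
  pct_r <- resample_to_grid(pct, g, "linear")
  focus <- retract_fov(fov, config$focus_margin_mm, g$spacing)

  field <- NULL
  pct_def <- pct_r
  prev <- NULL
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    # conversion and artifact correction from the current deformed pCT
    hist <- build_joint_histogram(pct_def, cbct, focus, config$bins)
    classes <- identify_tissue_classes(hist, config$n_classes)
    conv <- fit_conversion_function(classes)
    converted <- convert_cbct(cbct, conv)
    artifact <- estimate_artifact_map(converted, pct_def, fov,
                                      config$sigma_mm, config$feather_mm)
    corrected <- converted$voxels - artifact$map
    corrected_img <- volume_image(corrected, g$spacing, g$origin, "HU")
    if (!is.null(prev)) {
      change <- mean(abs(corrected[fov] - prev[fov]))
      trace <- c(trace, change)
      if (change < config$tol_hu) { converged <- TRUE; prev <- corrected; break }
    }
    prev <- corrected
    # re-register against the artifact-corrected image, so shading never
    # masquerades as deformation
    if (it == 1L) {
      field <- deform(pct_r, corrected_img, focus, config$deform,
                      compute_ic = FALSE)
    } else {
      field <- deform(pct_r, corrected_img, focus, config$deform_refine,
                      init = field, compute_ic = FALSE)
    }
    pct_def <- warp_image(pct_r, field, "linear")
  }

  field$inverse_consistency_mm <- inverse_consistency_error(field, mask = focus)
  w <- feather_weight(fov, config$feather_mm, g$spacing)
  composite <- w * prev + (1 - w) * pct_def$voxels
  out <- volume_image(composite, g$spacing, g$origin, "HU")
  structure(list(corrcbct = out, conversion = conv, artifact = artifact,
                 field = field, converged = converged,
                 iterations = length(trace) + 1L, trace = trace,
                 focus = focus, fov = fov, pct_deformed = pct_def),
            class = "corrcbct_result")
}

#' @export
print.corrcbct_result <- function(x, ...) {
  cat(sprintf("<corrcbct_result> %d iterations, %sconverged%s\n",
              x$iterations, if (x$converged) "" else "NOT ",
              if (length(x$trace)) sprintf(", final mean |dHU| %.2f", utils::tail(x$trace, 1)) else ""))
  invisible(x)
}

#' Per-iteration convergence trace of a corrected-CBCT fit
#'
#' @param x A `corrcbct_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `mean_abs_dhu` (change from the
#'   previous iteration's corrected image).
#' @export
tidy.corrcbct_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$trace) + 1L, mean_abs_dhu = x$trace)
}

#' One-row summary of a corrected-CBCT fit
#'
#' @param x A `corrcbct_result`.
#' @param ... Unused.
#' @return Tibble with iteration count, convergence flag, final change and
#'   registration inverse-consistency error.
#' @export
glance.corrcbct_result <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    final_mean_abs_dhu = if (length(x$trace)) utils::tail(x$trace, 1) else NA_real_,
    n_junctions = length(x$conversion$gray),
    inverse_consistency_mm = x$field$inverse_consistency_mm %||% NA_real_
  )
}

#' Two-mode linear rescaling of a CBCT (naive baseline)
#'
#' Maps the two dominant modes of the CBCT gray histogram onto the two
#' dominant modes of a reference CT's HU histogram with a single global
#' line. This is the bulk recalibration a treatment-planning system would
#' apply without joint-histogram classes or artifact correction; it is kept
#' as the comparison baseline for the corrected CBCT.
#'
#' @param cbct CBCT `volume_image`.
#' @param reference HU `volume_image` on the same grid.
#' @param mask Logical mask (normally the FOV).
#' @return An HU `volume_image`.
#' @export
naive_rescale_cbct <- function(cbct, reference, mask) {
  if (is_volume_image(mask)) mask <- mask$voxels > 0.5
  two_modes <- function(v) {
    h <- stats::density(v, n = 512)
    pk <- which(diff(sign(diff(c(-Inf, h$y, -Inf)))) == -2)
    pk <- pk[order(h$y[pk], decreasing = TRUE)]
    sort(h$x[pk[1:2]])
  }
  mg <- two_modes(cbct$voxels[mask])
  mh <- two_modes(reference$voxels[mask])
  slope <- diff(mh) / diff(mg)
  hu <- (cbct$voxels - mg[1]) * slope + mh[1]
  volume_image(pmin(pmax(hu, -1024), 3071), cbct$spacing, cbct$origin, "HU")
}
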