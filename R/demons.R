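#' Configuration for deformable registration
#'
#' Multi-resolution intensity-driven (demons-style) free-form registration
#' with Gaussian smoothness regularization. Iteration counts are fixed, so
#' registration is fully deterministic.
#'
#' @param levels Downsampling factors, coarse to fine.
#' @param iters Iterations per level.
#' @param sigma_update_mm Gaussian smoothing of each force update (fluid
#'   regularization), mm.
#' @param sigma_field_mm Gaussian smoothing of the accumulated field
#'   (diffusion regularization), mm.
#' @param max_step_mm Cap on the per-iteration displacement increment, mm.
#' @return A list of class `deform_config`.
#' @export
deform_config <- function(levels = c(4L, 2L, 1L), iters = c(60L, 40L, 12L),
                          sigma_update_mm = 8, sigma_field_mm = 3.5,
                          max_step_mm = 2) {
  structure(list(levels = as.integer(levels), iters = as.integer(iters),
                 sigma_update_mm = sigma_update_mm,
                 sigma_field_mm = sigma_field_mm, max_step_mm = max_step_mm),
            class = "deform_config")
}

#' Deformable image registration restricted to a focus region
#'
#' Estimates a smooth displacement field mapping the fixed image's space
#' into the moving image (pull-back convention: the warped moving image is
#' `moving(x + u(x))`). The field is exactly zero (identity) outside the
#' focus region, which should be the CBCT field of view retracted by 20 mm
#' (see [retract_fov()]) so the optimization never works against
#' field-of-view edge effects. Intensities of both images must be
#' commensurate (convert CBCT gray values first).
#'
#' @param moving,fixed `volume_image`s on a common grid.
#' @param focus Logical mask; displacements are estimated only here.
#' @param config A [deform_config()].
#' @param init Optional initial `deformation_field` (warm start).
#' @return A `deformation_field` with extra members: `trace` (per-iteration
#'   focus MSE), `converged`, `inverse_consistency_mm`.
#' @export
deform <- function(moving, fixed, focus, config = deform_config(), init = NULL,
                   compute_ic = TRUE) {
  stopifnot_volume(moving); stopifnot_volume(fixed)
  if (!same_grid(moving, fixed)) stop("images must share a grid", call. = FALSE)
  g <- grid_of(fixed)
  if (is_volume_image(focus)) focus <- focus$voxels > 0.5
  if (!any(focus)) stop("empty focus region", call. = FALSE)

  u <- NULL
  trace <- list()
  for (li in seq_along(config$levels)) {
    fct <- config$levels[li]
    gl <- coarse_grid(g, fct)
    mv <- resample_to_grid(moving, gl, "linear")
    fx <- resample_to_grid(fixed, gl, "linear")
    fo <- resample_mask(focus, g, gl)
    if (!any(fo)) fo <- array(TRUE, dim = gl$shape)
    u <- if (is.null(u)) {
      if (!is.null(init)) {
        resample_field_arr(init$displacements, init$grid, gl)
      } else {
        array(0, dim = c(gl$shape, 3L))
      }
    } else {
      resample_field_arr(u, g_prev, gl)
    }
    u <- demons_level(mv, fx, fo, u, gl, config$iters[li], config)
    trace[[li]] <- attr(u, "mse_trace")
    g_prev <- gl
  }
  if (!same_grid(g_prev, g)) u <- resample_field_arr(u, g_prev, g)

  fo_full <- focus
  field <- deformation_field(u, g, domain = fo_full)
  # MSE scales differ between resolution levels, so convergence is judged
  # within the finest level only
  fin <- trace[[length(trace)]]
  field$trace <- trace
  field$converged <- is.finite(min(fin)) && min(fin) <= fin[1] * 1.02
  if (!field$converged) {
    stop(paste0("deformable registration diverged (finest-level focus MSE ",
                sprintf("%.1f -> %.1f); iteration trace: ", fin[1], min(fin)),
                paste(signif(fin, 4), collapse = ", ")), call. = FALSE)
  }
  if (compute_ic) {
    field$inverse_consistency_mm <- inverse_consistency_error(field, mask = fo_full)
  }
  field
}

demons_level <- function(mv, fx, focus, u, gl, n_iter, config) {
  fvox <- fx$voxels
  grads <- image_gradient(fvox, gl$spacing)
  g2 <- grads[[1]]^2 + grads[[2]]^2 + grads[[3]]^2
  base <- grid_coords(gl)
  fmask <- array(as.numeric(focus), dim = gl$shape)
  alpha2 <- (stats::sd(fvox[focus]) / config$max_step_mm)^2
  mse_trace <- numeric(0)
  best_u <- u
  best_mse <- Inf
  for (it in seq_len(n_iter)) {
    pts <- base + cbind(as.vector(u[, , , 1]), as.vector(u[, , , 2]),
                        as.vector(u[, , , 3]))
    w <- array(sample_at(mv, pts, "linear"), dim = gl$shape)
    diffv <- w - fvox
    mse <- mean(diffv[focus]^2)
    mse_trace <- c(mse_trace, mse)
    if (mse < best_mse) { best_mse <- mse; best_u <- u }
    # stop refining once the similarity plateaus or starts to creep up
    if (it > 3 && mse > 1.01 * best_mse) break
    if (it > 3 && (mse_trace[it - 1] - mse) < 1e-4 * mse) break
    denom <- g2 + alpha2 * 1e-6 + (diffv^2) / (config$max_step_mm^2)
    denom[denom < 1e-9] <- 1e-9
    fac <- -diffv / denom
    for (c3 in 1:3) {
      upd <- gaussian_smooth(fac * grads[[c3]] * fmask,
                             config$sigma_update_mm, gl$spacing)
      u[, , , c3] <- (u[, , , c3] + upd) * fmask
    }
    if (config$sigma_field_mm > 0) {
      for (c3 in 1:3) {
        u[, , , c3] <- gaussian_smooth(u[, , , c3], config$sigma_field_mm,
                                       gl$spacing) * fmask
      }
    }
  }
  u <- best_u
  attr(u, "mse_trace") <- mse_trace
  u
}

# central-difference gradient in physical units (per mm)
image_gradient <- function(a, spacing) {
  d <- dim(a)
  out <- vector("list", 3)
  for (ax in 1:3) {
    gplus <- a; gminus <- a
    idx_hi <- c(2:d[ax], d[ax]); idx_lo <- c(1, 1:(d[ax] - 1))
    if (ax == 1) { gplus <- a[idx_hi, , , drop = FALSE]; gminus <- a[idx_lo, , , drop = FALSE] }
    if (ax == 2) { gplus <- a[, idx_hi, , drop = FALSE]; gminus <- a[, idx_lo, , drop = FALSE] }
    if (ax == 3) { gplus <- a[, , idx_hi, drop = FALSE]; gminus <- a[, , idx_lo, drop = FALSE] }
    out[[ax]] <- array((gplus - gminus) / (2 * spacing[ax]), dim = d)
  }
  out
}

resample_field_arr <- function(u, from_grid, to_grid) {
  out <- array(0, dim = c(to_grid$shape, 3L))
  pts <- grid_coords(to_grid)
  for (c3 in 1:3) {
    comp <- volume_image(array(u[, , , c3], dim = from_grid$shape),
                         from_grid$spacing, from_grid$origin, "DOSE")
    out[, , , c3] <- array(sample_at(comp, pts, "linear", pad = 0),
                           dim = to_grid$shape)
  }
  out
}
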