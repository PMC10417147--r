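#' Rigid intensity-based alignment
#'
#' Recovers a rigid transform (translation plus small rotations about the
#' volume centre) that maps the moving image onto the fixed image by
#' minimizing the mean squared intensity difference, multi-resolution
#' Nelder-Mead. Both images must already be on a common grid (resample
#' first if not).
#'
#' @param moving,fixed `volume_image`s on the same grid with commensurate
#'   intensities.
#' @param rotations Optimize the three rotation angles as well as the
#'   translation (default) or translation only.
#' @param max_iter Nelder-Mead iteration cap per resolution level.
#' @param mask Optional logical mask on the fixed grid; the similarity is
#'   evaluated only there (use it to exclude truncated field-of-view
#'   regions of the fixed image).
#' @return `list(translation, rotation_deg, moved, mse_before, mse_after)`
#'   where `moved` is the resampled moving image.
#' @export
rigid_align <- function(moving, fixed, rotations = TRUE, max_iter = 200L,
                        mask = NULL) {
  stopifnot_volume(moving); stopifnot_volume(fixed)
  if (!same_grid(moving, fixed)) stop("images must share a grid", call. = FALSE)
  g <- grid_of(fixed)
  center <- g$origin + (g$shape - 1) * g$spacing / 2
  npar <- if (rotations) 6L else 3L
  if (is.null(mask)) mask <- array(TRUE, g$shape)
  if (is_volume_image(mask)) mask <- mask$voxels > 0.5

  # mean squared difference over the in-mask overlap region only, so
  # out-of-extent padding and truncated fixed-image regions cannot bias
  # the optimum
  cost_on <- function(mov_small, fix_small, mk, pts, ctr) {
    keep <- as.vector(mk)
    pts <- pts[keep, , drop = FALSE]
    fv <- as.vector(fix_small$voxels)[keep]
    function(par) {
      tr <- rigid_points(pts, par, ctr, npar)
      ok <- in_extent(mov_small, tr)
      if (sum(ok) < length(fv) / 4) return(Inf)
      mean((sample_at(mov_small, tr[ok, , drop = FALSE], "linear") - fv[ok])^2)
    }
  }

  par <- numeric(npar)
  # exhaustive coarse translation search (robust against the flat, rugged
  # similarity landscape at low resolution), then simplex refinement
  gs4 <- coarse_grid(g, 4L)
  fn4 <- cost_on(resample_to_grid(moving, gs4, "linear"),
                 resample_to_grid(fixed, gs4, "linear"),
                 resample_mask(mask, g, gs4), grid_coords(gs4),
                 center)
  cand <- as.matrix(expand.grid(x = seq(-12, 12, by = 3),
                                y = seq(-12, 12, by = 3),
                                z = seq(-12, 12, by = 3)))
  vals <- apply(cand, 1, function(t3) fn4(c(t3, numeric(npar - 3L))))
  par[1:3] <- cand[which.min(vals), ]
  for (fct in c(2L, 1L)) {
    gs <- coarse_grid(g, fct)
    fn <- cost_on(resample_to_grid(moving, gs, "linear"),
                  resample_to_grid(fixed, gs, "linear"),
                  resample_mask(mask, g, gs), grid_coords(gs), center)
    scale <- if (npar == 6L) c(2, 2, 2, 0.02, 0.02, 0.02) else c(2, 2, 2)
    if (fct == 1L) scale <- scale / 4
    opt <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = max_iter * (fct + 1L),
                                       reltol = 1e-10, parscale = scale))
    par <- opt$par
  }

  pts <- grid_coords(g)
  tr <- rigid_points(pts, par, center, npar)
  ok <- in_extent(moving, tr) & as.vector(mask)
  moved_vals <- sample_at(moving, tr, "linear")
  moved <- volume_image(array(moved_vals, dim = g$shape), g$spacing, g$origin,
                        moving$kind)
  fv <- as.vector(fixed$voxels)
  mse0 <- mean((as.vector(moving$voxels)[ok] - fv[ok])^2)
  mse1 <- mean((moved_vals[ok] - fv[ok])^2)
  if (!is.finite(mse1) || mse1 > mse0 * 1.5 + 1e-6) {
    stop(sprintf(paste0("rigid registration failed to improve similarity ",
                        "(MSE %.1f -> %.1f); check image overlap"), mse0, mse1),
         call. = FALSE)
  }
  list(translation = par[1:3],
       rotation_deg = if (npar == 6L) par[4:6] * 180 / pi else c(0, 0, 0),
       moved = moved, mse_before = mse0, mse_after = mse1)
}

# sample positions for a pull-back rigid warp: rotate about ctr then translate.
# forward model: fixed(x) ~ moving(R (x - ctr) + ctr + t)
rigid_points <- function(pts, par, ctr, npar) {
  t3 <- par[1:3]
  if (npar == 6L && any(par[4:6] != 0)) {
    R <- rotation_matrix(par[4], par[5], par[6])
    pc <- sweep(pts, 2, ctr)
    pts2 <- pc %*% t(R)
    pts2 <- sweep(pts2, 2, ctr + t3, FUN = "+")
  } else {
    pts2 <- sweep(pts, 2, t3, FUN = "+")
  }
  pts2
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

coarse_grid <- function(g, factor) {
  if (factor == 1L) return(g)
  shape <- pmax(8L, as.integer(ceiling(g$shape / factor)))
  spacing <- g$spacing * (g$shape - 1) / pmax(shape - 1, 1)
  grid_spec(shape, spacing, g$origin)
}
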