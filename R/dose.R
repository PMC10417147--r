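#' Water-equivalent path length along a single ray
#'
#' Uniform ray stepping through the stopping-power volume: cumulative
#' SPR-weighted distance from the entry point, with the step capped at half
#' the smallest voxel spacing. Points outside the grid contribute air
#' (SPR ~ 0).
#'
#' @param spr SPR `volume_image` (from [hu_to_spr()]).
#' @param entry Length-3 physical start point, mm.
#' @param direction Length-3 direction (normalized internally).
#' @param length_mm Path length to integrate; default: to the far side of
#'   the grid bounding box.
#' @param step_mm Step size; default half the minimum spacing.
#' @return Tibble with `t_mm` (distance from entry, at step midpoints) and
#'   `wepl_mm` (cumulative water-equivalent depth). Zero rows when the ray
#'   misses the grid entirely.
#' @export
compute_wepl <- function(spr, entry, direction, length_mm = NULL,
                         step_mm = NULL) {
  stopifnot_volume(spr)
  d <- direction / sqrt(sum(direction^2))
  g <- grid_of(spr)
  if (is.null(step_mm)) step_mm <- min(g$spacing) / 2
  lo <- g$origin - g$spacing / 2
  hi <- g$origin + (g$shape - 0.5) * g$spacing
  if (is.null(length_mm)) {
    # slab intersection with the bounding box
    t0 <- -Inf; t1 <- Inf
    for (ax in 1:3) {
      if (abs(d[ax]) < 1e-12) {
        if (entry[ax] < lo[ax] || entry[ax] > hi[ax]) return(
          tibble::tibble(t_mm = numeric(0), wepl_mm = numeric(0)))
      } else {
        ta <- (lo[ax] - entry[ax]) / d[ax]; tb <- (hi[ax] - entry[ax]) / d[ax]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
      }
    }
    if (!is.finite(t1) || t1 <= max(t0, 0)) {
      return(tibble::tibble(t_mm = numeric(0), wepl_mm = numeric(0)))
    }
    length_mm <- t1
  }
  n <- max(1L, ceiling(length_mm / step_mm))
  tmid <- (seq_len(n) - 0.5) * (length_mm / n)
  pts <- cbind(entry[1] + tmid * d[1], entry[2] + tmid * d[2],
               entry[3] + tmid * d[3])
  vals <- sample_at(spr, pts, "linear", pad = 0.001)
  tibble::tibble(t_mm = tmid, wepl_mm = cumsum(vals) * (length_mm / n))
}

# orthonormal beam frame (e1, e2, d) for a unit direction d
beam_frame <- function(d) {
  d <- d / sqrt(sum(d^2))
  up <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(d[2] * up[3] - d[3] * up[2], d[3] * up[1] - d[1] * up[3],
          d[1] * up[2] - d[2] * up[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2, d = d)
}

# beam-aligned grid covering the volume's bounding box corners
beam_grid <- function(g, frame, lateral_mm, depth_mm) {
  corners <- as.matrix(expand.grid(
    x = c(g$origin[1] - g$spacing[1] / 2, g$origin[1] + (g$shape[1] - 0.5) * g$spacing[1]),
    y = c(g$origin[2] - g$spacing[2] / 2, g$origin[2] + (g$shape[2] - 0.5) * g$spacing[2]),
    z = c(g$origin[3] - g$spacing[3] / 2, g$origin[3] + (g$shape[3] - 0.5) * g$spacing[3])))
  B <- cbind(frame$e1, frame$e2, frame$d)
  proj <- corners %*% B
  lo <- apply(proj, 2, min); hi <- apply(proj, 2, max)
  # snap node positions to multiples of the sampling step: for axis-aligned
  # beams the beam nodes then coincide with voxel centres
  step <- c(lateral_mm, lateral_mm, depth_mm)
  lo <- floor(lo / step) * step
  shape <- c(ceiling((hi[1] - lo[1]) / lateral_mm) + 1L,
             ceiling((hi[2] - lo[2]) / lateral_mm) + 1L,
             ceiling((hi[3] - lo[3]) / depth_mm) + 1L)
  list(lo = lo, shape = as.integer(shape),
       spacing = c(lateral_mm, lateral_mm, depth_mm), B = B)
}

# physical-space coordinates of all beam-grid nodes (column-major order)
beam_grid_points <- function(bg) {
  ax <- lapply(1:3, function(a) bg$lo[a] + (seq_len(bg$shape[a]) - 1) * bg$spacing[a])
  P <- cbind(rep(ax[[1]], times = bg$shape[2] * bg$shape[3]),
             rep(rep(ax[[2]], each = bg$shape[1]), times = bg$shape[3]),
             rep(ax[[3]], each = bg$shape[1] * bg$shape[2]))
  P %*% t(bg$B)
}

#' Plan proton beams on the planning anatomy
#'
#' Places the preset beam arrangement (one anterior plus two posterior
#' oblique beams, the posterior-dominant mirror, or a single beam), aims at
#' the union of the CTV masks, and sets a per-ray distal range from the
#' planning SPR: for every lateral ray position in the aperture (the target
#' projection dilated by `aperture_margin_mm`), the planned range is the
#' water-equivalent depth of the distal target edge plus
#' `distal_margin_mm`. The returned plan carries a normalization factor
#' calibrated so that the dose recomputed on the planning SPR gives
#' D99(CTV high-risk) = 100%.
#'
#' @param structures `structure_set` with CTV masks.
#' @param spr Planning SPR `volume_image`.
#' @param arrangement `"anterior_3"`, `"posterior_3"` or `"single"`.
#' @param aperture_margin_mm Lateral margin around the target projection.
#' @param distal_margin_mm Range margin beyond the distal target edge.
#' @param lateral_mm,depth_mm Beam-frame sampling (defaults: the image's
#'   min spacing laterally, half of it in depth).
#' @return An object of class `beam_set` (list of `beam_spec` + `norm`).
#' @export
plan_beams <- function(structures, spr,
                       arrangement = c("anterior_3", "posterior_3", "single"),
                       aperture_margin_mm = 6, distal_margin_mm = 4,
                       lateral_mm = NULL, depth_mm = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot_volume(spr)
  g <- grid_of(spr)
  target <- mask_by_role(structures, "CTV_HIGH") |
    mask_by_role(structures, "CTV_STANDARD")
  if (!any(target)) stop("empty target", call. = FALSE)
  if (is.null(lateral_mm)) lateral_mm <- min(g$spacing)
  if (is.null(depth_mm)) depth_mm <- min(g$spacing) / 2

  dirs <- switch(arrangement,
    anterior_3 = list(c(0, 1, 0), c(-sqrt(0.5), -sqrt(0.5), 0),
                      c(sqrt(0.5), -sqrt(0.5), 0)),
    posterior_3 = list(c(0, -1, 0), c(-sqrt(0.5), sqrt(0.5), 0),
                       c(sqrt(0.5), sqrt(0.5), 0)),
    single = list(c(0, 1, 0)))
  weights <- if (length(dirs) == 3L) c(0.4, 0.3, 0.3) else 1

  tgt_img <- volume_image(array(as.numeric(target), dim = g$shape), g$spacing,
                          g$origin, "DOSE")
  beams <- vector("list", length(dirs))
  for (b in seq_along(dirs)) {
    fr <- beam_frame(dirs[[b]])
    bg <- beam_grid(g, fr, lateral_mm, depth_mm)
    P <- beam_grid_points(bg)
    spr_bf <- array(sample_at(spr, P, "linear", pad = 0.001), dim = bg$shape)
    tgt_bf <- array(sample_at(tgt_img, P, "linear", pad = 0) >= 0.5,
                    dim = bg$shape)
    wepl_bf <- depth_cumsum(spr_bf) * bg$spacing[3]
    nl <- bg$shape[1] * bg$shape[2]
    dim(wepl_bf) <- c(nl, bg$shape[3])
    dim(tgt_bf) <- c(nl, bg$shape[3])
    has_t <- rowSums(tgt_bf) > 0
    range_map <- rep(NA_real_, nl)
    if (any(has_t)) {
      wt <- wepl_bf * tgt_bf
      range_map[has_t] <- apply(wt[has_t, , drop = FALSE], 1, max) + distal_margin_mm
    }
    ap <- matrix(has_t, bg$shape[1], bg$shape[2])
    ap_dil <- dilate2d_mm(ap, aperture_margin_mm, bg$spacing[1:2])
    rng <- matrix(range_map, bg$shape[1], bg$shape[2])
    rng_fill <- grow_max2d(rng, ceiling(aperture_margin_mm / bg$spacing[1]))
    rng[ap_dil & !ap] <- rng_fill[ap_dil & !ap]
    beams[[b]] <- structure(list(direction = fr$d, frame = fr, grid = bg,
                                 weight = weights[b], aperture = ap_dil,
                                 range_map = rng),
                            class = "beam_spec")
  }
  bs <- structure(list(beams = beams, norm = 1, arrangement = arrangement),
                  class = "beam_set")
  plan_dose <- compute_dose_proxy(spr, bs)
  d99 <- d_metric(compute_dvh(plan_dose, mask_by_role(structures, "CTV_HIGH")),
                  0.99)
  if (d99 <= 0) stop("planning failed: zero target coverage", call. = FALSE)
  bs$norm <- 100 / d99
  bs
}

#' @export
print.beam_set <- function(x, ...) {
  cat(sprintf("<beam_set> %s: %d beams, norm %.4g\n", x$arrangement,
              length(x$beams), x$norm))
  for (b in x$beams) {
    cat(sprintf("  dir (%.2f, %.2f, %.2f), weight %.2f, aperture %d rays, range %.0f-%.0f mm WEPL\n",
                b$direction[1], b$direction[2], b$direction[3], b$weight,
                sum(b$aperture), min(b$range_map, na.rm = TRUE),
                max(b$range_map, na.rm = TRUE)))
  }
  invisible(x)
}

# cumulative depth integral with node-centred (trapezoid) convention, so
# the value at node k is the integral from the first node to node k
depth_cumsum <- function(a) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1] * d[2])
  half <- 0.5 * m
  for (k in seq_len(ncol(m))[-1]) m[, k] <- m[, k - 1] + m[, k]
  m <- m - half - half[, 1]
  array(m, dim = d)
}

dilate2d_mm <- function(m, margin_mm, spacing) {
  m3 <- array(m, dim = c(dim(m), 1L))
  d2 <- sq_distance_transform(!m3, c(spacing, 1), max_dist = margin_mm + max(spacing))
  matrix(d2[, , 1] <= margin_mm^2 & d2[, , 1] > 0 | m, dim(m)[1], dim(m)[2])
}

grow_max2d <- function(m, r_vox) {
  out <- m
  for (k in seq_len(r_vox)) {
    p <- out
    n1 <- nrow(p); n2 <- ncol(p)
    sh <- list(rbind(p[-1, ], NA), rbind(NA, p[-n1, ]),
               cbind(p[, -1], NA), cbind(NA, p[, -n2]))
    for (s in sh) out <- pmax(out, s, na.rm = TRUE)
  }
  out
}

#' Compute the simplified proton dose proxy
#'
#' For each beam the stopping-power volume is resampled into the
#' beam-aligned frame, water-equivalent depth is accumulated along the beam
#' axis, and a spread-out-Bragg-peak-like depth dose is applied per ray:
#' full dose up to the planned distal range, a sharp linear distal falloff
#' over `falloff_mm` of water-equivalent depth, zero beyond. Beam doses are
#' summed by weight, mapped back to the image grid, and scaled by the
#' plan's normalization so the planning geometry yields
#' D99(CTV high-risk) = 100%. Deterministic: identical inputs give
#' bit-identical dose. There is no lateral scatter model; the proxy exists
#' to translate density/range errors into coverage changes.
#'
#' @param spr SPR `volume_image` of the anatomy to evaluate.
#' @param beams A `beam_set` from [plan_beams()].
#' @param falloff_mm Distal falloff width in WEPL mm.
#' @return Dose `volume_image` (kind `"DOSE"`), percent of prescription.
#' @export
compute_dose_proxy <- function(spr, beams, falloff_mm = 5) {
  stopifnot_volume(spr)
  g <- grid_of(spr)
  total <- array(0, dim = g$shape)
  co <- grid_coords(g)
  for (b in beams$beams) {
    bg <- b$grid
    P <- beam_grid_points(bg)
    spr_bf <- array(sample_at(spr, P, "linear", pad = 0.001), dim = bg$shape)
    wepl_bf <- depth_cumsum(spr_bf) * bg$spacing[3]
    nl <- bg$shape[1] * bg$shape[2]
    dim(wepl_bf) <- c(nl, bg$shape[3])
    rng <- as.vector(b$range_map)
    ap <- as.vector(b$aperture)
    dose_bf <- matrix(0, nl, bg$shape[3])
    act <- which(ap & !is.na(rng))
    if (length(act)) {
      w <- wepl_bf[act, , drop = FALSE]
      r <- rng[act]
      dd <- pmin(pmax((r + falloff_mm - w) / falloff_mm, 0), 1)
      dose_bf[act, ] <- dd
    }
    dim(dose_bf) <- bg$shape
    # map back: image voxel centres expressed in beam coordinates
    pb <- co %*% bg$B
    fb <- sweep(pb, 2, bg$lo)
    bvol <- volume_image(dose_bf, bg$spacing, c(0, 0, 0), "DOSE")
    vals <- sample_at(bvol, fb, "linear", pad = 0)
    total <- total + array(vals, dim = g$shape) * b$weight
  }
  volume_image(total * beams$norm, g$spacing, g$origin, "DOSE")
}
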