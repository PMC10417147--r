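#' Grid presets for the head-and-neck phantom
#'
#' `"clinical_ct"` and `"clinical_cbct"` follow the planning-CT and CBCT
#' acquisition geometry (512 x 512 x 387 at 1.17 x 1.17 x 1.00 mm and
#' 512 x 512 x 110 at 0.54 x 0.54 x 2.50 mm respectively). `"test"` is the
#' downscaled grid used throughout the test-suite and examples: the same
#' physical head/neck/shoulder extent on ~100x coarser sampling so a full
#' pipeline run stays interactive.
#'
#' @param preset One of `"test"`, `"clinical_ct"`, `"clinical_cbct"`.
#' @return A `grid_spec` centred on the phantom midline.
#' @export
phantom_grid <- function(preset = c("test", "clinical_ct", "clinical_cbct")) {
  preset <- match.arg(preset)
  g <- switch(preset,
    test = list(shape = c(96L, 64L, 56L), spacing = c(4.2, 4.2, 4.0)),
    clinical_ct = list(shape = c(512L, 512L, 387L), spacing = c(1.17, 1.17, 1.00)),
    clinical_cbct = list(shape = c(512L, 512L, 110L), spacing = c(0.54, 0.54, 2.50))
  )
  grid_spec(g$shape, g$spacing, origin = -(g$shape - 1) * g$spacing / 2)
}

#' Specification of the synthetic head-and-neck phantom
#'
#' Geometry of an anthropomorphic surrogate: an ellipsoidal head on a neck
#' cylinder over a shoulder slab, with spine / mandible / shoulder bone
#' surrogates, pharyngeal and nasal air cavities, a high-risk target in the
#' mid neck and an elongated standard-risk target running inferiorly toward
#' the shoulder region (standard-risk nodal volumes extend into the lower
#' neck, which is what makes them sensitive to shoulder setup change).
#' All positions in mm in the grid's physical frame (phantom centred at 0).
#'
#' @param grid `grid_spec` to rasterize on.
#' @param hu Named list of class HU means and texture: `air`, `soft`, `bone`,
#'   `tumor`, `texture_sd` (smooth intra-soft-tissue heterogeneity),
#'   `texture_corr_mm`, `noise_sd` (fine acquisition noise).
#' @param seed Integer seed making generation fully deterministic.
#' @return An object of class `phantom_spec` (a list of geometry parameters).
#' @export
phantom_spec <- function(grid = phantom_grid("test"),
                         hu = list(air = -1000, soft = 40, bone = 700,
                                   tumor = 80, texture_sd = 25,
                                   texture_corr_mm = 10, noise_sd = 6),
                         seed = 1L) {
  spec <- list(
    grid = grid,
    hu = utils::modifyList(list(air = -1000, soft = 40, bone = 700, tumor = 80,
                                texture_sd = 25, texture_corr_mm = 10,
                                noise_sd = 6), hu),
    head = list(center = c(0, 0, 60), half_axes = c(75, 88, 72)),
    neck = list(half_axes = c(58, 64), z = c(-65, 35)),
    torso = list(half_axes = c(185, 92), z_top = -40),
    spine = list(center_xy = c(0, 34), radius = 14, z = c(-110, 45)),
    mandible = list(centers = rbind(c(-26, -42, 32), c(0, -52, 30), c(26, -42, 32)),
                    radius = 13),
    shoulders = list(centers = rbind(c(-120, 8, -80), c(120, 8, -80)),
                     half_axes = c(45, 30, 22)),
    cavities = list(
      trachea = list(center_xy = c(0, -12), radius = 9, z = c(-110, 40)),
      nasal = list(center = c(0, -46, 68), radius = 12)
    ),
    ctv_high = list(center = c(20, -2, 8), radius = 24),
    ctv_standard = list(p0 = c(30, 4, -8), p1 = c(52, 6, -68), radius = 14),
    seed = as.integer(seed)
  )
  if (spec$hu$air >= spec$hu$soft || spec$hu$soft >= spec$hu$bone) {
    stop("class HU must be ordered air < soft < bone", call. = FALSE)
  }
  class(spec) <- "phantom_spec"
  spec
}

#' Generate a planning CT and structure set from a phantom specification
#'
#' Deterministic given `spec$seed`. The returned structure set contains
#' `CTV_HIGH`, `CTV_STANDARD`, `EXTERNAL` plus bone/air surrogate masks used
#' by the anatomy-change and degradation simulators.
#'
#' @param spec A [phantom_spec()].
#' @return `list(ct = volume_image (HU), structures = structure_set)`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec", call. = FALSE)
  g <- spec$grid
  co <- grid_coords(g)
  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]
  sh <- g$shape

  head <- ellipsoid_mask(x, y, z, spec$head$center, spec$head$half_axes)
  neck <- (x / spec$neck$half_axes[1])^2 + (y / spec$neck$half_axes[2])^2 <= 1 &
    z >= spec$neck$z[1] & z <= spec$neck$z[2]
  torso <- (x / spec$torso$half_axes[1])^2 + (y / spec$torso$half_axes[2])^2 <= 1 &
    z <= spec$torso$z_top
  body <- head | neck | torso

  spine <- (x - spec$spine$center_xy[1])^2 + (y - spec$spine$center_xy[2])^2 <=
    spec$spine$radius^2 & z >= spec$spine$z[1] & z <= spec$spine$z[2]
  mand <- rep(FALSE, length(x))
  for (i in seq_len(nrow(spec$mandible$centers))) {
    mand <- mand | sphere_mask(x, y, z, spec$mandible$centers[i, ], spec$mandible$radius)
  }
  shoulder <- rep(FALSE, length(x))
  for (i in seq_len(nrow(spec$shoulders$centers))) {
    shoulder <- shoulder | ellipsoid_mask(x, y, z, spec$shoulders$centers[i, ],
                                          spec$shoulders$half_axes)
  }
  bone <- (spine | mand | shoulder) & body

  tr <- spec$cavities$trachea
  trachea <- (x - tr$center_xy[1])^2 + (y - tr$center_xy[2])^2 <= tr$radius^2 &
    z >= tr$z[1] & z <= tr$z[2] & body
  nasal <- sphere_mask(x, y, z, spec$cavities$nasal$center, spec$cavities$nasal$radius) & body
  cavity <- (trachea | nasal) & !bone

  ctv_high_raw <- sphere_mask(x, y, z, spec$ctv_high$center, spec$ctv_high$radius)
  ctv_std_raw <- capsule_mask(x, y, z, spec$ctv_standard$p0, spec$ctv_standard$p1,
                              spec$ctv_standard$radius)
  if (any(ctv_high_raw & !body) || any(ctv_std_raw & !body)) {
    stop("target escapes the body contour", call. = FALSE)
  }
  ctv_high <- ctv_high_raw & body & !bone & !cavity
  ctv_std <- ctv_std_raw & body & !bone & !cavity
  if (!any(ctv_high) || !any(ctv_std)) stop("a CTV is empty on this grid", call. = FALSE)

  hu <- rep(spec$hu$air, length(x))
  hu[body] <- spec$hu$soft
  hu[ctv_high | ctv_std] <- spec$hu$tumor
  hu[bone] <- spec$hu$bone
  hu[cavity] <- spec$hu$air
  hu <- array(hu, dim = sh)

  with_seed(spec$seed, {
    if (spec$hu$texture_sd > 0) {
      tex <- gaussian_smooth(array(stats::rnorm(prod(sh)), dim = sh),
                             spec$hu$texture_corr_mm, g$spacing)
      tex <- tex / stats::sd(tex) * spec$hu$texture_sd
      soft_only <- array(body & !bone & !cavity, dim = sh)
      hu <- hu + tex * soft_only
    }
    # slight partial-volume blur so edges carry gradient information
    hu <- gaussian_smooth(hu, 0.6 * min(g$spacing), g$spacing)
    if (spec$hu$noise_sd > 0) {
      hu <- hu + array(stats::rnorm(prod(sh), sd = spec$hu$noise_sd), dim = sh)
    }
  })

  masks <- list(
    EXTERNAL = array(body, dim = sh),
    CTV_HIGH = array(ctv_high, dim = sh),
    CTV_STANDARD = array(ctv_std, dim = sh),
    bone = array(bone, dim = sh),
    shoulders = array(shoulder & body, dim = sh),
    air_cavity = array(cavity, dim = sh)
  )
  roles <- c(EXTERNAL = "EXTERNAL", CTV_HIGH = "CTV_HIGH",
             CTV_STANDARD = "CTV_STANDARD", bone = "OTHER",
             shoulders = "OTHER", air_cavity = "OTHER")
  list(
    ct = volume_image(hu, g$spacing, g$origin, "HU"),
    structures = structure_set(masks, roles, g, check_fov_connectivity = FALSE)
  )
}

ellipsoid_mask <- function(x, y, z, center, half_axes) {
  ((x - center[1]) / half_axes[1])^2 + ((y - center[2]) / half_axes[2])^2 +
    ((z - center[3]) / half_axes[3])^2 <= 1
}

sphere_mask <- function(x, y, z, center, radius) {
  (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= radius^2
}

# distance-to-segment capsule
capsule_mask <- function(x, y, z, p0, p1, radius) {
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- pmin(pmax(((x - p0[1]) * v[1] + (y - p0[2]) * v[2] + (z - p0[3]) * v[3]) / L2, 0), 1)
  dx <- x - (p0[1] + t * v[1]); dy <- y - (p0[2] + t * v[2]); dz <- z - (p0[3] + t * v[3])
  dx^2 + dy^2 + dz^2 <= radius^2
}
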