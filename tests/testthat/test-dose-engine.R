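# uniform water box for transport sanity checks
water_box <- function(n = 50, sp = 2) {
  g <- grid_spec(rep(n, 3L), rep(sp, 3L), rep(0, 3L))
  volume_image(array(1, g$shape), g$spacing, g$origin, "DENSITY")
}

test_that("WEPL through water equals the geometric path", {
  spr <- water_box(60)
  # 100 mm window fully interior to the phantom, away from boundary ramps
  w <- compute_wepl(spr, entry = c(59, 59, -2), direction = c(0, 0, 1))
  at100 <- max(w$wepl_mm[w$t_mm <= 107]) - max(w$wepl_mm[w$t_mm <= 7])
  expect_lt(abs(at100 - 100), 0.5)
})

test_that("WEPL through a slab phantom matches the closed-form sum", {
  g <- grid_spec(c(20, 20, 80), c(2, 2, 1), c(0, 0, 0))
  v <- array(0.001, g$shape)
  v[, , 6:55] <- 1.0      # 50 mm of water
  v[, , 56:75] <- 1.5     # 20 mm at SPR 1.5 -> 30 mm WEPL
  spr <- volume_image(v, g$spacing, g$origin, "DENSITY")
  w <- compute_wepl(spr, entry = c(19, 19, 4.5), direction = c(0, 0, 1),
                    length_mm = 71)
  expect_lt(abs(max(w$wepl_mm) - 80), 0.5)
})

test_that("halving the step changes WEPL by less than 0.2 mm", {
  ph <- fx_phantom()
  spr <- hu_to_spr(ph$ct)
  e <- c(0, -140, 0); d <- c(0, 1, 0)
  w1 <- compute_wepl(spr, e, d, length_mm = 250, step_mm = 2)
  w2 <- compute_wepl(spr, e, d, length_mm = 250, step_mm = 1)
  expect_lt(abs(max(w1$wepl_mm) - max(w2$wepl_mm)), 0.2)
})

test_that("a ray missing the grid yields an empty profile", {
  spr <- water_box()
  w <- compute_wepl(spr, entry = c(500, 500, 0), direction = c(0, 0, 1))
  expect_identical(nrow(w), 0L)
})

fx_plan <- function() {
  cached("plan", {
    ph <- fx_phantom()
    spr <- hu_to_spr(ph$ct)
    list(ph = ph, spr = spr,
         plan = plan_beams(ph$structures, spr, "anterior_3"))
  })
}

test_that("three-beam preset: 3 beams, weights summing to 1, covering ranges", {
  pl <- fx_plan()$plan
  expect_identical(length(pl$beams), 3L)
  expect_equal(sum(vapply(pl$beams, function(b) b$weight, 0)), 1)
  # distal range along the central axis covers the WEPL to the distal edge
  ph <- fx_plan()$ph
  spr <- fx_plan()$spr
  tgt <- ph$structures$masks$CTV_HIGH | ph$structures$masks$CTV_STANDARD
  g <- grid_of(ph$ct)
  ctr <- mask_centroid(tgt, g)
  b1 <- pl$beams[[1]]   # anterior beam, +y
  w <- compute_wepl(spr, c(ctr[1], g$origin[2], ctr[3]), c(0, 1, 0))
  co <- grid_coords(g)
  y_distal <- max(co[as.vector(tgt), 2])
  wepl_distal <- max(w$wepl_mm[w$t_mm <= y_distal - g$origin[2]])
  expect_gte(max(b1$range_map, na.rm = TRUE), wepl_distal)
})

test_that("beam axis of a single-beam plan passes through the target centroid", {
  ph <- fx_phantom()
  spr <- hu_to_spr(ph$ct)
  pl <- plan_beams(ph$structures, spr, "single")
  b <- pl$beams[[1]]
  g <- grid_of(ph$ct)
  tgt <- ph$structures$masks$CTV_HIGH | ph$structures$masks$CTV_STANDARD
  ctr <- mask_centroid(tgt, g)
  # centroid of the aperture in lateral beam coordinates vs target centroid
  ap_idx <- which(b$aperture, arr.ind = TRUE)
  ap_ctr <- b$grid$lo[1:2] + (colMeans(ap_idx) - 1) * b$grid$spacing[1:2]
  ctr_bf <- as.vector(ctr %*% b$grid$B)[1:2]
  expect_lt(max(abs(ap_ctr - ctr_bf)), 2 * max(g$spacing))
})

test_that("planned geometry reproduces D99(CTV_HIGH) = 100% and is deterministic", {
  fx <- fx_plan()
  dose <- compute_dose_proxy(fx$spr, fx$plan)
  d99 <- d_metric(compute_dvh(dose, fx$ph$structures$masks$CTV_HIGH), 0.99)
  expect_equal(d99, 100, tolerance = 1e-9)
  dose2 <- compute_dose_proxy(fx$spr, fx$plan)
  expect_identical(dose$voxels, dose2$voxels)
})

test_that("uniform water reproduces the 1D depth dose within 1%", {
  spr <- water_box()
  g <- grid_of(spr)
  m <- array(FALSE, g$shape); m[20:30, 20:30, 20:30] <- TRUE
  ss <- structure_set(list(CTV_HIGH = m, CTV_STANDARD = m),
                      c(CTV_HIGH = "CTV_HIGH", CTV_STANDARD = "CTV_STANDARD"), g)
  pl <- plan_beams(ss, spr, "single")
  dose <- compute_dose_proxy(spr, pl)
  b <- pl$beams[[1]]
  # planned range of the ray through the axis voxels (48, ., 48)
  axis_bf <- as.vector(c(48, 0, 48) %*% b$grid$B)[1:2]
  li <- round((axis_bf - b$grid$lo[1:2]) / b$grid$spacing[1:2]) + 1
  rng <- b$range_map[li[1], li[2]]
  # central-axis profile: plateau then linear falloff over 5 mm WEPL.
  # the 1D model's range parameter is fitted (integration conventions may
  # differ by a fraction of a depth step) and must agree with the planned
  # range within half a step; the profile must then match within 1%.
  co <- grid_coords(g)
  axis_idx <- which(abs(co[, 1] - 48) < 0.1 & abs(co[, 3] - 48) < 0.1)
  depth <- co[axis_idx, 2] + 1   # geometric depth in water from the surface
  got <- dose$voxels[axis_idx]
  inside <- depth > 2 & depth < 95
  shape_err <- function(r) {
    max(abs(got[inside] -
              (pmin(pmax((r + 5 - depth[inside]) / 5, 0), 1) * pl$norm)))
  }
  rs <- seq(rng - 2, rng + 2, by = 0.01)
  errs <- vapply(rs, shape_err, 0)
  r_star <- rs[which.min(errs)]
  expect_lt(min(errs) / 100, 0.01)
  expect_lt(abs(r_star - rng), b$grid$spacing[3] / 2 + 0.01)
})

test_that("a 10 mm upstream water-equivalent insult undershoots the distal target", {
  fx <- fx_plan()
  ph <- fx$ph
  g <- grid_of(ph$ct)
  co <- grid_coords(g)
  tgt <- ph$structures$masks$CTV_HIGH
  # slab of extra density anterior (upstream for the +y anterior beam) of the target
  hu <- ph$ct$voxels
  slab <- co[, 2] > -95 & co[, 2] < -75 & abs(co[, 1]) < 120 & abs(co[, 3]) < 90
  # +10 mm WEPL over 20 mm path: SPR 1 -> 1.5 means delta HU ~ +910
  hu[slab] <- hu[slab] + 910
  pert <- volume_image(hu, g$spacing, g$origin, "HU")
  dose <- compute_dose_proxy(hu_to_spr(pert), fx$plan)
  # distal-most target voxels for the anterior beam (largest y)
  y_t <- co[as.vector(tgt), 2]
  distal <- array(as.vector(tgt) & co[, 2] > max(y_t) - 6, g$shape)
  # anterior beam carries weight 0.4; its distal contribution should collapse
  base <- compute_dose_proxy(hu_to_spr(ph$ct), fx$plan)
  expect_lt(mean(dose$voxels[distal]), mean(base$voxels[distal]) - 25)
  # range-shift monotonicity: increasing insult never increases D99
  d99s <- vapply(c(0, 300, 600, 910), function(extra) {
    hu2 <- ph$ct$voxels
    hu2[slab] <- hu2[slab] + extra
    dd <- compute_dose_proxy(hu_to_spr(volume_image(hu2, g$spacing, g$origin, "HU")),
                             fx$plan)
    d_metric(compute_dvh(dd, tgt), 0.99)
  }, 0)
  expect_true(all(diff(d99s) <= 1e-9))
})

test_that("total dose is invariant under a beam-aligned rotation of the scene", {
  spr <- water_box()
  g <- grid_of(spr)
  m <- array(FALSE, g$shape); m[22:28, 22:28, 22:28] <- TRUE
  ss <- structure_set(list(CTV_HIGH = m, CTV_STANDARD = m),
                      c(CTV_HIGH = "CTV_HIGH", CTV_STANDARD = "CTV_STANDARD"), g)
  pl <- plan_beams(ss, spr, "single")           # beam along +y
  dose <- compute_dose_proxy(spr, pl)
  # rotate scene 90 degrees about the beam axis: x <-> z for the mask
  m2 <- aperm(m, c(3, 2, 1))
  ss2 <- structure_set(list(CTV_HIGH = m2, CTV_STANDARD = m2),
                       c(CTV_HIGH = "CTV_HIGH", CTV_STANDARD = "CTV_STANDARD"), g)
  pl2 <- plan_beams(ss2, spr, "single")
  dose2 <- compute_dose_proxy(spr, pl2)
  expect_lt(abs(sum(dose$voxels) - sum(dose2$voxels)) / sum(dose$voxels), 0.01)
})

test_that("DVH curve and D-metrics agree with brute-force counting", {
  g <- small_grid(10, 2)
  set.seed(21)
  for (rep in 1:50) {
    dose <- volume_image(array(runif(prod(g$shape), 0, 110), g$shape),
                         g$spacing, g$origin, "DOSE")
    mask <- array(runif(prod(g$shape)) > 0.4, g$shape)
    if (!any(mask)) next
    dv <- compute_dvh(dose, mask)
    doses <- dose$voxels[mask]
    qs <- runif(20, 0, 110)
    expect_identical(dvh_fraction(dv, qs),
                     vapply(qs, function(q) mean(doses >= q), 0))
    # D99 equals the sorting-based order statistic exactly
    n <- length(doses)
    k <- ceiling(0.99 * n)
    expect_identical(d_metric(dv, 0.99), sort(doses, decreasing = TRUE)[k])
  }
})

test_that("D99 worked examples and monotonicity in the volume fraction", {
  g <- grid_spec(c(10, 10, 1), c(1, 1, 1), c(0, 0, 0))
  v <- array(100, g$shape); v[1, 1, 1] <- 0
  dv <- compute_dvh(volume_image(v, g$spacing, g$origin, "DOSE"),
                    array(TRUE, g$shape))
  expect_identical(d_metric(dv, 0.99), 100)
  v[2, 1, 1] <- 0
  dv2 <- compute_dvh(volume_image(v, g$spacing, g$origin, "DOSE"),
                     array(TRUE, g$shape))
  expect_identical(d_metric(dv2, 0.99), 0)

  set.seed(3)
  for (rep in 1:10) {
    dv3 <- compute_dvh(volume_image(array(runif(100), c(5, 5, 4)),
                                    c(1, 1, 1), c(0, 0, 0), "DOSE"),
                       array(TRUE, c(5, 5, 4)))
    fs <- sort(runif(8, 0.01, 0.99))
    vals <- vapply(fs, function(f) d_metric(dv3, f), 0)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("uniform dose gives a step DVH normalized to full volume at zero", {
  g <- small_grid(6)
  dv <- compute_dvh(volume_image(array(100, g$shape), g$spacing, g$origin, "DOSE"),
                    array(TRUE, g$shape))
  expect_identical(d_metric(dv, 0.99), 100)
  expect_identical(dvh_fraction(dv, 0), 1)
  expect_identical(dvh_fraction(dv, 100), 1)
  expect_identical(dvh_fraction(dv, 100.0001), 0)
  expect_error(compute_dvh(volume_image(array(1, g$shape), g$spacing,
                                        g$origin, "DOSE"),
                           array(FALSE, g$shape)), "empty")
})
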