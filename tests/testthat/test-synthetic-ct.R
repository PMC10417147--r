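test_that("joint histogram: identity pair is diagonal and counts are conserved", {
  g <- small_grid()
  v <- rand_volume(g, seed = 6)
  mask <- array(TRUE, g$shape)
  jh <- build_joint_histogram(v, volume_image(v$voxels, g$spacing, g$origin,
                                              "CBCT_GRAY"), mask, 32)
  expect_identical(sum(jh$counts), sum(mask))
  # equal binning on identical values: all mass on the diagonal
  expect_identical(sum(diag(jh$counts)), sum(mask))
  expect_error(build_joint_histogram(v, v, array(FALSE, g$shape)), "empty")
})

test_that("two-class image pair yields exactly two modes at the class values", {
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2), c(0, 0, 0))
  set.seed(8)
  cls <- array(runif(prod(g$shape)) > 0.5, g$shape)
  hu <- array(ifelse(cls, 60, -950) + rnorm(prod(g$shape), 0, 10), g$shape)
  gray <- 0.7 * hu + 100 + rnorm(prod(g$shape), 0, 8)
  a <- volume_image(hu, g$spacing, g$origin, "HU")
  b <- volume_image(gray, g$spacing, g$origin, "CBCT_GRAY")
  jh <- build_joint_histogram(a, b, array(TRUE, g$shape), 64)
  pts <- identify_tissue_classes(jh, 4)
  expect_identical(nrow(pts), 2L)
  expect_lt(abs(pts$hu[1] - (-950)), 30)
  expect_lt(abs(pts$hu[2] - 60), 30)
  expect_lt(abs(pts$gray[1] - (0.7 * -950 + 100)), 30)
  # determinism
  expect_identical(pts, identify_tissue_classes(jh, 4))
})

test_that("single-mode histograms raise the degenerate-histogram error", {
  g <- small_grid()
  v <- volume_image(array(rnorm(prod(g$shape), 50, 5), g$shape), g$spacing,
                    g$origin, "HU")
  b <- volume_image(v$voxels * 0.8, g$spacing, g$origin, "CBCT_GRAY")
  jh <- build_joint_histogram(v, b, array(TRUE, g$shape), 64)
  expect_error(identify_tissue_classes(jh), "degenerate")
})

test_that("phantom tissue classes land within 30 HU of the class means", {
  ph <- fx_phantom()
  sim <- fx_clean_sim()
  ch <- fx_changed()
  g <- grid_of(ph$ct)
  focus <- retract_fov(sim$fov, 20, g$spacing)
  jh <- build_joint_histogram(ch$ct, sim$cbct, focus, 96)
  pts <- identify_tissue_classes(jh, 4)
  expect_gte(nrow(pts), 2L)
  # always includes an air-class and a soft-tissue-class point
  expect_lt(min(pts$hu), -800)
  expect_true(any(abs(pts$hu - 40) < 30))
})

test_that("conversion function: interpolation, extrapolation, clamping, junctions", {
  cv <- conversion_function(c(0, 1000), c(-1000, 0))
  expect_identical(predict(cv, 500), -500)
  expect_identical(predict(cv, c(0, 1000)), c(-1000, 0))
  # single segment equals the unique line through the two points
  set.seed(9)
  gs <- runif(100, -500, 1500)
  expect_lt(max(abs(predict(cv, gs) - pmax(gs - 1000, -1024))), 1e-9)
  # clamped to the representable HU range
  expect_identical(predict(cv, -1e5), -1024)
  expect_identical(conversion_function(c(0, 1), c(0, 1e5)) |> predict(1e5), 3071)
})

test_that("fit_conversion_function sorts, monotonizes and warns", {
  pts <- tibble::tibble(gray = c(500, -760, 72), hu = c(700, -1000, 40))
  cv <- fit_conversion_function(pts)
  expect_identical(cv$gray, sort(pts$gray))
  expect_true(!is.unsorted(cv$hu))
  bad <- tibble::tibble(gray = c(0, 100, 200), hu = c(0, 300, 100))
  expect_warning(cv2 <- fit_conversion_function(bad), "isotonic")
  expect_true(!is.unsorted(cv2$hu))
  expect_error(fit_conversion_function(tibble::tibble(gray = 1, hu = 1)), ">= 2")
})

test_that("artifact map: zero for identical inputs, recovers planted shading", {
  ph <- fx_phantom()
  g <- grid_of(ph$ct)
  deg <- cbct_degradation_spec(fov_diameter_mm = 260, gain = 1, offset = 0,
                               shading_amplitude = 80, noise_sd = 0, seed = 7)
  sim <- simulate_cbct(ph$ct, deg)
  cb_hu <- volume_image(sim$cbct$voxels, g$spacing, g$origin, "HU")

  zero <- estimate_artifact_map(ph$ct, ph$ct, sim$fov)
  expect_lt(max(abs(zero$map)), 1e-9)

  am <- estimate_artifact_map(cb_hu, ph$ct, sim$fov)
  inner <- retract_fov(sim$fov, 15, g$spacing)
  shading <- (cb_hu$voxels - ph$ct$voxels)
  amp_ratio <- sum(am$map[inner] * shading[inner]) / sum(shading[inner]^2)
  expect_gte(amp_ratio, 0.8)
  expect_lt(mean(abs(shading - am$map)[inner]), 15)
  # the map is genuinely low-frequency
  expect_gt(spectral_low_fraction(am$map, g$spacing, 1 / 50), 0.95)
})

test_that("a one-voxel impulse leaks under 10% into the artifact map", {
  ph <- fx_phantom()
  g <- grid_of(ph$ct)
  sim <- fx_clean_sim()
  spike <- array(0, g$shape); spike[48, 32, 28] <- 500
  a <- volume_image(spike, g$spacing, g$origin, "HU")
  b <- volume_image(spike * 0, g$spacing, g$origin, "HU")
  am <- estimate_artifact_map(a, b, sim$fov)
  expect_lt(max(abs(am$map)) / 500, 0.1)
})

test_that("density and SPR calibrations hit their anchors and closed forms", {
  g <- small_grid(4)
  img <- function(h) volume_image(array(h, g$shape), g$spacing, g$origin, "HU")
  expect_equal(to_density(img(0))$voxels[1], 1.0)
  expect_equal(to_density(img(-1000))$voxels[1], 0.001)
  expect_equal(to_density(img(750))$voxels[1], 1.0 + 750 / 1500 * 0.85)
  expect_equal(hu_to_spr(img(0))$voxels[1], 1.0)
  expect_equal(hu_to_spr(img(-1000))$voxels[1], 0.001)
  expect_equal(hu_to_spr(img(600))$voxels[1], 1.0 + 600 / 1500 * 0.55)
  expect_error(hu_calibration(c(0, 100), c(1, 0.5)), "monotone")
})

test_that("virtual-CT masking rule matches its worked examples", {
  # densities -> HU via the piecewise default-calibration inverse
  hu_of <- function(rho) ifelse(rho >= 1, (rho - 1) * 1500 / 0.85,
                                (rho - 1) * 1000 / 0.999)
  g <- grid_spec(c(2, 2, 1), c(1, 1, 1), c(0, 0, 0))
  base_hu <- c(hu_of(1.00), hu_of(1.80), hu_of(1.00), hu_of(1.00))
  corr_hu <- c(hu_of(0.20), hu_of(1.20), hu_of(1.00), hu_of(0.75))
  pct <- volume_image(array(base_hu, g$shape), g$spacing, g$origin, "HU")
  corr <- volume_image(array(corr_hu, g$shape), g$spacing, g$origin, "HU")
  fov <- array(TRUE, g$shape)
  out <- make_virtct(pct, corr, corr, identity_field(g), fov)
  # (1.00 vs 0.20): overridden; (1.80 vs 1.20): NOT (neither < 0.6);
  # equal densities: not; (1.00 vs 0.75): delta 0.25 < 0.3: not
  expect_identical(as.vector(out$override), c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$virtct$voxels[2, 1, 1], out$base$voxels[2, 1, 1])
  expect_identical(out$virtct$voxels[1, 1, 1], corr$voxels[1, 1, 1])
})

test_that("override set equals the brute-force rule on random densities, boundaries excluded", {
  g <- grid_spec(c(64, 64, 64), c(1, 1, 1), c(0, 0, 0))
  set.seed(13)
  n <- prod(g$shape)
  rho_v <- runif(n, 0, 2)
  rho_c <- runif(n, 0, 2)
  # pack the density grid around the 0.3 / 0.6 boundaries so near-threshold
  # voxels are well represented
  rho_v[1:3000] <- 0.6 + runif(3000, -0.02, 0.02)
  rho_c[1:3000] <- rho_v[1:3000] + sample(c(-1, 1), 3000, TRUE) *
    (0.3 + runif(3000, -0.02, 0.02))
  hu_of <- function(rho) ifelse(rho >= 1, (rho - 1) * 1500 / 0.85,
                                (rho - 1) * 1000 / 0.999)
  pct <- volume_image(array(hu_of(rho_v), g$shape), g$spacing, g$origin, "HU")
  corr <- volume_image(array(hu_of(rho_c), g$shape), g$spacing, g$origin, "HU")
  fov <- array(TRUE, g$shape)
  t0 <- Sys.time()
  out <- make_virtct(pct, corr, corr, identity_field(g), fov)
  rv <- to_density(out$base)$voxels; rc <- to_density(corr)$voxels
  brute <- (abs(rv - rc) > 0.3) & (pmin(rv, rc) < 0.6)
  expect_identical(as.vector(out$override), as.vector(brute))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 10)
})
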