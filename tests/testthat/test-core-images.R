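test_that("volume_image validates its invariants", {
  expect_error(volume_image(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(volume_image(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(volume_image(array(c(0, NA), c(2, 2, 2)), c(1, 1, 1)), "finite")
  v <- volume_image(array(0, c(2, 3, 4)), c(1, 2, 3), c(-1, 0, 1), "CBCT_GRAY")
  expect_identical(dim(v), c(2L, 3L, 4L))
  expect_identical(v$kind, "CBCT_GRAY")
})

test_that("NIfTI round-trip is bit-exact for integer volumes", {
  g <- small_grid()
  zero <- volume_image(array(0, g$shape), c(0.54, 0.54, 2.50), c(-5, 3, 10), "HU")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(zero, f)
  back <- read_volume(f, "HU")
  expect_identical(back$voxels, zero$voxels)
  expect_equal(back$spacing, c(0.54, 0.54, 2.50), tolerance = 1e-6)
  expect_equal(back$origin, c(-5, 3, 10), tolerance = 1e-4)

  for (seed in 1:10) {
    v <- rand_volume(g, seed = seed, integer = TRUE)
    write_volume(v, f)
    back <- read_volume(f, "HU")
    expect_identical(max(abs(back$voxels - v$voxels)), 0)
  }
})

test_that("floating volumes survive IO within tight tolerance", {
  g <- small_grid()
  v <- rand_volume(g, seed = 11)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  expect_lt(max(abs(read_volume(f)$voxels - v$voxels)), 1e-6)
})

test_that("read_volume rejects missing and non-3D data", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4))), f)
  expect_error(read_volume(f), "3D")
})

test_that("structure sets round-trip through the labeled volume + sidecar", {
  g <- small_grid()
  m1 <- array(FALSE, g$shape); m1[4:9, 4:9, 4:9] <- TRUE
  m2 <- array(FALSE, g$shape); m2[6:12, 6:12, 6:12] <- TRUE
  ss <- structure_set(list(EXTERNAL = m2 | m1, CTV_HIGH = m1),
                      c(EXTERNAL = "EXTERNAL", CTV_HIGH = "CTV_HIGH"), g)
  f <- tempfile(fileext = ".nii.gz")
  write_structures(ss, f)
  back <- read_structures(f)
  expect_identical(back$masks$CTV_HIGH, ss$masks$CTV_HIGH)
  expect_identical(back$masks$EXTERNAL, ss$masks$EXTERNAL)
  expect_identical(unname(back$roles["CTV_HIGH"]), "CTV_HIGH")
})

test_that("structure_set enforces grid agreement, CTV non-emptiness and FOV connectivity", {
  g <- small_grid()
  empty <- array(FALSE, g$shape)
  expect_error(structure_set(list(CTV_HIGH = empty),
                             c(CTV_HIGH = "CTV_HIGH"), g), "empty")
  two <- array(FALSE, g$shape); two[2, 2, 2] <- TRUE; two[14, 14, 14] <- TRUE
  expect_error(structure_set(list(FOV = two), c(FOV = "FOV"), g), "connected")
  small <- array(FALSE, c(4, 4, 4)); small[2, 2, 2] <- TRUE
  expect_error(structure_set(list(a = small), NULL, g), "grid shape")
})

test_that("resampling: identity grid, constant field, and analytic ramp shift", {
  g <- small_grid()
  v <- rand_volume(g, seed = 2)
  same <- resample_to_grid(v, g, "linear")
  expect_identical(same$voxels, v$voxels)

  cst <- volume_image(array(7, g$shape), g$spacing, g$origin, "DOSE")
  tg <- grid_spec(c(10, 10, 10), g$spacing, g$origin + 3)
  out <- resample_to_grid(cst, tg, "linear")
  expect_true(all(abs(out$voxels - 7) < 1e-12))

  # linear ramp in x, shifted by half a voxel
  co <- array(rep(g$origin[1] + (0:(g$shape[1] - 1)) * g$spacing[1],
                  times = prod(g$shape[2:3])), dim = g$shape)
  ramp <- volume_image(co, g$spacing, g$origin, "DOSE")
  tg <- grid_spec(g$shape - 1L, g$spacing, g$origin + g$spacing / 2)
  out <- resample_to_grid(ramp, tg, "linear")
  expected <- tg$origin[1] + (0:(tg$shape[1] - 1)) * tg$spacing[1]
  got <- out$voxels[, 1, 1]
  expect_lt(max(abs(got - expected)), 1e-6)
})

test_that("nearest-neighbour resampling maps binary masks to binary masks", {
  g <- small_grid()
  set.seed(5)
  m <- array(runif(prod(g$shape)) > 0.5, g$shape)
  tg <- grid_spec(c(11, 13, 9), c(2.7, 2.3, 3.1), g$origin + 1)
  out <- resample_mask(m, g, tg)
  expect_type(out, "logical")
  expect_identical(dim(out), tg$shape)
})

test_that("resample_to_grid rejects unknown interpolation", {
  g <- small_grid()
  expect_error(resample_to_grid(rand_volume(g), g, "cubic"))
})

test_that("distance transform matches the brute-force oracle", {
  set.seed(42)
  for (rep in 1:3) {
    m <- array(runif(6 * 5 * 4) > 0.45, c(6, 5, 4))
    sp <- c(1.2, 0.9, 2.0)
    d <- sqrt(sq_distance_transform(m, sp))
    expect_equal(d, brute_distance(m, sp), tolerance = 1e-9)
  }
})

test_that("eroded sphere voxel count equals brute-force distance thresholding", {
  g <- grid_spec(c(24, 24, 24), c(2, 2, 2), c(0, 0, 0))
  co <- grid_coords(g)
  m <- array(sqrt(rowSums(sweep(co, 2, c(23, 23, 23))^2)) <= 18, g$shape)
  margin <- 5
  er <- retract_fov(m, margin, g$spacing)
  bf <- brute_distance(m, g$spacing)
  expect_identical(er, m & bf > margin)
})

test_that("FOV retraction honours the clinical geometry and margins", {
  g <- grid_spec(c(70, 70, 8), c(4.2, 4.2, 4), -c(69, 69, 7) * c(4.2, 4.2, 4) / 2)
  co <- grid_coords(g)
  fov <- array(co[, 1]^2 + co[, 2]^2 <= 130^2, g$shape)
  expect_identical(retract_fov(fov, 0, g$spacing), fov)
  er <- retract_fov(fov, 20, g$spacing)
  r_out <- sqrt(co[, 1]^2 + co[, 2]^2)[as.vector(er)]
  expect_lt(max(r_out), 112)   # ~110 mm radius after retraction
  expect_gt(max(r_out), 105)
  expect_error(retract_fov(fov, 200, g$spacing), "empty focus")
})

test_that("retraction by a+b equals sequential retraction up to voxelization", {
  g <- grid_spec(c(30, 30, 20), c(2, 2, 3), c(0, 0, 0))
  co <- grid_coords(g)
  m <- array(sqrt(rowSums(sweep(co, 2, c(29, 29, 28))^2)) <= 24, g$shape)
  ab <- retract_fov(m, 10, g$spacing)
  seq2 <- retract_fov(retract_fov(m, 6, g$spacing), 4, g$spacing)
  # disagreement may only sit within one voxel diagonal of the threshold
  d <- brute_distance(m, g$spacing)
  mismatch <- xor(ab, seq2)
  if (any(mismatch)) {
    expect_lt(max(abs(d[mismatch] - 10)), sqrt(sum(g$spacing^2)))
  }
  expect_true(all(ab[d > 10 + sqrt(sum(g$spacing^2))] ==
                    seq2[d > 10 + sqrt(sum(g$spacing^2))]))
})
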