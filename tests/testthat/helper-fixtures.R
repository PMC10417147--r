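# shared lazily-built fixtures; expensive objects are computed once per run
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# default downscaled phantom
fx_phantom <- function() cached("phantom", generate_phantom(phantom_spec()))

# noise-free phantom for registration recovery
fx_phantom_clean <- function() {
  cached("phantom_clean", generate_phantom(phantom_spec(hu = list(noise_sd = 0))))
}

# treatment-day anatomy: 16.4% shrink, 6 mm inferior shoulder shift, cavity fill
fx_changed <- function() {
  cached("changed", {
    ph <- fx_phantom()
    apply_anatomy_change(ph$ct, ph$structures,
                         anatomy_change_spec(0.164, c(0, 0, -6), 0.4, seed = 2))
  })
}

# CBCT with the systematic degradations the correction must undo:
# gain 0.8 / offset 40 gray map plus 80-gray smooth shading
fx_degraded_sim <- function() {
  cached("degraded_sim",
         simulate_cbct(fx_changed()$ct,
                       cbct_degradation_spec(gain = 0.8, offset = 40,
                                             shading_amplitude = 80,
                                             noise_sd = 0, seed = 3)))
}

# artifact-free CBCT (identity-recoverable gray map) from the same anatomy
fx_clean_sim <- function() {
  cached("clean_sim", {
    simulate_cbct(fx_changed()$ct,
                  cbct_degradation_spec(gain = 0.8, offset = 40,
                                        shading_amplitude = 0, noise_sd = 0,
                                        seed = 4))
  })
}

# the expensive corrected-CBCT fit on the degraded case
fx_corr <- function() {
  cached("corr", {
    ph <- fx_phantom()
    sim <- fx_degraded_sim()
    make_corrcbct(ph$ct, sim$cbct, sim$fov)
  })
}

# ground-truth CT fixture at unchanged geometry (shared by several files)
fx_gtct_identity <- function() {
  cached("gtct_identity", {
    ch <- fx_changed()
    sim <- simulate_cbct(ch$ct, cbct_degradation_spec(gain = 0.8, offset = 40,
                                                      shading_amplitude = 60,
                                                      noise_sd = 0, seed = 11))
    make_gtct(ch$ct, sim$cbct, sim$fov)
  })
}

small_grid <- function(n = 16L, sp = 2) {
  grid_spec(rep(n, 3L), rep(sp, 3L), rep(0, 3L))
}

rand_volume <- function(grid, seed = 1, kind = "HU", integer = FALSE) {
  set.seed(seed)
  v <- array(rnorm(prod(grid$shape), 0, 300), dim = grid$shape)
  if (integer) v <- round(v)
  volume_image(v, grid$spacing, grid$origin, kind)
}

# brute-force Euclidean distance from each voxel centre to the nearest
# background voxel centre (oracle for the distance transform)
brute_distance <- function(mask, spacing) {
  co <- which(mask | !mask, arr.ind = TRUE)  # all voxels
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, dim = dim(mask))
  if (nrow(bg) == 0L) return(array(Inf, dim = dim(mask)))
  for (i in seq_len(nrow(co))) {
    d2 <- ((co[i, 1] - bg[, 1]) * spacing[1])^2 +
      ((co[i, 2] - bg[, 2]) * spacing[2])^2 +
      ((co[i, 3] - bg[, 3]) * spacing[3])^2
    out[co[i, 1], co[i, 2], co[i, 3]] <- sqrt(min(d2))
  }
  out
}
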