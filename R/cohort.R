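#' Cohort scenario distributions
#'
#' Distributions from which per-case anatomy changes, CBCT degradations and
#' planted coverage-loss values are drawn. The defaults emulate the
#' monitoring population the trigger thresholds were designed for: mean
#' early-course target shrinkage 16.4%, inferior shoulder shifts of a few
#' mm, a roughly one-in-five planted review rate, and surrogate D99 errors
#' that are largest for the verification CT and smallest for the virtual CT.
#'
#' @param p_trigger Probability a case is planted above a review threshold.
#' @param shrink_mean,shrink_sd Target shrink fraction distribution
#'   (truncated to `[0, 0.45]`).
#' @param shoulder_shift_sd_mm SD of the inferior (negative-Z) shoulder
#'   shift magnitude.
#' @param p_cavity_fill Probability of an air-cavity filling event; the
#'   filled fraction is then uniform on (0.2, 0.9).
#' @param loss_high,loss_std Mean/SD of planted non-trigger coverage loss
#'   (percentage points) for high-risk and standard-risk targets.
#' @param surrogate_sd Named SDs of planted surrogate D99 error vs ground
#'   truth for `VFCT`, `CORRCBCT`, `VIRTCT`.
#' @param degradation Baseline [cbct_degradation_spec()] parameters
#'   (per-case seeds and gain/offset jitter are added on top).
#' @return A list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(p_trigger = 0.19,
                            shrink_mean = 0.164, shrink_sd = 0.06,
                            shoulder_shift_sd_mm = 3,
                            p_cavity_fill = 0.3,
                            loss_high = c(mean = 1.2, sd = 0.9),
                            loss_std = c(mean = 1.6, sd = 1.2),
                            surrogate_sd = c(VFCT = 1.5, CORRCBCT = 0.7,
                                             VIRTCT = 0.5),
                            degradation = list(gain = 0.8, offset = 40,
                                               shading_amplitude = 60,
                                               noise_sd = 15)) {
  structure(list(p_trigger = p_trigger, shrink_mean = shrink_mean,
                 shrink_sd = shrink_sd,
                 shoulder_shift_sd_mm = shoulder_shift_sd_mm,
                 p_cavity_fill = p_cavity_fill, loss_high = loss_high,
                 loss_std = loss_std, surrogate_sd = surrogate_sd,
                 degradation = degradation),
            class = "cohort_scenario")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-case specifications from the scenario distributions. Every
#' case records: the phantom / anatomy-change / CBCT-degradation specs with
#' their seeds, the planted ground-truth D99 losses and surrogate errors
#' (strictly above or below the review thresholds, so downstream trigger
#' counts can be checked against the plant list exactly), and a planted
#' review flag. With `write_images = TRUE` the pCT, treatment-day CT
#' (vfCT), CBCT, FOV and structures are generated and written under
#' `dir/case_###/`; a JSON manifest with full provenance is always written
#' when `dir` is given. Pure function of `seed`.
#'
#' @param n Number of cases (`>= 1`).
#' @param scenario A [cohort_scenario()].
#' @param seed Integer master seed.
#' @param dir Optional output directory (created).
#' @param write_images Also rasterize and write the image volumes.
#' @param grid `grid_spec` for generated phantoms.
#' @return An object of class `cohort`: `cases` (tibble of per-case specs
#'   and planted values), `scenario`, `seed`, `dir`.
#' @export
generate_cohort <- function(n, scenario = cohort_scenario(), seed = 1L,
                            dir = NULL, write_images = FALSE,
                            grid = phantom_grid("test")) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  sc <- scenario
  thr <- trigger_thresholds()
  cases <- with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      shrink <- min(max(stats::rnorm(1, sc$shrink_mean, sc$shrink_sd), 0), 0.45)
      shift_z <- -abs(stats::rnorm(1, 0, sc$shoulder_shift_sd_mm))
      cavity <- if (stats::runif(1) < sc$p_cavity_fill) stats::runif(1, 0.2, 0.9) else 0
      gain <- sc$degradation$gain * stats::runif(1, 0.95, 1.05)
      offset <- sc$degradation$offset + stats::rnorm(1, 0, 10)

      is_trigger <- stats::runif(1) < sc$p_trigger
      if (is_trigger) {
        mode <- sample(c("high", "standard", "both"), 1)
        lh <- if (mode %in% c("high", "both")) {
          thr[["CTV_HIGH"]] + 0.3 + abs(stats::rnorm(1, 0, 1.5))
        } else {
          min(max(stats::rnorm(1, sc$loss_high[["mean"]], sc$loss_high[["sd"]]),
                  -1), thr[["CTV_HIGH"]] - 0.2)
        }
        ls <- if (mode %in% c("standard", "both")) {
          thr[["CTV_STANDARD"]] + 0.3 + abs(stats::rnorm(1, 0, 2))
        } else {
          min(max(stats::rnorm(1, sc$loss_std[["mean"]], sc$loss_std[["sd"]]),
                  -1), thr[["CTV_STANDARD"]] - 0.2)
        }
      } else {
        lh <- min(max(stats::rnorm(1, sc$loss_high[["mean"]], sc$loss_high[["sd"]]),
                      -1), thr[["CTV_HIGH"]] - 0.2)
        ls <- min(max(stats::rnorm(1, sc$loss_std[["mean"]], sc$loss_std[["sd"]]),
                      -1), thr[["CTV_STANDARD"]] - 0.2)
      }
      err <- lapply(sc$surrogate_sd, function(s) stats::rnorm(2, 0, s))
      rows[[i]] <- tibble::tibble(
        case_id = sprintf("case_%03d", i),
        phantom_seed = sample.int(1e6, 1),
        change_seed = sample.int(1e6, 1),
        cbct_seed = sample.int(1e6, 1),
        shrink = shrink, shift_z = shift_z, cavity_fill = cavity,
        gain = gain, offset = offset,
        planted_review = is_trigger,
        loss_high = lh, loss_std = ls,
        err_vfct_high = err$VFCT[1], err_vfct_std = err$VFCT[2],
        err_corrcbct_high = err$CORRCBCT[1], err_corrcbct_std = err$CORRCBCT[2],
        err_virtct_high = err$VIRTCT[1], err_virtct_std = err$VIRTCT[2]
      )
    }
    dplyr::bind_rows(rows)
  })

  cohort <- structure(list(cases = cases, scenario = sc, seed = as.integer(seed),
                           dir = dir, grid = grid),
                      class = "cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (write_images) {
      for (i in seq_len(n)) write_cohort_case(cohort, i)
    }
    manifest <- list(n = n, seed = seed, scenario = unclass(sc),
                     grid = list(shape = grid$shape, spacing = grid$spacing,
                                 origin = grid$origin),
                     images_written = write_images,
                     cases = cases)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cases, seed %d, %d planted reviews%s\n",
              nrow(x$cases), x$seed, sum(x$cases$planted_review),
              if (!is.null(x$dir)) paste0(", dir ", x$dir) else ""))
  invisible(x)
}

# rasterize one case and write its volumes + structures
write_cohort_case <- function(cohort, i) {
  row <- cohort$cases[i, ]
  case_dir <- file.path(cohort$dir, row$case_id)
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  imgs <- build_cohort_case(cohort, i)
  write_volume(imgs$pct, file.path(case_dir, "pct.nii.gz"))
  write_volume(imgs$vfct, file.path(case_dir, "vfct.nii.gz"))
  write_volume(imgs$cbct, file.path(case_dir, "cbct.nii.gz"))
  fov_img <- volume_image(array(as.numeric(imgs$fov), dim = dim(imgs$fov)),
                          imgs$pct$spacing, imgs$pct$origin, "DOSE")
  write_volume(fov_img, file.path(case_dir, "fov.nii.gz"))
  write_structures(imgs$structures, file.path(case_dir, "structures.nii.gz"))
  write_structures(imgs$structures_day, file.path(case_dir, "structures_day.nii.gz"))
  invisible(case_dir)
}

#' Rasterize the image triplet of one cohort case
#'
#' @param cohort A [generate_cohort()] result.
#' @param i Case index.
#' @return List with `pct`, `vfct`, `cbct`, `fov`, `structures` (planning),
#'   `structures_day` (treatment-day ground truth), `true_field`,
#'   `true_inverse`.
#' @export
build_cohort_case <- function(cohort, i) {
  row <- cohort$cases[i, ]
  ph <- generate_phantom(phantom_spec(grid = cohort$grid, seed = row$phantom_seed))
  ch <- apply_anatomy_change(ph$ct, ph$structures,
                             anatomy_change_spec(row$shrink,
                                                 c(0, 0, row$shift_z),
                                                 row$cavity_fill,
                                                 seed = row$change_seed))
  deg <- cbct_degradation_spec(gain = row$gain, offset = row$offset,
                               shading_amplitude = cohort$scenario$degradation$shading_amplitude,
                               noise_sd = cohort$scenario$degradation$noise_sd,
                               seed = row$cbct_seed)
  sim <- simulate_cbct(ch$ct, deg, ch$structures)
  list(pct = ph$ct, vfct = ch$ct, cbct = sim$cbct, fov = sim$fov,
       structures = ph$structures, structures_day = ch$structures,
       true_field = ch$field, true_inverse = sim$true_inverse)
}

#' Planted coverage records of a cohort
#'
#' Expands the planted D99 losses and surrogate errors into the long
#' coverage-record table used by [summarize_cohort()]: PLAN = 100,
#' GTCT = 100 - planted loss, and each surrogate = GTCT + planted error
#' (floored at 0).
#'
#' @param cohort A [generate_cohort()] result.
#' @return Tibble of coverage records.
#' @export
cohort_coverage_records <- function(cohort) {
  cs <- cohort$cases
  recs <- list()
  for (st in c("CTV_HIGH", "CTV_STANDARD")) {
    sfx <- if (st == "CTV_HIGH") "high" else "std"
    gt <- 100 - cs[[paste0("loss_", sfx)]]
    recs[[paste0(st, "_plan")]] <- tibble::tibble(
      case_id = cs$case_id, image = "PLAN", structure = st, d99 = 100)
    recs[[paste0(st, "_gt")]] <- tibble::tibble(
      case_id = cs$case_id, image = "GTCT", structure = st, d99 = gt)
    for (img in c("VFCT", "CORRCBCT", "VIRTCT")) {
      e <- cs[[paste0("err_", tolower(img), "_", sfx)]]
      recs[[paste0(st, "_", img)]] <- tibble::tibble(
        case_id = cs$case_id, image = img, structure = st,
        d99 = pmax(gt + e, 0))
    }
  }
  dplyr::bind_rows(recs)
}
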