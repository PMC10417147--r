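#' Default run configuration
#'
#' All tunable parameters of the monitoring workflow in one nested list.
#' Thresholds carry their clinical defaults: density masking at
#' 0.3 / 0.6 g/cm3, trigger thresholds at 3 (high-risk) / 5 (standard-risk)
#' percentage points of relative D99, DIR focus margin 20 mm.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    grid_preset = "test",
    corrcbct = list(bins = 96L, n_classes = 4L, sigma_mm = 25,
                    feather_mm = 10, focus_margin_mm = 20, tol_hu = 2,
                    max_iter = 5L),
    virtct = list(delta_rho = 0.3, low_rho = 0.6),
    trigger = list(high = 3, standard = 5),
    dose = list(arrangement = "anterior_3", falloff_mm = 5,
                aperture_margin_mm = 6, distal_margin_mm = 4),
    cohort = list(n = 2L, p_trigger = 0.19),
    write_volumes = TRUE
  )
}

#' Load a YAML run configuration merged over the defaults
#'
#' @param path Path to a YAML file; `NULL` returns [default_config()].
#' @return Nested named list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_corrcbct <- function(cfg) {
  cc <- cfg$corrcbct
  corrcbct_config(bins = cc$bins, n_classes = cc$n_classes,
                  sigma_mm = cc$sigma_mm, feather_mm = cc$feather_mm,
                  focus_margin_mm = cc$focus_margin_mm, tol_hu = cc$tol_hu,
                  max_iter = cc$max_iter)
}

config_thresholds <- function(cfg) {
  c(CTV_HIGH = cfg$trigger$high, CTV_STANDARD = cfg$trigger$standard)
}

#' Simulate a cohort to disk
#'
#' @param config Run configuration (see [default_config()]).
#' @param out_dir Cohort output directory.
#' @param n Number of cases (overrides `config$cohort$n`).
#' @param write_images Rasterize and write image volumes per case.
#' @return The [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir, n = NULL,
                         write_images = TRUE) {
  n <- n %||% config$cohort$n
  sc <- cohort_scenario(p_trigger = config$cohort$p_trigger %||% 0.19)
  cohort <- generate_cohort(n, sc, seed = config$seed, dir = out_dir,
                            write_images = write_images,
                            grid = phantom_grid(config$grid_preset))
  invisible(cohort)
}

#' Evaluate one case end-to-end
#'
#' Runs the full monitoring pipeline on a case directory containing
#' `pct.nii.gz`, `cbct.nii.gz`, `fov.nii.gz` and `structures.nii.gz`
#' (planning contours), optionally `vfct.nii.gz` (+
#' `structures_day.nii.gz`): corrected CBCT, virtual CT, ground-truth CT
#' when a verification CT is present, the proton dose proxy on every image
#' set, D99 per target, and the adaptive-review trigger report. All
#' intermediate artifacts are persisted under `out_dir`.
#'
#' @param case_dir Case directory.
#' @param config Run configuration.
#' @param out_dir Output directory (default `case_dir/eval`).
#' @return An object of class `case_report`: `records` (coverage tibble),
#'   `deltas`, `trigger` (`trigger_report`), `corrcbct`
#'   (`corrcbct_result`), `virtct`, `gtct` (or `NULL`), `paths`.
#' @export
run_evaluate_case <- function(case_dir, config = default_config(),
                              out_dir = file.path(case_dir, "eval")) {
  need <- c("pct.nii.gz", "cbct.nii.gz", "fov.nii.gz", "structures.nii.gz")
  for (f in need) {
    if (!file.exists(file.path(case_dir, f))) {
      stop(sprintf("case is missing required image '%s'", f), call. = FALSE)
    }
  }
  pct <- read_volume(file.path(case_dir, "pct.nii.gz"), "HU")
  cbct <- read_volume(file.path(case_dir, "cbct.nii.gz"), "CBCT_GRAY")
  fov <- read_volume(file.path(case_dir, "fov.nii.gz"), "DOSE")$voxels > 0.5
  structures <- read_structures(file.path(case_dir, "structures.nii.gz"))
  vfct_path <- file.path(case_dir, "vfct.nii.gz")
  vfct <- if (file.exists(vfct_path)) read_volume(vfct_path, "HU") else NULL
  sd_path <- file.path(case_dir, "structures_day.nii.gz")
  structures_day <- if (file.exists(sd_path)) read_structures(sd_path) else NULL

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cc_cfg <- config_corrcbct(config)
  g <- grid_of(cbct)

  corr <- make_corrcbct(pct, cbct, fov, cc_cfg)
  virt <- make_virtct(pct, cbct, corr$corrcbct, corr$field, fov,
                      delta_rho = config$virtct$delta_rho,
                      low_rho = config$virtct$low_rho)
  gt <- if (!is.null(vfct)) make_gtct(vfct, cbct, fov, cc_cfg) else NULL

  # plan on the planning anatomy, evaluate on each image set
  spr_plan <- hu_to_spr(pct)
  plan <- plan_beams(structures, spr_plan, config$dose$arrangement,
                     aperture_margin_mm = config$dose$aperture_margin_mm,
                     distal_margin_mm = config$dose$distal_margin_mm)
  structs_cb <- if (same_grid(structures$grid, g)) structures else
    resample_structures(structures, g)
  structs_eval <- map_contours(structs_cb, corr$field)

  case_id <- basename(normalizePath(case_dir, mustWork = FALSE))
  d99_of <- function(img, structs) {
    dose <- compute_dose_proxy(hu_to_spr(img), plan, config$dose$falloff_mm)
    vapply(c("CTV_HIGH", "CTV_STANDARD"), function(role) {
      d_metric(compute_dvh(dose, mask_by_role(structs, role)), 0.99)
    }, 0)
  }
  recs <- list(tibble::tibble(case_id = case_id, image = "PLAN",
                              structure = c("CTV_HIGH", "CTV_STANDARD"),
                              d99 = unname(d99_of(pct, structures))))
  eval_imgs <- list(CORRCBCT = corr$corrcbct, VIRTCT = virt$virtct)
  if (!is.null(gt)) eval_imgs$GTCT <- gt$gtct
  for (nm in names(eval_imgs)) {
    structs_nm <- if (nm == "GTCT" && !is.null(structures_day)) {
      map_contours(structures_day, gt$field)
    } else structs_eval
    recs[[nm]] <- tibble::tibble(case_id = case_id, image = nm,
                                 structure = c("CTV_HIGH", "CTV_STANDARD"),
                                 d99 = unname(d99_of(eval_imgs[[nm]], structs_nm)))
  }
  if (!is.null(vfct) && !is.null(structures_day)) {
    recs$VFCT <- tibble::tibble(case_id = case_id, image = "VFCT",
                                structure = c("CTV_HIGH", "CTV_STANDARD"),
                                d99 = unname(d99_of(vfct, structures_day)))
  }
  records <- dplyr::bind_rows(recs)

  plan_d99 <- dplyr::filter(records, .data$image == "PLAN")
  eval_kind <- if (!is.null(gt)) "GTCT" else "VIRTCT"
  eval_d99 <- dplyr::filter(records, .data$image == eval_kind)
  deltas <- dplyr::inner_join(plan_d99, eval_d99, by = c("case_id", "structure"),
                              suffix = c("_plan", "_eval")) |>
    dplyr::transmute(.data$case_id, .data$structure,
                     delta_d99 = .data$d99_plan - .data$d99_eval)
  trig <- apply_trigger(deltas, config_thresholds(config))

  if (isTRUE(config$write_volumes)) {
    write_volume(corr$corrcbct, file.path(out_dir, "corrcbct.nii.gz"))
    write_volume(virt$virtct, file.path(out_dir, "virtct.nii.gz"))
    ov <- volume_image(array(as.numeric(virt$override), dim = g$shape),
                       g$spacing, g$origin, "DOSE")
    write_volume(ov, file.path(out_dir, "override_mask.nii.gz"))
    if (!is.null(gt)) write_volume(gt$gtct, file.path(out_dir, "gtct.nii.gz"))
  }
  jsonlite::write_json(
    list(case_id = case_id,
         records = records, deltas = deltas,
         trigger = list(review = trig$review,
                        structures = trig$structures,
                        thresholds = as.list(config_thresholds(config))),
         corrcbct = list(converged = corr$converged,
                         iterations = corr$iterations, trace = corr$trace,
                         junctions = tidy(corr$conversion)),
         evaluated_against = eval_kind),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")

  structure(list(case_id = case_id, records = records, deltas = deltas,
                 trigger = trig, corrcbct = corr, virtct = virt, gtct = gt,
                 paths = list(out_dir = out_dir,
                              report = file.path(out_dir, "report.json"))),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report> %s: review %s\n", x$case_id,
              if (x$trigger$review) "REQUIRED" else "not required"))
  print(x$records)
  invisible(x)
}

#' Aggregate evaluated cases into the cohort report
#'
#' Reads every `case_*/eval/report.json` under `cohort_dir`, assembles the
#' coverage-record table, runs [summarize_cohort()], and writes
#' `accuracy.csv`, `pairwise_tests.csv`, `loss.csv`, `triggers.csv` and an
#' HTML summary with the accuracy plot.
#'
#' @param cohort_dir Cohort directory with evaluated cases.
#' @param config Run configuration.
#' @return The `cohort_summary`, invisibly.
#' @export
run_cohort_report <- function(cohort_dir, config = default_config()) {
  reports <- Sys.glob(file.path(cohort_dir, "case_*", "eval", "report.json"))
  if (length(reports) == 0L) stop("no evaluated cases found", call. = FALSE)
  records <- dplyr::bind_rows(lapply(reports, function(p) {
    rj <- jsonlite::read_json(p, simplifyVector = TRUE)
    tibble::as_tibble(rj$records)
  }))
  summ <- summarize_cohort(records, config_thresholds(config))
  out <- file.path(cohort_dir, "report")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summ$accuracy, file.path(out, "accuracy.csv"), row.names = FALSE)
  utils::write.csv(summ$pairwise, file.path(out, "pairwise_tests.csv"), row.names = FALSE)
  utils::write.csv(summ$loss, file.path(out, "loss.csv"), row.names = FALSE)
  utils::write.csv(summ$triggers, file.path(out, "triggers.csv"), row.names = FALSE)
  write_html_report(summ, records, out)
  invisible(summ)
}

write_html_report <- function(summ, records, out_dir) {
  png_path <- file.path(out_dir, "accuracy.png")
  ok <- tryCatch({
    p <- autoplot.cohort_summary(summ)
    ggplot2::ggsave(png_path, p, width = 7, height = 4, dpi = 120)
    TRUE
  }, error = function(e) FALSE)
  gl <- glance.cohort_summary(summ)
  rows <- apply(summ$accuracy, 1, function(r) {
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>")
  })
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Cohort dose-monitoring summary</title></head><body>",
    sprintf("<h1>Cohort summary: %d cases</h1>", gl$n_cases),
    sprintf("<p>Adaptive review triggered for %d / %d cases (%.0f%%) at thresholds &gt;%g (high-risk) / &gt;%g (standard-risk) percentage points D99 loss.</p>",
            gl$n_reviews, gl$n_cases, 100 * gl$review_rate,
            gl$threshold_high, gl$threshold_standard),
    "<h2>Surrogate accuracy vs ground truth</h2>",
    sprintf("<table border='1' cellpadding='4'><tr><th>%s</th></tr>",
            paste(names(summ$accuracy), collapse = "</th><th>")),
    rows, "</table>",
    if (ok) "<p><img src='accuracy.png' width='700'></p>" else NULL,
    "</body></html>")
  writeLines(html, file.path(out_dir, "summary.html"))
  invisible(file.path(out_dir, "summary.html"))
}
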