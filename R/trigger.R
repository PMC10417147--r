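#' Coverage records
#'
#' A coverage record holds the D99 (relative %, plan-normalized) of one
#' structure on one image set of one case. Records are plain tibble rows so
#' cohorts are just long tables.
#'
#' @param case_id Case identifier.
#' @param image One of [image_kinds()]: `PLAN`, `GTCT`, `VFCT`, `CORRCBCT`,
#'   `VIRTCT`.
#' @param structure Structure role: `CTV_HIGH` or `CTV_STANDARD`.
#' @param d99 D99 in relative %, `>= 0`.
#' @return A one-row tibble.
#' @export
coverage_record <- function(case_id, image, structure, d99) {
  image <- match.arg(image, image_kinds())
  structure <- match.arg(structure, c("CTV_HIGH", "CTV_STANDARD"))
  if (!is.finite(d99) || d99 < 0) stop("`d99` must be finite and >= 0", call. = FALSE)
  tibble::tibble(case_id = as.character(case_id), image = image,
                 structure = structure, d99 = as.numeric(d99))
}

#' @rdname coverage_record
#' @export
image_kinds <- function() c("PLAN", "GTCT", "VFCT", "CORRCBCT", "VIRTCT")

#' Coverage change from plan to evaluation
#'
#' `delta = plan D99 - evaluation D99`, in percentage points of relative
#' dose: positive values are a loss of coverage.
#'
#' @param plan,eval One-row coverage records (tibbles) for the same case
#'   and structure.
#' @return Numeric delta in percentage points.
#' @export
delta_d99 <- function(plan, eval) {
  for (col in c("case_id", "structure")) {
    if (!identical(plan[[col]], eval[[col]])) {
      stop(sprintf("records disagree on %s ('%s' vs '%s')", col,
                   plan[[col]], eval[[col]]), call. = FALSE)
    }
  }
  plan$d99 - eval$d99
}

#' Default adaptive-review trigger thresholds
#'
#' A D99 decrease of more than 3 percentage points on the high-risk CTV or
#' more than 5 on the standard-risk CTV triggers a plan review; both
#' comparisons are strict.
#'
#' @return Named numeric vector (`CTV_HIGH`, `CTV_STANDARD`).
#' @export
trigger_thresholds <- function() c(CTV_HIGH = 3, CTV_STANDARD = 5)

#' Apply the adaptive-review trigger rule to per-structure coverage deltas
#'
#' @param deltas Tibble with columns `structure` (`CTV_HIGH` /
#'   `CTV_STANDARD`) and `delta_d99` (percentage points, positive = loss),
#'   optionally `case_id`.
#' @param thresholds Named vector of strict thresholds per structure role.
#' @return An object of class `trigger_report`: the per-structure tibble
#'   with a `triggered` column, plus `review` (any structure triggered) and
#'   the thresholds used.
#' @export
apply_trigger <- function(deltas, thresholds = trigger_thresholds()) {
  if (nrow(deltas) == 0L) stop("no CTV deltas supplied", call. = FALSE)
  unknown <- setdiff(unique(deltas$structure), names(thresholds))
  if (length(unknown)) {
    stop("no threshold for structure role(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(
    deltas,
    threshold = unname(thresholds[.data$structure]),
    triggered = .data$delta_d99 > .data$threshold
  )
  boundary <- abs(out$delta_d99 - out$threshold) < 1e-9
  if (any(boundary)) {
    message(sprintf("note: %d delta(s) exactly at threshold; strict '>' rule leaves them untriggered",
                    sum(boundary)))
  }
  structure(list(structures = out, review = any(out$triggered),
                 thresholds = thresholds),
            class = "trigger_report")
}

#' @export
print.trigger_report <- function(x, ...) {
  cat(sprintf("<trigger_report> review %s\n",
              if (x$review) "REQUIRED" else "not required"))
  print(x$structures)
  invisible(x)
}

#' @rdname apply_trigger
#' @param x A `trigger_report`.
#' @param ... Unused.
#' @export
tidy.trigger_report <- function(x, ...) x$structures

#' @rdname apply_trigger
#' @export
glance.trigger_report <- function(x, ...) {
  tibble::tibble(review = x$review,
                 n_triggered = sum(x$structures$triggered),
                 threshold_high = x$thresholds[["CTV_HIGH"]],
                 threshold_standard = x$thresholds[["CTV_STANDARD"]])
}

#' Exact / approximate Wilcoxon signed-rank test
#'
#' Two-sided paired test on a vector of differences. Zeros are discarded
#' (Wilcoxon's convention) and ties receive midranks. For `n <= 15`
#' non-zero differences the null distribution of the positive-rank sum is
#' enumerated exactly (via the generating-function convolution over all
#' 2^n sign assignments, doubled ranks keeping midranks integral); above
#' that a normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x Numeric vector of paired differences.
#' @param exact_max Largest n handled by exact enumeration.
#' @return `list(statistic = W+ (positive-rank sum), p_value, n, method)`.
#' @export
wilcoxon_signed_rank <- function(x, exact_max = 15L) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) stop("all differences are zero: test undefined", call. = FALSE)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    # distribution of 2*W+ over equal-probability sign assignments
    maxs <- sum(r2)
    probs <- c(1, rep(0, maxs))
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(maxs + 1 - ri)])
      probs <- (probs + shifted) / 2
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(maxs + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Summarize a cohort of coverage records
#'
#' For every case with a ground-truth CT record, each surrogate image's
#' absolute D99 discrepancy from the ground truth is collected; the summary
#' reports mean +/- SD of |dD99| per image kind and structure, a paired
#' Wilcoxon signed-rank p-value of each synthetic CT's |dD99| distribution
#' against the verification CT's, the quartiles of ground-truth coverage
#' loss, and the adaptive-review trigger counts under the standard
#' thresholds. Cases without a ground-truth record are excluded with a
#' warning; the result is invariant to case order.
#'
#' @param records Long tibble of coverage records (columns `case_id`,
#'   `image`, `structure`, `d99`).
#' @param thresholds Trigger thresholds, per structure role.
#' @return An object of class `cohort_summary`: `accuracy` (per image x
#'   structure tibble), `loss` (ground-truth coverage-loss stats),
#'   `triggers` (per-structure and overall counts), `n_cases`.
#' @export
summarize_cohort <- function(records, thresholds = trigger_thresholds()) {
  stopifnot(all(c("case_id", "image", "structure", "d99") %in% names(records)))
  have_gt <- records |>
    dplyr::filter(.data$image == "GTCT") |>
    dplyr::distinct(.data$case_id)
  dropped <- setdiff(unique(records$case_id), have_gt$case_id)
  if (length(dropped)) {
    warning(sprintf("excluding %d case(s) without a gtCT record: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")),
            call. = FALSE)
    records <- dplyr::filter(records, .data$case_id %in% have_gt$case_id)
  }
  if (nrow(records) == 0L) {
    stop("no cases with ground-truth records to summarize", call. = FALSE)
  }
  wide <- records |>
    tidyr::pivot_wider(names_from = "image", values_from = "d99")

  surrogates <- intersect(c("VFCT", "CORRCBCT", "VIRTCT"), names(wide))
  acc_long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(surrogates), names_to = "image",
                        values_to = "d99_surrogate") |>
    dplyr::filter(!is.na(.data$d99_surrogate)) |>
    dplyr::mutate(abs_dd99 = abs(.data$d99_surrogate - .data$GTCT))
  accuracy <- acc_long |>
    dplyr::group_by(.data$image, .data$structure) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_dd99 = mean(.data$abs_dd99),
                     sd_abs_dd99 = if (dplyr::n() > 1) stats::sd(.data$abs_dd99) else NA_real_,
                     .groups = "drop")
  # paired comparisons of surrogate |dD99| distributions (synthetic CTs vs
  # the verification CT, and virtual vs corrected CBCT)
  pair_tbl <- acc_long |>
    dplyr::select("case_id", "structure", "image", "abs_dd99") |>
    tidyr::pivot_wider(names_from = "image", values_from = "abs_dd99")
  pairings <- list(c("CORRCBCT", "VFCT"), c("VIRTCT", "VFCT"),
                   c("VIRTCT", "CORRCBCT"))
  pw <- list()
  for (st in unique(accuracy$structure)) {
    sub <- dplyr::filter(pair_tbl, .data$structure == st)
    for (pr in pairings) {
      if (!all(pr %in% names(sub))) next
      diffs <- sub[[pr[1]]] - sub[[pr[2]]]
      diffs <- diffs[!is.na(diffs)]
      p <- if (length(diffs[diffs != 0]) >= 5) {
        wilcoxon_signed_rank(diffs)$p_value
      } else NA_real_
      pw[[length(pw) + 1L]] <- tibble::tibble(
        structure = st, image = pr[1], reference = pr[2],
        n = length(diffs), p_value = p)
    }
  }
  pairwise <- dplyr::bind_rows(pw)
  accuracy <- dplyr::left_join(
    accuracy,
    dplyr::select(dplyr::filter(pairwise, .data$reference == "VFCT"),
                  "structure", "image", p_vs_vfct = "p_value"),
    by = c("image", "structure"))

  loss_tbl <- wide |>
    dplyr::filter(!is.na(.data$PLAN), !is.na(.data$GTCT)) |>
    dplyr::mutate(loss = .data$PLAN - .data$GTCT)
  loss <- loss_tbl |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(n = dplyr::n(), mean_loss = mean(.data$loss),
                     sd_loss = if (dplyr::n() > 1) stats::sd(.data$loss) else NA_real_,
                     q25 = stats::quantile(.data$loss, 0.25),
                     median = stats::median(.data$loss),
                     q75 = stats::quantile(.data$loss, 0.75),
                     .groups = "drop")
  trig <- loss_tbl |>
    dplyr::mutate(triggered = .data$loss > unname(thresholds[.data$structure])) |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(n_triggered = sum(.data$triggered), .groups = "drop")
  reviews <- loss_tbl |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(review = any(.data$loss > unname(thresholds[.data$structure])),
                     .groups = "drop")
  structure(list(accuracy = accuracy, pairwise = pairwise, loss = loss,
                 triggers = trig, review_cases = reviews,
                 n_cases = length(unique(records$case_id)),
                 n_reviews = sum(reviews$review),
                 review_rate = mean(reviews$review),
                 thresholds = thresholds),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases, %d reviews triggered (%.0f%%)\n",
              x$n_cases, x$n_reviews, 100 * x$review_rate))
  print(x$accuracy)
  invisible(x)
}

#' @rdname summarize_cohort
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @export
tidy.cohort_summary <- function(x, ...) x$accuracy

#' @rdname summarize_cohort
#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, n_reviews = x$n_reviews,
                 review_rate = x$review_rate,
                 threshold_high = x$thresholds[["CTV_HIGH"]],
                 threshold_standard = x$thresholds[["CTV_STANDARD"]])
}

#' Box-plot style distribution of surrogate accuracy
#'
#' @param object A `cohort_summary`.
#' @param records The record tibble the summary was built from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, records = NULL, ...) {
  df <- object$accuracy
  ggplot2::ggplot(df, ggplot2::aes(x = .data$image, y = .data$mean_abs_dd99)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_abs_dd99 - .data$sd_abs_dd99, 0),
                                        ymax = .data$mean_abs_dd99 + .data$sd_abs_dd99),
                           width = 0.25) +
    ggplot2::facet_wrap(~structure) +
    ggplot2::labs(x = NULL, y = "|dD99| vs ground truth (percentage points)",
                  title = "Surrogate dosimetric accuracy") +
    ggplot2::theme_minimal()
}
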