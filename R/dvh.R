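#' Cumulative dose-volume histogram of a structure
#'
#' @param dose Dose `volume_image`.
#' @param mask Non-empty logical mask on the dose grid.
#' @param structure Optional structure name carried into the output.
#' @return An object of class `dvh`: sorted in-mask dose samples plus a
#'   tibble accessor via [tidy.dvh()].
#' @export
compute_dvh <- function(dose, mask, structure = NA_character_) {
  stopifnot_volume(dose)
  if (is_volume_image(mask)) mask <- mask$voxels > 0.5
  if (!identical(dim(mask), dim(dose$voxels))) {
    stop("dose and mask must share a grid", call. = FALSE)
  }
  if (!any(mask)) stop("empty structure mask", call. = FALSE)
  structure(list(doses = sort(dose$voxels[mask]), structure = structure),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh>%s %d voxels, dose [%.1f, %.1f]%%, D99 %.1f%%\n",
              if (is.na(x$structure)) "" else paste0(" ", x$structure),
              length(x$doses), min(x$doses), max(x$doses), d_metric(x, 0.99)))
  invisible(x)
}

#' Volume fraction receiving at least a given dose
#'
#' @param dvh A `dvh`.
#' @param dose Query dose(s).
#' @return Fraction(s) in `[0, 1]`; 1 at dose 0 by normalization.
#' @export
dvh_fraction <- function(dvh, dose) {
  n <- length(dvh$doses)
  vapply(dose, function(d) (n - findInterval(d - 1e-12, dvh$doses)) / n, 0)
}

#' Dose covering a given volume fraction (D-metric)
#'
#' The smallest attained dose `d` such that at least `volume_fraction` of
#' the structure receives `>= d`; equivalently the
#' `ceiling(f * n)`-th largest in-mask dose. `D99 = d_metric(dvh, 0.99)`.
#'
#' @param dvh A `dvh`.
#' @param volume_fraction In (0, 1); 0.99 for D99.
#' @return Dose in the dose grid's units (percent of prescription).
#' @export
d_metric <- function(dvh, volume_fraction = 0.99) {
  if (volume_fraction <= 0 || volume_fraction >= 1) {
    stop("`volume_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- length(dvh$doses)
  k <- ceiling(volume_fraction * n)
  # doses are sorted ascending: k-th largest is position n - k + 1
  dvh$doses[n - k + 1]
}

#' Tidy a DVH into its cumulative curve
#'
#' @param x A `dvh`.
#' @param ... Unused.
#' @return Tibble with `dose` and `volume_fraction`, non-increasing from 1.
#' @export
tidy.dvh <- function(x, ...) {
  ds <- unique(c(0, x$doses))
  tibble::tibble(structure = x$structure, dose = ds,
                 volume_fraction = dvh_fraction(x, ds))
}

#' Plot one or more DVH curves
#'
#' @param object A `dvh` or list of `dvh`s.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh <- function(object, ...) {
  df <- tidy.dvh(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose,
                                   y = 100 * .data$volume_fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Relative dose (%)", y = "Volume (%)",
                  title = "Cumulative dose-volume histogram") +
    ggplot2::theme_minimal()
}
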