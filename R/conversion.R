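#' Piecewise-linear CBCT-gray to CT-number conversion function
#'
#' A monotone map from CBCT gray values to Hounsfield units defined by
#' ordered junction points, evaluated by linear interpolation between
#' junctions, extended beyond the terminal junctions with the terminal
#' segment slopes and clamped to the representable HU range
#' `[-1024, 3071]`.
#'
#' @param gray Numeric vector of junction gray values, strictly increasing.
#' @param hu Numeric vector of junction HU values, non-decreasing (a
#'   non-monotone sequence is isotonically adjusted with a warning by
#'   [fit_conversion_function()]).
#' @return An object of class `conversion_function`.
#' @export
conversion_function <- function(gray, hu) {
  if (length(gray) != length(hu) || length(gray) < 2L) {
    stop("need >= 2 junction points", call. = FALSE)
  }
  if (is.unsorted(gray, strictly = TRUE)) {
    stop("junction gray values must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(hu)) {
    stop("junction HU values must be non-decreasing", call. = FALSE)
  }
  structure(list(gray = as.numeric(gray), hu = as.numeric(hu)),
            class = "conversion_function")
}

#' @export
print.conversion_function <- function(x, ...) {
  cat(sprintf("<conversion_function> %d junctions, gray [%.4g, %.4g] -> HU [%.5g, %.5g]\n",
              length(x$gray), min(x$gray), max(x$gray), min(x$hu), max(x$hu)))
  invisible(x)
}

#' Evaluate a conversion function
#'
#' @param object A `conversion_function`.
#' @param gray Gray values to convert.
#' @param ... Unused.
#' @return HU values, clamped to `[-1024, 3071]`.
#' @export
predict.conversion_function <- function(object, gray, ...) {
  pmin(pmax(pwl_interp(object$gray, object$hu, gray), -1024), 3071)
}

#' Apply a conversion function to a CBCT volume
#'
#' @param cbct A `volume_image` with kind `"CBCT_GRAY"` (or `"HU"`, passed
#'   through conversion regardless).
#' @param conv A `conversion_function`.
#' @return A `volume_image` in HU.
#' @export
convert_cbct <- function(cbct, conv) {
  stopifnot_volume(cbct)
  hu <- predict.conversion_function(conv, as.vector(cbct$voxels))
  volume_image(array(hu, dim = dim(cbct$voxels)), cbct$spacing, cbct$origin, "HU")
}

#' Fit a piecewise-linear conversion from identified tissue-class points
#'
#' Junctions are the class points ordered by gray value. If the HU sequence
#' is non-monotone after ordering, it is isotonically adjusted (pool
#' adjacent violators) and a warning is emitted.
#'
#' @param class_points Data frame / tibble with columns `gray` and `hu`
#'   (as produced by [identify_tissue_classes()]), or a 2-column matrix.
#' @return A `conversion_function`.
#' @export
fit_conversion_function <- function(class_points) {
  if (is.matrix(class_points)) {
    class_points <- data.frame(gray = class_points[, 1], hu = class_points[, 2])
  }
  gray <- class_points$gray; hu <- class_points$hu
  if (length(gray) < 2L) stop("need >= 2 class points", call. = FALSE)
  ord <- order(gray)
  gray <- gray[ord]; hu <- hu[ord]
  if (any(diff(gray) <= 0)) stop("class points must have distinct gray values", call. = FALSE)
  if (is.unsorted(hu)) {
    warning("non-monotone HU sequence at junctions; applying isotonic adjustment",
            call. = FALSE)
    hu <- stats::isoreg(gray, hu)$yf
  }
  conversion_function(gray, hu)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the junctions of a conversion function
#'
#' @param x A `conversion_function`.
#' @param ... Unused.
#' @return A tibble with one row per junction (`gray`, `hu`).
#' @export
tidy.conversion_function <- function(x, ...) {
  tibble::tibble(gray = x$gray, hu = x$hu)
}

#' Plot a conversion function
#'
#' @param object A `conversion_function`.
#' @param ... Unused.
#' @return A ggplot object: the piecewise-linear map with its junctions.
#' @export
autoplot.conversion_function <- function(object, ...) {
  pad <- diff(range(object$gray)) * 0.15
  xs <- seq(min(object$gray) - pad, max(object$gray) + pad, length.out = 400)
  curve_df <- tibble::tibble(gray = xs,
                             hu = predict.conversion_function(object, xs))
  ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$gray, y = .data$hu)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tidy.conversion_function(object), colour = "red",
                        size = 2) +
    ggplot2::labs(x = "CBCT gray value", y = "CT number (HU)",
                  title = "Piecewise-linear intensity conversion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
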