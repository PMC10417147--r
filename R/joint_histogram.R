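#' Joint intensity histogram of a deformed planning CT and a CBCT
#'
#' 2D count matrix over (planning-CT HU bins x CBCT gray bins), computed
#' only inside a mask (normally the registration focus region). Bin edges
#' span the observed in-mask ranges.
#'
#' @param pct_deformed Planning CT deformed onto the CBCT grid (HU
#'   `volume_image`).
#' @param cbct CBCT `volume_image` on the same grid.
#' @param mask Logical mask of voxels to histogram.
#' @param bins Length-2 (HU bins, gray bins) or scalar.
#' @return An object of class `joint_histogram`: `counts` (HU x gray),
#'   `hu_edges`, `gray_edges`, `n`.
#' @export
build_joint_histogram <- function(pct_deformed, cbct, mask, bins = 96) {
  stopifnot_volume(pct_deformed); stopifnot_volume(cbct)
  if (!same_grid(pct_deformed, cbct)) stop("images must share a grid", call. = FALSE)
  if (is_volume_image(mask)) mask <- mask$voxels > 0.5
  if (!any(mask)) stop("empty histogram mask", call. = FALSE)
  bins <- rep_len(as.integer(bins), 2L)
  hu <- pct_deformed$voxels[mask]
  gr <- cbct$voxels[mask]
  hu_edges <- seq(min(hu), max(hu), length.out = bins[1] + 1L)
  gray_edges <- seq(min(gr), max(gr), length.out = bins[2] + 1L)
  ih <- bin_index(hu, hu_edges)
  ig <- bin_index(gr, gray_edges)
  counts <- matrix(tabulate(ih + (ig - 1L) * bins[1], nbins = prod(bins)),
                   nrow = bins[1], ncol = bins[2])
  structure(list(counts = counts, hu_edges = hu_edges, gray_edges = gray_edges,
                 n = length(hu)),
            class = "joint_histogram")
}

bin_index <- function(x, edges) {
  nb <- length(edges) - 1L
  w <- (edges[length(edges)] - edges[1]) / nb
  if (w <= 0) return(rep(1L, length(x)))
  pmin(nb, pmax(1L, 1L + as.integer(floor((x - edges[1]) / w))))
}

#' @export
print.joint_histogram <- function(x, ...) {
  cat(sprintf("<joint_histogram> %d x %d bins, %d voxels, HU [%.4g, %.4g], gray [%.4g, %.4g]\n",
              nrow(x$counts), ncol(x$counts), x$n, x$hu_edges[1],
              x$hu_edges[length(x$hu_edges)], x$gray_edges[1],
              x$gray_edges[length(x$gray_edges)]))
  invisible(x)
}

#' Identify tissue-class points on a joint histogram
#'
#' Finds modes of the CBCT gray-value marginal (after light kernel
#' smoothing), then represents each class by its refined gray position and
#' the median planning-CT HU of the voxels in that gray band. Always checks
#' that at least an air-class and a soft-tissue-class mode are separable;
#' fewer than two modes raises a degenerate-histogram error (the fallback
#' is an identity-slope map through the single mode, which the caller can
#' construct explicitly).
#'
#' @param hist A [build_joint_histogram()] result.
#' @param n_classes Maximum number of class points to return (>= 2).
#' @param smooth_bins Half-width of the smoothing kernel, in bins.
#' @return A tibble with columns `gray`, `hu`, `mass`, ordered by gray.
#' @export
identify_tissue_classes <- function(hist, n_classes = 4L, smooth_bins = 2L) {
  m <- colSums(hist$counts)
  nb <- length(m)
  k <- stats::dnorm(seq(-3, 3, length.out = 2L * 3L * smooth_bins + 1L))
  k <- k / sum(k)
  ms <- as.numeric(stats::filter(c(rep(m[1], length(k)), m, rep(m[nb], length(k))),
                                 k, sides = 2))
  ms <- ms[(length(k) + 1):(length(k) + nb)]
  cand <- which(diff(sign(diff(c(-Inf, ms, -Inf)))) == -2)
  cand <- cand[ms[cand] > 0.004 * max(ms)]
  # accept modes highest-first; a candidate is a separate tissue class only
  # if a genuine valley (below 60% of its own height) separates it from
  # every already-accepted mode
  peaks <- integer(0)
  for (p in cand[order(ms[cand], decreasing = TRUE)]) {
    ok <- TRUE
    for (q in peaks) {
      valley <- min(ms[min(p, q):max(p, q)])
      if (valley > 0.6 * ms[p]) { ok <- FALSE; break }
    }
    if (ok) peaks <- c(peaks, p)
  }
  peaks <- sort(peaks)
  if (length(peaks) < 2L) {
    stop(paste0("degenerate joint histogram: fewer than 2 separable gray modes; ",
                "consider an identity-slope conversion through the single mode"),
         call. = FALSE)
  }
  if (length(peaks) > n_classes) {
    peaks <- sort(peaks[order(ms[peaks], decreasing = TRUE)[seq_len(n_classes)]])
  }
  gray_centers <- (hist$gray_edges[-1] + hist$gray_edges[-length(hist$gray_edges)]) / 2
  hu_centers <- (hist$hu_edges[-1] + hist$hu_edges[-length(hist$hu_edges)]) / 2
  # each junction is estimated from a tight window around its mode so the
  # point sits on the true gray->HU curve rather than being dragged by
  # partial-volume tails between classes
  win <- 3L
  out <- lapply(peaks, function(p) {
    band <- max(1L, p - win):min(nb, p + win)
    wts <- m[band]
    gray <- sum(gray_centers[band] * wts) / max(sum(wts), 1)
    hu_marg <- rowSums(hist$counts[, band, drop = FALSE])
    hu <- weighted_median(hu_centers, hu_marg)
    tibble::tibble(gray = gray, hu = hu, mass = sum(wts))
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$gray)
  # merge junctions that collapsed onto nearly identical gray values
  out <- out[c(TRUE, diff(out$gray) > 1e-9), , drop = FALSE]
  out
}

weighted_median <- function(x, w) {
  if (sum(w) == 0) return(stats::median(x))
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}
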