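# internal helpers shared across modules

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian low-pass filter in physical units
#'
#' Separable Gaussian smoothing implemented via the 3D FFT, with the kernel
#' applied as a frequency-domain attenuation `exp(-2 pi^2 sigma^2 f^2)` per
#' axis. With `pad_mm > 0` the array is zero-padded before transforming so
#' the filter does not wrap across opposite image edges.
#'
#' @param a 3D numeric array.
#' @param sigma_mm Gaussian standard deviation in mm (scalar or per-axis).
#' @param spacing Voxel spacing in mm.
#' @param pad_mm Zero-padding margin in mm (0 = periodic).
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(a, sigma_mm, spacing, pad_mm = 0) {
  d <- dim(a)
  sigma_mm <- rep_len(sigma_mm, 3L)
  if (all(sigma_mm <= 0)) return(a)
  padn <- pmax(0L, as.integer(ceiling(pad_mm / spacing)))
  dn <- vapply(1:3, function(ax) stats::nextn(d[ax] + 2L * padn[ax], c(2, 3, 5)), 1L)
  big <- array(0, dim = dn)
  big[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  att <- lapply(1:3, function(ax) {
    n <- dn[ax]
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * spacing[ax])
    f <- f[seq_len(n)]
    exp(-2 * pi^2 * sigma_mm[ax]^2 * f^2)
  })
  Hfull <- outer(outer(att[[1]], att[[2]]), att[[3]])
  sm <- Re(stats::fft(stats::fft(big) * Hfull, inverse = TRUE)) / prod(dn)
  array(sm[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])], dim = d)
}

# normalized (mask-weighted) Gaussian convolution: smooths a*mask and divides
# by smoothed mask, so values outside the mask do not bleed in.
masked_gaussian_smooth <- function(a, mask, sigma_mm, spacing, pad_mm = NULL) {
  if (is.null(pad_mm)) pad_mm <- 3 * max(sigma_mm)
  num <- gaussian_smooth(a * mask, sigma_mm, spacing, pad_mm)
  den <- gaussian_smooth(array(as.numeric(mask), dim = dim(mask)), sigma_mm,
                         spacing, pad_mm)
  out <- num / pmax(den, 1e-8)
  out[den < 1e-6] <- 0
  array(out, dim = dim(a))
}

# piecewise-linear table lookup with terminal-slope extrapolation
pwl_interp <- function(x_anchor, y_anchor, x) {
  n <- length(x_anchor)
  if (n < 2L) stop("need at least 2 anchors", call. = FALSE)
  if (is.unsorted(x_anchor, strictly = TRUE)) {
    stop("anchor x values must be strictly increasing", call. = FALSE)
  }
  y <- stats::approx(x_anchor, y_anchor, xout = pmin(pmax(x, x_anchor[1]), x_anchor[n]),
                     rule = 2, ties = "ordered")$y
  lo <- x < x_anchor[1]
  if (any(lo)) {
    s <- (y_anchor[2] - y_anchor[1]) / (x_anchor[2] - x_anchor[1])
    y[lo] <- y_anchor[1] + s * (x[lo] - x_anchor[1])
  }
  hi <- x > x_anchor[n]
  if (any(hi)) {
    s <- (y_anchor[n] - y_anchor[n - 1]) / (x_anchor[n] - x_anchor[n - 1])
    y[hi] <- y_anchor[n] + s * (x[hi] - x_anchor[n])
  }
  y
}
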