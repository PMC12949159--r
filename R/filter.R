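# Butterworth band-pass design and zero-phase filtering.
#
# The EMG sensors deliver 2000 Hz data that the analysis conditions with a
# fourth-order Butterworth band-pass (10-500 Hz) applied forward-backward
# (zero phase), so that envelope peaks stay aligned with crank angle.
# Implemented from first principles (analog prototype -> LP/BP transform ->
# bilinear transform) because no DSP design package is assumed at run time.

# Expand a polynomial from its roots (complex-safe).
poly_from_roots <- function(roots) {
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0 + 0i) - c(0 + 0i, p * r)
  p
}

#' Butterworth band-pass coefficients
#'
#' Designs a digital Butterworth band-pass filter via the bilinear transform
#' with frequency pre-warping. `order` is the analog prototype order (the
#' convention used by MATLAB's and SciPy's `butter`), so the resulting
#' digital filter has `2 * order` poles.
#'
#' @param order Prototype (per-edge) filter order. Default 4.
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @examples
#' co <- butter_bandpass(4, 10, 500, fs = 2000)
#' sum(co$b) # ~0: DC is rejected
#' @export
butter_bandpass <- function(order = 4, low = 10, high = 500, fs = 2000) {
  check_number(order, "order", min = 1)
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  check_number(low, "low", min = 0, strict_min = TRUE)
  check_number(high, "high", min = 0, strict_min = TRUE)
  nyq <- fs / 2
  if (high >= nyq) {
    warning(sprintf(
      "upper band edge %.1f Hz is at or above Nyquist (%.1f Hz); clipped to %.1f Hz",
      high, nyq, 0.99 * nyq
    ))
    high <- 0.99 * nyq
  }
  if (low >= high) stop_validation("low band edge must be below high band edge")

  # pre-warped analog edge frequencies (rad/s)
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))

  # low-pass -> band-pass: each prototype pole splits into two
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  p_bp <- c(pb + disc, pb - disc)
  z_bp <- rep(0 + 0i, order) # 'order' zeros at s = 0
  k_bp <- bw^order

  # bilinear transform s = 2 fs (z - 1) / (z + 1)
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))

  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a / a[1])
}

# Single-pass IIR filter (direct form, via stats::filter which runs in C):
# MA part as a one-sided convolution, AR part as a recursive filter.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb:length(xp)]
  if (length(a) > 1) {
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  }
  u
}

# Forward-backward (zero phase) filtering with odd-reflection padding so
# start-up transients decay inside the padding, not the data.
filtfilt_iir <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (n == 0) stop_validation("cannot filter an empty series")
  pad <- pad %||% min(n - 1L, 2000L)
  if (pad > 0) {
    front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    ext <- c(front, x, back)
  } else {
    ext <- x
  }
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  if (pad > 0) y <- y[seq(pad + 1L, pad + n)]
  y
}
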