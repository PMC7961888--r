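# Butterworth bandpass design and zero-phase filtering.
#
# The environment provides no DSP package, so the classical design chain is
# implemented directly: analog lowpass prototype -> lowpass-to-bandpass
# s-plane transform -> bilinear transform -> polynomial transfer function.
# The recursive difference equation runs through stats::filter (compiled),
# not an interpreted loop.

# Polynomial with given roots, coefficients in decreasing degree order.
.poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0i) - c(0i, p * rt)
  p
}

#' Design a digital Butterworth bandpass filter
#'
#' Returns transfer-function coefficients for an order-`n` Butterworth
#' bandpass (2n poles in the digital filter) with passband `low_hz`..`high_hz`
#' at sampling rate `fs_hz`, via the bilinear transform with frequency
#' pre-warping. At the band edges the magnitude response is 1/sqrt(2); DC and
#' Nyquist are nulled exactly (`n` zeros at z = 1 and at z = -1), which is
#' what removes any offset such as the sensor supply midpoint.
#'
#' @param low_hz,high_hz passband edges in Hz, `0 < low_hz < high_hz < fs_hz/2`.
#' @param fs_hz sampling rate in Hz.
#' @param order prototype order `n` (default 4).
#' @return list with numerator `b` and denominator `a` (length `2*order + 1`),
#'   `a[1] == 1`.
#' @examples
#' f <- butter_bandpass(150, 450, 2000)
#' @export
butter_bandpass <- function(low_hz, high_hz, fs_hz, order = 4) {
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  if (high_hz >= fs_hz / 2)
    stop("high_hz must be below the Nyquist frequency fs_hz/2")
  n <- as.integer(order)
  stopifnot(n >= 1)

  # analog Butterworth prototype poles (unit cutoff, left half-plane)
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  # pre-warped edge frequencies and lowpass->bandpass transform
  fs2 <- 2 * fs_hz
  w1 <- fs2 * tan(pi * low_hz / fs_hz)
  w2 <- fs2 * tan(pi * high_hz / fs_hz)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  half <- p_lp * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0^2), half - sqrt(half^2 - w0^2))
  z_bp <- rep(0 + 0i, n)          # n zeros at s = 0
  gain <- bw^n                    # analog gain so passband magnitude is 1

  # bilinear transform, matching gain at the warped frequencies
  zd <- (fs2 + z_bp) / (fs2 - z_bp)
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  gain <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  zd <- c(zd, rep(-1 + 0i, n))    # zeros from s = Inf map to z = -1

  b <- Re(.poly_from_roots(zd)) * gain
  a <- Re(.poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Magnitude response of a digital filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| from the transfer-function coefficients.
#' Used as the analytic oracle for attenuation checks: it shares no code with
#' the time-domain filtering path.
#'
#' @param filt list with `b`, `a` as from [butter_bandpass()].
#' @param f_hz frequencies to evaluate (Hz).
#' @param fs_hz sampling rate (Hz).
#' @return numeric vector of magnitudes.
#' @export
filter_gain <- function(filt, f_hz, fs_hz) {
  vapply(f_hz, function(f) {
    zb <- exp(-1i * 2 * pi * f / fs_hz * (seq_along(filt$b) - 1))
    za <- exp(-1i * 2 * pi * f / fs_hz * (seq_along(filt$a) - 1))
    Mod(sum(filt$b * zb) / sum(filt$a * za))
  }, numeric(1))
}

# Causal IIR filter via stats::filter: MA part as a one-sided convolution,
# AR part as the recursive filter y[t] = x[t] + sum(coef * y[t-lag]).
iir_filter <- function(filt, x) {
  b <- filt$b; a <- filt$a
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:length(xp)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Zero-phase forward-backward filtering with odd-reflection padding at both
# ends (removes edge transients; pad length 3x the filter length as in
# common practice, capped by the series length).
filtfilt_fb <- function(filt, x) {
  n <- length(x)
  npad <- min(3 * (max(length(filt$a), length(filt$b)) - 1) * 4, n - 1)
  if (npad < 1) stop("series too short to filter")
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  xe <- c(head_pad, x, tail_pad)
  y <- iir_filter(filt, xe)
  y <- rev(iir_filter(filt, rev(y)))
  y[(npad + 1):(npad + n)]
}
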