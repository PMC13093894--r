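# FFT-based signal primitives: zero-phase band-pass filtering and the
# analytic (Hilbert) signal. These back both the PAC and entrainment stages.

#' Zero-phase band-pass filter
#'
#' Filters a real signal with a real, even frequency-domain mask: unity gain
#' inside `[low, high]`, raised-cosine transitions of width one quarter of the
#' nearer band edge outside it, zero beyond. Because the mask is real and
#' symmetric the filter introduces no group delay (the impulse response is
#' time-symmetric), and the attenuation one octave outside the band exceeds
#' 20 dB by construction (the gain is identically zero there).
#'
#' @param x numeric signal.
#' @param low,high pass-band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param fs sampling rate in Hz.
#' @param transition optional transition widths in Hz, length-2
#'   `c(below, above)`; defaults to `c(low/4, high/4)` (capped at Nyquist).
#' @return filtered numeric signal of the same length.
#' @export
bandpass <- function(x, low, high, fs, transition = NULL) {
  stopifnot_scalar(low, "low", positive = TRUE)
  stopifnot_scalar(high, "high", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (low >= high) stop("`low` must be < `high`", call. = FALSE)
  if (high >= fs / 2) stop("band touches or exceeds Nyquist (fs/2)", call. = FALSE)
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (is.null(transition)) transition <- c(low / 4, high / 4)
  tw_lo <- min(transition[1], low * 0.999)
  tw_hi <- min(transition[2], fs / 2 - high)
  n <- length(x)
  f <- fs * (0:(n - 1)) / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  gain <- numeric(n)
  inb <- f >= low & f <= high
  gain[inb] <- 1
  lo_ramp <- f >= (low - tw_lo) & f < low
  gain[lo_ramp] <- 0.5 * (1 + cos(pi * (low - f[lo_ramp]) / tw_lo))
  if (tw_hi > 0) {
    hi_ramp <- f > high & f <= (high + tw_hi)
    gain[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - high) / tw_hi))
  }
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal, in radians over `(-pi, pi]`. Phase 0
#' corresponds to the peak of the real oscillation (cosine convention).
#' The caller is responsible for band-limiting the input (see [bandpass()]).
#'
#' @param x numeric signal (band-limited).
#' @return numeric vector of phases in radians.
#' @export
analytic_phase <- function(x) wrap_phase(Arg(analytic_signal(x)))

#' Instantaneous amplitude (envelope) of a band-limited signal
#'
#' Modulus of the analytic signal.
#'
#' @inheritParams analytic_phase
#' @return numeric envelope, same length as `x`.
#' @export
analytic_amplitude <- function(x) Mod(analytic_signal(x))
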