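# Trial segmentation, Morlet time-frequency decomposition, live/dead
# artifact subtraction, and inter-trial phase coherence:
# ITPC(t) = | (1/N) * sum_k exp(i * theta_k(t)) |, the resultant vector
# length of the per-trial instantaneous phases.

#' Segment a recording into stimulation-aligned trials
#'
#' Trial k covers `[onset_k - pre, onset_k + post)`. Onsets whose window
#' would overrun the recording are dropped (never zero-padded, which would
#' bias ITPC at the edges); the dropped count is reported via a message and
#' stored in the result.
#'
#' @param recording an [lfp_recording()] with at least one event.
#' @param window length-2 `c(pre, post)` in seconds; default `c(0.2, 1)`
#'   covering a 1-s sonication with a 0.2-s baseline.
#' @return an object of class `TrialSet`: `trials`
#'   (n_trials x n_samples matrix), `fs`, `window`, `times` (s relative to
#'   onset), `onset_times`, `n_dropped`.
#' @export
segment_trials <- function(recording, window = c(0.2, 1)) {
  stopifnot(inherits(recording, "LfpRecording"))
  if (length(window) != 2L || window[1] < 0 || window[2] <= 0)
    stop("`window` must be c(pre >= 0, post > 0)", call. = FALSE)
  if (length(recording$events) == 0)
    stop("recording has no stimulation events", call. = FALSE)
  fs <- recording$fs
  npre <- round(window[1] * fs)
  npost <- round(window[2] * fs)
  n <- length(recording$samples)
  rows <- list(); kept <- numeric(0); dropped <- 0L
  for (onset in recording$events) {
    i0 <- round(onset * fs) + 1L
    lo <- i0 - npre; hi <- i0 + npost - 1L
    if (lo < 1L || hi > n) { dropped <- dropped + 1L; next }
    rows[[length(rows) + 1L]] <- recording$samples[lo:hi]
    kept <- c(kept, onset)
  }
  if (length(rows) == 0) stop("no usable onsets: every window overruns the recording", call. = FALSE)
  if (dropped > 0)
    message(sprintf("segment_trials: dropped %d onset(s) whose window overruns the recording", dropped))
  structure(list(trials = do.call(rbind, rows), fs = fs, window = window,
                 times = (seq_len(npre + npost) - 1L - npre) / fs,
                 onset_times = kept, n_dropped = dropped),
            class = "TrialSet")
}

#' @export
print.TrialSet <- function(x, ...) {
  cat(sprintf("<TrialSet> %d trials x %d samples @ %g Hz, window (-%g, %g) s, %d dropped\n",
              nrow(x$trials), ncol(x$trials), x$fs, x$window[1], x$window[2],
              x$n_dropped))
  invisible(x)
}

# Complex Morlet wavelet transform of one trial at one frequency, via FFT
# convolution with zero padding. Wavelets are L2-normalized so white noise
# yields a flat expected power profile across frequencies.
morlet_row <- function(x, f, fs, n_cycles) {
  sigma <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma * fs)
  tt <- (-half:half) / fs
  psi <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma^2))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  n <- length(x)
  nfft <- next_pow2(n + length(psi) - 1L)
  conv <- stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(psi, numeric(nfft - length(psi)))),
                     inverse = TRUE) / nfft
  conv[(half + 1L):(half + n)]
}

#' Time-frequency representation of a trial set
#'
#' Complex Morlet decomposition (default 7 cycles) of every trial, returned
#' as trial-averaged power alongside (optionally) the per-trial complex
#' coefficients.
#'
#' @param trials a [segment_trials()] result.
#' @param freqs frequency grid in Hz; default 1-Hz steps over 1..100 (values
#'   below the reciprocal trial length are unresolvable and rejected).
#' @param n_cycles wavelet width in cycles (default 7).
#' @param keep_coefficients keep the n_trials x n_samples x n_freqs complex
#'   coefficient array (default TRUE).
#' @return an object of class `Tfr`: `times`, `freqs`, `power`
#'   (n_samples x n_freqs trial-averaged), `coefficients` (or NULL),
#'   `method`, `n_trials`.
#' @export
compute_tfr <- function(trials, freqs = 1:100, n_cycles = 7,
                        keep_coefficients = TRUE) {
  stopifnot(inherits(trials, "TrialSet"))
  ns <- ncol(trials$trials)
  if (any(freqs <= 0) || any(freqs >= trials$fs / 2))
    stop("`freqs` must lie in (0, fs/2)", call. = FALSE)
  if (any(freqs < trials$fs / ns))
    stop(sprintf("frequencies below 1/window length (%.3g Hz) are unresolvable",
                 trials$fs / ns), call. = FALSE)
  nt <- nrow(trials$trials)
  power <- matrix(0, ns, length(freqs))
  coef <- if (keep_coefficients) array(0i, dim = c(nt, ns, length(freqs))) else NULL
  for (j in seq_along(freqs)) {
    for (k in seq_len(nt)) {
      w <- morlet_row(trials$trials[k, ], freqs[j], trials$fs, n_cycles)
      power[, j] <- power[, j] + Mod(w)^2
      if (keep_coefficients) coef[k, , j] <- w
    }
  }
  structure(list(times = trials$times, freqs = freqs, power = power / nt,
                 coefficients = coef,
                 method = sprintf("morlet (%g cycles)", n_cycles),
                 n_trials = nt),
            class = "Tfr")
}

#' @export
print.Tfr <- function(x, ...) {
  cat(sprintf("<Tfr> %s: %d times x %d freqs (%g..%g Hz), %d trials%s\n",
              x$method, length(x$times), length(x$freqs), min(x$freqs),
              max(x$freqs), x$n_trials,
              if (!is.null(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Subtract an artifact-only TFR from a live TFR
#'
#' Element-wise subtraction of trial-averaged power, floored at zero
#' (live/dead recordings are separate sessions, so complex subtraction
#' across them is ill-defined; power subtraction removes the deterministic
#' electromagnetic pulse artifact's energy at the PRF and its harmonics).
#'
#' @param live,dead [compute_tfr()] results on identical time/frequency
#'   grids.
#' @return a `Tfr` with the cleaned power and a provenance note.
#' @export
subtract_artifact_tfr <- function(live, dead) {
  stopifnot(inherits(live, "Tfr"), inherits(dead, "Tfr"))
  if (!isTRUE(all.equal(live$times, dead$times)) ||
      !isTRUE(all.equal(live$freqs, dead$freqs)))
    stop("live and dead TFRs are on different time/frequency grids", call. = FALSE)
  out <- live
  out$power <- pmax(live$power - dead$power, 0)
  out$coefficients <- NULL
  out$provenance <- sprintf("live power minus dead power (%s)", live$method)
  out
}

#' Inter-trial phase coherence
#'
#' Each trial is band-passed at
#' `[target_freq - bandwidth/2, target_freq + bandwidth/2)` with the
#' zero-phase filter, the Hilbert instantaneous phase `theta_k(t)` is
#' extracted, and the resultant vector length
#' `ITPC(t) = |(1/N) * sum_k exp(i * theta_k(t))|` is returned per time
#' point: 1 means perfect phase locking across trials, and the expectation
#' under uniform (unlocked) phases is approximately `(1/2) * sqrt(pi / N)`.
#'
#' @param trials a [segment_trials()] result with N >= 2 trials.
#' @param target_freq center frequency in Hz (the PRF for entrainment
#'   analysis).
#' @param bandwidth full bandwidth in Hz; default 10 (35-45 Hz for a 40-Hz
#'   PRF), wide enough for the pulse response, narrow enough to exclude
#'   low-frequency leakage.
#' @return an object of class `ItpcSeries`: `times`, `itpc` (in [0, 1]),
#'   `n_trials`, `target_freq`, `bandwidth`.
#' @export
itpc <- function(trials, target_freq, bandwidth = 10) {
  stopifnot(inherits(trials, "TrialSet"))
  N <- nrow(trials$trials)
  if (N < 2) stop("ITPC needs at least 2 trials", call. = FALSE)
  lo <- target_freq - bandwidth / 2
  hi <- target_freq + bandwidth / 2
  if (lo <= 0 || hi >= trials$fs / 2)
    stop("ITPC band outside (0, fs/2)", call. = FALSE)
  acc <- complex(length.out = ncol(trials$trials))
  for (k in seq_len(N)) {
    theta <- analytic_phase(bandpass(trials$trials[k, ], lo, hi, trials$fs))
    acc <- acc + exp(1i * theta)
  }
  structure(list(times = trials$times, itpc = Mod(acc) / N, n_trials = N,
                 target_freq = target_freq, bandwidth = bandwidth),
            class = "ItpcSeries")
}

#' @export
print.ItpcSeries <- function(x, ...) {
  cat(sprintf("<ItpcSeries> %g Hz (+/- %g/2), N = %d trials: mean ITPC = %.3f\n",
              x$target_freq, x$bandwidth, x$n_trials, mean(x$itpc)))
  invisible(x)
}

#' Full entrainment report for a live/dead pair
#'
#' Pipeline: segment both recordings, compute their TFRs, subtract the dead
#' (artifact-only) power from the live power, and compute ITPC at the PRF on
#' the live trials. The report states whether the cleaned trial-averaged
#' spectrum, time-averaged over the post-onset window, peaks (within
#' `prf +/- 10` Hz) at the grid frequency nearest the PRF.
#'
#' @param live,dead [lfp_recording()] objects sharing `fs` and events.
#' @param prf pulse repetition frequency in Hz (default 40).
#' @param window epoch window `c(pre, post)` in s.
#' @param freqs TFR frequency grid.
#' @param bandwidth ITPC bandwidth (Hz).
#' @param itpc_on `"raw"` (default) computes ITPC on the live trials as
#'   recorded; `"cleaned"` first subtracts the dead trial average from each
#'   live trial (time-domain, valid because the artifact is
#'   stimulus-locked).
#' @return list with `cleaned_tfr`, `itpc`, `mean_itpc_sonication` (mean
#'   over `t` in `[0, post]`), `peak_freq`, `peak_at_prf`, `n_dropped`.
#' @export
entrainment_report <- function(live, dead, prf = 40, window = c(0.2, 1),
                               freqs = 1:100, bandwidth = 10,
                               itpc_on = c("raw", "cleaned")) {
  stopifnot(inherits(live, "LfpRecording"), inherits(dead, "LfpRecording"))
  itpc_on <- match.arg(itpc_on)
  if (live$fs != dead$fs) stop("live/dead sampling rates differ", call. = FALSE)
  if (length(live$events) == 0) stop("recordings have no stimulation events", call. = FALSE)
  if (!isTRUE(all.equal(live$events, dead$events)))
    stop("live/dead event times differ", call. = FALSE)
  tr_live <- segment_trials(live, window)
  tr_dead <- segment_trials(dead, window)
  tfr_live <- compute_tfr(tr_live, freqs, keep_coefficients = FALSE)
  tfr_dead <- compute_tfr(tr_dead, freqs, keep_coefficients = FALSE)
  cleaned <- subtract_artifact_tfr(tfr_live, tfr_dead)
  tr_itpc <- tr_live
  if (itpc_on == "cleaned") {
    avg_dead <- colMeans(tr_dead$trials)
    tr_itpc$trials <- sweep(tr_live$trials, 2, avg_dead)
  }
  series <- itpc(tr_itpc, prf, bandwidth)
  post_sel <- cleaned$times >= 0
  spec <- colMeans(cleaned$power[post_sel, , drop = FALSE])
  in_range <- which(freqs >= prf - 10 & freqs <= prf + 10)
  peak_freq <- freqs[in_range[which.max(spec[in_range])]]
  nearest <- freqs[which.min(abs(freqs - prf))]
  son_sel <- series$times >= 0
  list(cleaned_tfr = cleaned, itpc = series,
       mean_itpc_sonication = mean(series$itpc[son_sel]),
       peak_freq = peak_freq, peak_at_prf = peak_freq == nearest,
       n_dropped = tr_live$n_dropped)
}
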