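# Welch power spectral density estimation and canonical band-power
# decomposition over the delta/theta/alpha/beta/gamma partition.

#' Canonical frequency bands
#'
#' The default band set: delta [1,4), theta [4,8), alpha [8,13), beta
#' [13,30), gamma [30,70) Hz. Edges are half-open so the five bands form a
#' partition of [1, 70) with no double counting; a component at exactly
#' 4 Hz belongs to theta.
#'
#' @return data.frame with columns `name`, `low`, `high`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low  = c(1, 4, 8, 13, 30),
             high = c(4, 8, 13, 30, 70),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("name", "low", "high") %in% names(bands)))
    stop("`bands` must be a data.frame with columns name, low, high", call. = FALSE)
  if (any(bands$low <= 0) || any(bands$low >= bands$high))
    stop("each band must satisfy 0 < low < high", call. = FALSE)
  bands
}

#' Welch power spectral density estimate
#'
#' Segments the trace into tapered windows, averages one-sided periodograms.
#' Defaults follow the common convention when only "Welch's method" is
#' specified: 1-s Hann windows (1-Hz resolution, the coarsest band-edge
#' granularity needed), 50% overlap, per-segment linear detrend. The density
#' is normalized so that its Riemann sum over [0, fs/2] equals the mean
#' windowed segment variance (Parseval consistency).
#'
#' @param recording an [lfp_recording()], or a numeric trace (then `fs` is
#'   required).
#' @param window_length segment length in seconds (default 1).
#' @param overlap_fraction fractional overlap in `[0, 1)` (default 0.5).
#' @param fs sampling rate, only when `recording` is a bare numeric vector.
#' @return an object of class `PsdEstimate`: list with `freqs` (Hz,
#'   0..fs/2), `density` (units^2/Hz), `df`, `window_length`,
#'   `overlap_fraction`, `n_segments`, `fs`.
#' @export
welch_psd <- function(recording, window_length = 1, overlap_fraction = 0.5,
                      fs = NULL) {
  if (inherits(recording, "LfpRecording")) {
    x <- recording$samples
    fs <- recording$fs
  } else {
    x <- as.numeric(recording)
    if (is.null(fs)) stop("`fs` required for a bare numeric trace", call. = FALSE)
  }
  stopifnot_scalar(window_length, "window_length", positive = TRUE)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)", call. = FALSE)
  L <- round(window_length * fs)
  if (length(x) < 2 * L)
    stop(sprintf("recording too short: need >= %d samples (2 windows of %g s), got %d",
                 2 * L, window_length, length(x)), call. = FALSE)
  step <- max(1L, round(L * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- hann_window(L)
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- detrend_linear(x[s:(s + L - 1L)]) * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    p1 <- P[seq_len(nf)]
    # one-sided: double interior bins (DC and Nyquist are unique)
    if (L %% 2 == 0) p1[2:(nf - 1L)] <- 2 * p1[2:(nf - 1L)]
    else p1[2:nf] <- 2 * p1[2:nf]
    acc <- acc + p1
  }
  structure(list(freqs = (0:(nf - 1L)) * fs / L, density = acc / length(starts),
                 df = fs / L, window_length = window_length,
                 overlap_fraction = overlap_fraction,
                 n_segments = length(starts), fs = fs),
            class = "PsdEstimate")
}

#' @export
print.PsdEstimate <- function(x, ...) {
  cat(sprintf("<PsdEstimate> %d frequencies (0..%g Hz, df=%g), %d segments of %g s (%.0f%% overlap)\n",
              length(x$freqs), max(x$freqs), x$df, x$n_segments,
              x$window_length, 100 * x$overlap_fraction))
  invisible(x)
}

#' Band-power decomposition of a PSD
#'
#' Absolute power per band is the Riemann sum of the density over grid
#' points with `low <= f < high` (half-open, so contiguous bands partition
#' their union exactly and a tone on a shared edge is counted once, in the
#' upper band). Relative power is the fraction of the total over the union
#' of the default bands, [1, 70) Hz.
#'
#' @param psd a [welch_psd()] result.
#' @param bands band definition data.frame (see [default_bands()]).
#' @return a data.frame (class `BandPowerTable`) with columns `name`, `low`,
#'   `high`, `abs_power`, `rel_power`, and attribute `total_power` (power
#'   over [1, 70) Hz or the union of the supplied contiguous bands).
#' @export
band_power <- function(psd, bands = default_bands()) {
  stopifnot(inherits(psd, "PsdEstimate"))
  bands <- validate_bands(bands)
  if (any(bands$high > max(psd$freqs) + psd$df / 2))
    stop("band extends beyond the PSD support (fs/2)", call. = FALSE)
  band_sum <- function(lo, hi) {
    sel <- psd$freqs >= lo & psd$freqs < hi
    sum(psd$density[sel]) * psd$df
  }
  abs_power <- mapply(band_sum, bands$low, bands$high)
  total <- band_sum(min(bands$low), max(bands$high))
  out <- data.frame(name = bands$name, low = bands$low, high = bands$high,
                    abs_power = as.numeric(abs_power),
                    rel_power = as.numeric(abs_power) / total,
                    stringsAsFactors = FALSE)
  attr(out, "total_power") <- total
  class(out) <- c("BandPowerTable", "data.frame")
  out
}

#' Per-group band-power summary for a cohort
#'
#' Runs [welch_psd()] and [band_power()] on every recording and aggregates
#' by group: per (group, band) mean, standard deviation and n, plus total
#' power. Rows are ordered by group label, then band low edge.
#'
#' @param recordings list of [lfp_recording()] objects; grouping uses the
#'   `group` field (recordings with `NA` group form group `"all"`).
#' @param bands band definitions (see [default_bands()]).
#' @param window_length,overlap_fraction forwarded to [welch_psd()].
#' @return list with `subjects` (one row per recording x band) and `summary`
#'   (one row per group x band with mean/sd/n of absolute and relative
#'   power).
#' @export
cohort_band_summary <- function(recordings, bands = default_bands(),
                                window_length = 1, overlap_fraction = 0.5) {
  if (length(recordings) == 0) stop("no recordings supplied", call. = FALSE)
  rows <- list()
  for (rec in recordings) {
    stopifnot(inherits(rec, "LfpRecording"))
    bp <- band_power(welch_psd(rec, window_length, overlap_fraction), bands)
    grp <- if (is.na(rec$group)) "all" else rec$group
    rows[[length(rows) + 1L]] <- data.frame(
      group = grp, subject = rec$label, name = bp$name, low = bp$low,
      abs_power = bp$abs_power, rel_power = bp$rel_power,
      total_power = attr(bp, "total_power"), stringsAsFactors = FALSE)
  }
  subj <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(subj, list(subj$group, subj$name), drop = TRUE),
    function(d) data.frame(
      group = d$group[1], name = d$name[1], low = d$low[1],
      mean_abs = mean(d$abs_power), sd_abs = stats::sd(d$abs_power),
      mean_rel = mean(d$rel_power), sd_rel = stats::sd(d$rel_power),
      n = nrow(d), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$group, agg$low), ]
  rownames(agg) <- NULL
  list(subjects = subj, summary = agg)
}
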