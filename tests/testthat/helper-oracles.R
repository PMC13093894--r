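# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (direct FFT arithmetic, closed forms) so that
# implementation-vs-oracle tests are genuine dual routes.

# Closed-form Tort MI for the noiseless modulation law A(phi) = 1 + k*cos(phi):
# p_j is the analytic integral of A over each of n equal bins of (-pi, pi].
tort_oracle_mi <- function(kappa, n_bins) {
  br <- seq(-pi, pi, length.out = n_bins + 1)
  p <- diff(br) + kappa * diff(sin(br))
  p <- p / sum(p)
  H <- -sum(p * log(p))
  (log(n_bins) - H) / log(n_bins)
}

# Expected resultant vector length of N uniform random unit phasors
# (Rayleigh asymptotics): E[R] = (1/2) * sqrt(pi / N).
expected_uniform_itpc <- function(N) 0.5 * sqrt(pi / N)

# Naive Welch oracle: non-overlapping, boxcar (no taper), mean-removed
# segments, averaged one-sided periodograms.
naive_psd_oracle <- function(x, fs, L) {
  starts <- seq(1, length(x) - L + 1, by = L)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- seg - mean(seg)
    P <- Mod(stats::fft(seg))^2 / (fs * L)
    p1 <- P[1:nf]
    if (L %% 2 == 0) p1[2:(nf - 1)] <- 2 * p1[2:(nf - 1)]
    else p1[2:nf] <- 2 * p1[2:nf]
    acc <- acc + p1
  }
  list(freqs = (0:(nf - 1)) * fs / L, density = acc / length(starts), df = fs / L)
}

# Build a TrialSet directly from a trials matrix (bypasses segmentation).
make_trialset <- function(trials, fs, pre = 0) {
  structure(list(trials = trials, fs = fs,
                 window = c(pre, ncol(trials) / fs - pre),
                 times = (seq_len(ncol(trials)) - 1 - round(pre * fs)) / fs,
                 onset_times = rep(0, nrow(trials)), n_dropped = 0L),
            class = "TrialSet")
}

# N tone trials at frequency f with given per-trial phase offsets.
tone_trials <- function(phases, f, fs, dur) {
  tt <- (0:(round(dur * fs) - 1)) / fs
  make_trialset(t(vapply(phases, function(ph) cos(2 * pi * f * tt + ph),
                         numeric(length(tt)))), fs)
}
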