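# Synthetic LFP generator: 1/f background, band-limited oscillators,
# phase-amplitude-coupled gamma, a 40-Hz evoked component with von Mises
# phase locking to pulse onsets, and a deterministic electromagnetic pulse
# artifact shared between paired live/dead recordings. Every downstream
# stage is validated against this module's known ground truth.

#' Band-limited oscillator specification
#'
#' One narrow-band Gaussian-noise component of the synthetic LFP. Components
#' are realized as spectrally shaped noise rather than pure tones so that
#' PSD-based power estimates behave as they do on real recordings.
#'
#' @param center_freq center frequency in Hz.
#' @param bandwidth full bandwidth in Hz; the component occupies
#'   `[center_freq - bandwidth/2, center_freq + bandwidth/2]`.
#' @param rms_amplitude target RMS amplitude (arbitrary voltage units).
#' @param name optional component name (used by cohort multipliers).
#' @return an object of class `OscillatorSpec`.
#' @export
oscillator_spec <- function(center_freq, bandwidth, rms_amplitude, name = NULL) {
  stopifnot_scalar(center_freq, "center_freq", positive = TRUE)
  stopifnot_scalar(bandwidth, "bandwidth", positive = TRUE)
  stopifnot_scalar(rms_amplitude, "rms_amplitude")
  if (rms_amplitude < 0) stop("`rms_amplitude` must be >= 0", call. = FALSE)
  if (center_freq - bandwidth / 2 <= 0)
    stop("oscillator band extends to or below 0 Hz", call. = FALSE)
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 rms_amplitude = rms_amplitude,
                 name = if (is.null(name)) sprintf("osc%g", center_freq) else name),
            class = "OscillatorSpec")
}

#' Phase-amplitude coupling specification
#'
#' Ground truth for cross-frequency coupling: the envelope of a band-limited
#' carrier follows the modulation law
#' `A(t) = base * (1 + kappa * cos(phi_p(t) - preferred_phase))`,
#' where `phi_p` is the phase of a low-frequency driver.
#'
#' @param phase_freq driver frequency in Hz.
#' @param amp_band length-2 carrier band `(low, high)` in Hz.
#' @param coupling_strength modulation depth kappa in `[0, 1]`.
#' @param preferred_phase driver phase (radians) at which the carrier
#'   amplitude peaks; default 0.
#' @return an object of class `PacSpec`.
#' @export
pac_spec <- function(phase_freq, amp_band, coupling_strength,
                     preferred_phase = 0) {
  stopifnot_scalar(phase_freq, "phase_freq", positive = TRUE)
  if (length(amp_band) != 2L || amp_band[1] <= 0 || amp_band[1] >= amp_band[2])
    stop("`amp_band` must be (low, high) with 0 < low < high", call. = FALSE)
  stopifnot_scalar(coupling_strength, "coupling_strength")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("`coupling_strength` must be in [0, 1]", call. = FALSE)
  if (phase_freq >= amp_band[1])
    stop("`phase_freq` must be below `amp_band[1]`", call. = FALSE)
  structure(list(phase_freq = phase_freq, amp_band = as.numeric(amp_band),
                 coupling_strength = coupling_strength,
                 preferred_phase = preferred_phase),
            class = "PacSpec")
}

#' Stimulus-locked evoked component specification
#'
#' During each sonication window the generator adds an oscillation at the
#' pulse repetition frequency whose per-trial phase offset is drawn from a
#' von Mises distribution: concentration 0 gives no locking (uniform phase),
#' large concentrations give near-perfect locking. The analytic inter-trial
#' phase coherence of this model is `R = I1(kappa) / I0(kappa)`.
#'
#' @param prf pulse repetition frequency in Hz.
#' @param evoked_rms RMS amplitude of the evoked oscillation within
#'   sonication windows.
#' @param locking_concentration von Mises concentration kappa (>= 0).
#' @param preferred_phase mean phase offset in radians.
#' @return an object of class `EntrainmentSpec`.
#' @export
entrainment_spec <- function(prf, evoked_rms, locking_concentration,
                             preferred_phase = 0) {
  stopifnot_scalar(prf, "prf", positive = TRUE)
  stopifnot_scalar(evoked_rms, "evoked_rms")
  if (evoked_rms < 0) stop("`evoked_rms` must be >= 0", call. = FALSE)
  stopifnot_scalar(locking_concentration, "locking_concentration")
  if (locking_concentration < 0)
    stop("`locking_concentration` must be >= 0", call. = FALSE)
  structure(list(prf = prf, evoked_rms = evoked_rms,
                 locking_concentration = locking_concentration,
                 preferred_phase = preferred_phase),
            class = "EntrainmentSpec")
}

#' Electromagnetic pulse artifact specification
#'
#' A deterministic transient repeated at the PRF during sonication windows,
#' rendered identically into the live and dead recordings of a pair. The
#' default waveform is a short biphasic (single-cycle damped sine) transient;
#' the physical artifact's shape is not constrained by the recording setup,
#' so the template is a declared default, overridable per period.
#'
#' @param prf pulse repetition frequency in Hz.
#' @param amplitude peak amplitude (arbitrary voltage units).
#' @param waveform optional one-period template; must have exactly
#'   `round(fs / prf)` samples when rendered at sampling rate `fs`.
#' @return an object of class `ArtifactSpec`.
#' @export
artifact_spec <- function(prf, amplitude, waveform = NULL) {
  stopifnot_scalar(prf, "prf", positive = TRUE)
  stopifnot_scalar(amplitude, "amplitude")
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(prf = prf, amplitude = amplitude, waveform = waveform),
            class = "ArtifactSpec")
}

#' Default biphasic artifact template
#'
#' One pulse period (`round(fs/prf)` samples) containing a single-cycle
#' damped sine of ~4 ms, peak-normalized to `amplitude`, then zeros.
#'
#' @inheritParams artifact_spec
#' @param fs sampling rate in Hz.
#' @return numeric template of length `round(fs / prf)`.
#' @export
default_artifact_template <- function(prf, fs, amplitude = 1) {
  period <- round(fs / prf)
  tmpl <- numeric(period)
  len <- min(period, max(4L, round(0.004 * fs)))
  tt <- (0:(len - 1)) / fs
  dur <- len / fs
  w <- sin(2 * pi * tt / dur) * exp(-3 * tt / dur)
  tmpl[seq_len(len)] <- w / max(abs(w)) * amplitude
  tmpl
}

#' Stimulation trial schedule
#'
#' Onsets start at `start_offset` and repeat every
#' `sonication_duration + inter_stimulus_interval`. With the default 1-s
#' sonication, 10-s inter-stimulus interval and a 300-s recording, 27 trials
#' fit.
#'
#' @param sonication_duration seconds of stimulation per trial.
#' @param inter_stimulus_interval seconds between sonication offset and the
#'   next onset.
#' @param duration total recording duration in seconds.
#' @param n_trials number of trials; default as many as fit.
#' @param start_offset lead-in before the first onset (s); default 0.5 so the
#'   default epoch pre-window never overruns the recording start.
#' @return an object of class `TrialSchedule` with an `onsets` field.
#' @export
trial_schedule <- function(sonication_duration = 1, inter_stimulus_interval = 10,
                           duration = 300, n_trials = NULL, start_offset = 0.5) {
  stopifnot_scalar(sonication_duration, "sonication_duration", positive = TRUE)
  stopifnot_scalar(inter_stimulus_interval, "inter_stimulus_interval", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  period <- sonication_duration + inter_stimulus_interval
  max_fit <- floor((duration - start_offset) / period)
  if (is.null(n_trials)) n_trials <- max_fit
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("schedule fits no trials in `duration`", call. = FALSE)
  if (n_trials > max_fit)
    stop(sprintf("schedule overflows the recording: %d trials of %g s fit in %.2f s, %d requested",
                 max_fit, period, duration, n_trials), call. = FALSE)
  onsets <- start_offset + (seq_len(n_trials) - 1L) * period
  structure(list(sonication_duration = sonication_duration,
                 inter_stimulus_interval = inter_stimulus_interval,
                 duration = duration, n_trials = n_trials,
                 start_offset = start_offset, onsets = onsets),
            class = "TrialSchedule")
}

#' Default canonical-band oscillator set
#'
#' Five band-limited components spanning the canonical delta through gamma
#' bands, with RMS amplitudes decreasing with frequency as in typical
#' hippocampal LFP.
#'
#' @return named list of [oscillator_spec()] objects.
#' @export
default_oscillators <- function() {
  list(
    delta = oscillator_spec(2.5, 3, 0.90, "delta"),
    theta = oscillator_spec(6.0, 4, 0.70, "theta"),
    alpha = oscillator_spec(10.5, 5, 0.45, "alpha"),
    beta  = oscillator_spec(21.5, 17, 0.35, "beta"),
    gamma = oscillator_spec(50.0, 40, 0.40, "gamma")
  )
}

#' Simulation configuration
#'
#' Fully determines one synthetic recording (or live/dead pair): a given
#' config and seed always produce bitwise-identical output.
#'
#' @param duration recording length in s (default 300, i.e. 5 min).
#' @param fs sampling rate in Hz (default 1000).
#' @param pink_exponent spectral exponent of the 1/f background
#'   (power ~ 1/f^exponent), in `[0, 2]`.
#' @param pink_rms RMS of the background (default 0.3: the generator is
#'   deliberately oscillator-dominated so band powers are attributable to
#'   their band components and generator multipliers are recoverable as
#'   squared power ratios; see the methods vignette).
#' @param oscillators list of [oscillator_spec()]; default the canonical five.
#' @param pac optional [pac_spec()].
#' @param pac_rms base RMS of the PAC driver/carrier pair.
#' @param entrainment optional [entrainment_spec()].
#' @param artifact optional [artifact_spec()].
#' @param schedule a [trial_schedule()]; default derived from `duration`.
#' @param sensor_noise_rms white sensor noise added independently to each
#'   recording of a pair (0 disables; required for exact live-minus-dead
#'   identities).
#' @param seed integer master seed; component seeds are derived from it.
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(duration = 300, fs = 1000, pink_exponent = 1,
                       pink_rms = 0.3, oscillators = default_oscillators(),
                       pac = NULL, pac_rms = 0.4, entrainment = NULL,
                       artifact = NULL, schedule = NULL,
                       sensor_noise_rms = 0, seed = 1L) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (pink_exponent < 0 || pink_exponent > 2)
    stop("`pink_exponent` must be in [0, 2]", call. = FALSE)
  if (is.null(schedule)) schedule <- trial_schedule(duration = duration)
  if (schedule$duration > duration)
    stop("schedule duration exceeds recording duration", call. = FALSE)
  top <- vapply(oscillators, function(o) o$center_freq + o$bandwidth / 2, 0)
  if (length(top) && fs < 2 * max(top))
    stop("fs below twice the highest component frequency", call. = FALSE)
  structure(list(duration = duration, fs = fs, pink_exponent = pink_exponent,
                 pink_rms = pink_rms, oscillators = oscillators, pac = pac,
                 pac_rms = pac_rms, entrainment = entrainment,
                 artifact = artifact, schedule = schedule,
                 sensor_noise_rms = sensor_noise_rms, seed = as.integer(seed)),
            class = "SimConfig")
}

#' LFP recording container
#'
#' @param samples numeric voltage trace (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param events stimulation-onset times in seconds, within
#'   `[0, duration)`.
#' @param label free-text label.
#' @param group optional group label (used by cohort summaries).
#' @param ground_truth optional `SimConfig` (plus cohort multipliers) that
#'   produced the recording.
#' @return an object of class `LfpRecording`.
#' @export
lfp_recording <- function(samples, fs, events = numeric(0), label = "",
                          group = NA_character_, ground_truth = NULL) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (!is.numeric(samples) || !all(is.finite(samples)))
    stop("`samples` must be finite numeric", call. = FALSE)
  duration <- length(samples) / fs
  events <- as.numeric(events)
  if (length(events) && (any(events < 0) || any(events >= duration)))
    stop("event times must lie within [0, duration)", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs, events = events,
                 label = label, group = group, ground_truth = ground_truth),
            class = "LfpRecording")
}

#' @export
print.LfpRecording <- function(x, ...) {
  cat(sprintf("<LfpRecording> %s%s: %.1f s @ %g Hz, %d events\n",
              x$label, if (is.na(x$group)) "" else sprintf(" [%s]", x$group),
              length(x$samples) / x$fs, x$fs, length(x$events)))
  invisible(x)
}

#' Generate 1/f ("pink") background noise
#'
#' Gaussian noise spectrally shaped so that power density is proportional to
#' `1/f^exponent`, standardized to the requested RMS. `exponent = 0` is the
#' white-noise limit.
#'
#' @param duration length in seconds.
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent in `[0, 2]`.
#' @param rms target RMS.
#' @param seed integer seed (fully determines the trace).
#' @return numeric trace of `round(duration * fs)` samples.
#' @export
generate_pink_noise <- function(duration, fs, exponent = 1, rms = 1, seed = 1L) {
  stopifnot_scalar(duration, "duration", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (exponent < 0 || exponent > 2)
    stop("`exponent` must be in [0, 2]", call. = FALSE)
  n <- round(duration * fs)
  if (rms == 0) return(numeric(n))
  white <- with_seed(seed, stats::rnorm(n))
  X <- stats::fft(white)
  f <- fs * (0:(n - 1)) / n
  f <- pmin(f, fs - f)
  scale <- numeric(n)
  nz <- f > 0
  scale[nz] <- f[nz]^(-exponent / 2)
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x / stats::sd(x) * rms
}

#' Generate one band-limited oscillator component
#'
#' Gaussian noise passed through the zero-phase band-pass filter, scaled to
#' the spec's RMS. The filter's raised-cosine transitions (1/16 of the
#' bandwidth) are placed inside the nominal band, so essentially all of the
#' component's power lies within `[center - bw/2, center + bw/2)` and
#' nothing leaks into neighboring analysis bands (ground-truth closure for
#' band-power recovery).
#'
#' @param spec an [oscillator_spec()].
#' @param duration,fs,seed as in [generate_pink_noise()].
#' @return numeric trace.
#' @export
generate_oscillator <- function(spec, duration, fs, seed = 1L) {
  stopifnot(inherits(spec, "OscillatorSpec"))
  n <- round(duration * fs)
  if (spec$rms_amplitude == 0) return(numeric(n))
  lo <- spec$center_freq - spec$bandwidth / 2
  hi <- spec$center_freq + spec$bandwidth / 2
  if (hi >= fs / 2) stop("oscillator band exceeds Nyquist", call. = FALSE)
  white <- with_seed(seed, stats::rnorm(n))
  tw <- spec$bandwidth / 16
  x <- bandpass(white, lo + tw, hi - tw, fs, transition = c(tw, tw))
  x / stats::sd(x) * spec$rms_amplitude
}

#' Generate a phase-amplitude-coupled component pair
#'
#' Returns the sum of a narrow-band noise driver centered at `phase_freq`
#' (RMS `base_rms`, bandwidth `phase_freq / 2`) and a band-limited carrier
#' whose envelope follows
#' `base_rms * (1 + kappa * cos(phi_driver(t) - preferred_phase))`, where
#' `phi_driver` is the driver's Hilbert phase. With `kappa = 0` the carrier
#' amplitude is independent of the driver phase. The driver is noise rather
#' than a pure tone: a strictly periodic driver would defeat time-shift
#' surrogates (shifting the envelope against a periodic phase merely rotates
#' the preferred phase without destroying the coupling).
#'
#' The carrier noise is rendered on the band inset by `phase_freq` at each
#' edge, so that the modulation sidebands (at carrier +/- `phase_freq`) stay
#' inside `amp_band`: an analysis filter at `amp_band` then recovers the
#' full modulation depth (ground-truth closure) instead of clipping it.
#'
#' @param pac a [pac_spec()].
#' @param duration,fs,seed as in [generate_pink_noise()].
#' @param base_rms base amplitude scale of both driver and carrier.
#' @return numeric trace.
#' @export
generate_pac_component <- function(pac, duration, fs, base_rms = 1, seed = 1L) {
  stopifnot(inherits(pac, "PacSpec"))
  if (pac$amp_band[2] >= fs / 2)
    stop("`amp_band` exceeds Nyquist (fs/2)", call. = FALSE)
  driver <- generate_oscillator(
    oscillator_spec(pac$phase_freq, pac$phase_freq / 2, base_rms, "pac_driver"),
    duration, fs, derive_seed(seed, "pac_driver"))
  phi <- analytic_phase(driver)
  inner <- pac$amp_band + c(pac$phase_freq, -pac$phase_freq)
  if (inner[1] >= inner[2])
    stop("`amp_band` too narrow: must be wider than 2 * phase_freq", call. = FALSE)
  carrier <- generate_oscillator(
    oscillator_spec((inner[1] + inner[2]) / 2, diff(inner), 1, "pac_carrier"),
    duration, fs, seed)
  modulated <- base_rms *
    (1 + pac$coupling_strength * cos(phi - pac$preferred_phase)) * carrier
  driver + modulated
}

#' Generate stimulus-locked evoked trials
#'
#' Renders the evoked component of an [entrainment_spec()]: during each
#' sonication window an oscillation at the PRF whose phase offset is a fresh
#' von Mises draw per trial; zero outside sonication windows.
#'
#' @param spec an [entrainment_spec()].
#' @param schedule a [trial_schedule()].
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return list with `samples` (full-length trace) and `events`
#'   (onset times in s, one per trial).
#' @export
generate_entrained_trials <- function(spec, schedule, fs, seed = 1L) {
  stopifnot(inherits(spec, "EntrainmentSpec"), inherits(schedule, "TrialSchedule"))
  n <- round(schedule$duration * fs)
  x <- numeric(n)
  len <- round(schedule$sonication_duration * fs)
  phases <- with_seed(seed,
    rvonmises(schedule$n_trials, spec$preferred_phase, spec$locking_concentration))
  tt <- (0:(len - 1)) / fs
  for (k in seq_len(schedule$n_trials)) {
    i0 <- round(schedule$onsets[k] * fs) + 1L
    idx <- i0:(i0 + len - 1L)
    x[idx] <- x[idx] +
      sqrt(2) * spec$evoked_rms * cos(2 * pi * spec$prf * tt + phases[k])
  }
  list(samples = x, events = schedule$onsets)
}

# Deterministic artifact rendering: the template repeated at the PRF inside
# every sonication window. No RNG, so live and dead copies are identical.
render_artifact <- function(spec, schedule, fs) {
  period <- round(fs / spec$prf)
  tmpl <- spec$waveform
  if (is.null(tmpl)) {
    tmpl <- default_artifact_template(spec$prf, fs, spec$amplitude)
  } else {
    if (length(tmpl) != period)
      stop(sprintf("artifact waveform must have round(fs/prf) = %d samples", period),
           call. = FALSE)
    tmpl <- tmpl * spec$amplitude
  }
  n <- round(schedule$duration * fs)
  x <- numeric(n)
  pulses_per_trial <- floor(schedule$sonication_duration * spec$prf)
  for (onset in schedule$onsets) {
    for (j in seq_len(pulses_per_trial) - 1L) {
      i0 <- round((onset + j / spec$prf) * fs) + 1L
      idx <- i0:min(i0 + period - 1L, n)
      x[idx] <- x[idx] + tmpl[seq_along(idx)]
    }
  }
  x
}

#' Render all configured components of a simulation
#'
#' The building block behind [simulate_recording_pair()]; exposed so that
#' tests can assert component additivity and exact artifact cancellation.
#'
#' @param config a [sim_config()].
#' @return list with `neural` (sum of pink background, oscillators, PAC and
#'   evoked components), `artifact`, the individual `components`, and
#'   `events`.
#' @export
simulate_components <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- round(config$duration * config$fs)
  comp <- list()
  comp$pink <- generate_pink_noise(config$duration, config$fs,
                                   config$pink_exponent, config$pink_rms,
                                   derive_seed(config$seed, "pink"))
  osc_sum <- numeric(n)
  for (i in seq_along(config$oscillators)) {
    o <- config$oscillators[[i]]
    osc_sum <- osc_sum + generate_oscillator(o, config$duration, config$fs,
                                             derive_seed(config$seed, o$name, i))
  }
  comp$oscillators <- osc_sum
  comp$pac <- if (!is.null(config$pac))
    generate_pac_component(config$pac, config$duration, config$fs,
                           config$pac_rms, derive_seed(config$seed, "pac"))
    else numeric(n)
  events <- config$schedule$onsets
  if (!is.null(config$entrainment)) {
    ent <- generate_entrained_trials(config$entrainment, config$schedule,
                                     config$fs, derive_seed(config$seed, "entrain"))
    comp$evoked <- ent$samples
    events <- ent$events
  } else comp$evoked <- numeric(n)
  artifact <- if (!is.null(config$artifact))
    render_artifact(config$artifact, config$schedule, config$fs)
    else numeric(n)
  list(neural = comp$pink + comp$oscillators + comp$pac + comp$evoked,
       artifact = artifact, components = comp, events = events)
}

#' Simulate a paired live/dead recording
#'
#' The live recording contains all neural components plus the pulse
#' artifact; the dead recording contains the artifact alone (the animal is
#' euthanized, the stimulation hardware still runs). Both share event times
#' and the identical artifact rendering, so with sensor noise disabled
#' `live - dead` equals the neural-only signal exactly.
#'
#' @param config a [sim_config()].
#' @return list with `live` and `dead` [lfp_recording()] objects.
#' @export
simulate_recording_pair <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (!is.null(config$artifact) && !is.null(config$entrainment) &&
      config$artifact$prf != config$entrainment$prf)
    warning("artifact PRF differs from entrainment PRF (physically independent; proceeding)")
  parts <- simulate_components(config)
  n <- length(parts$neural)
  noise_live <- noise_dead <- numeric(n)
  if (config$sensor_noise_rms > 0) {
    noise_live <- with_seed(derive_seed(config$seed, "sensor_live"),
                            stats::rnorm(n, sd = config$sensor_noise_rms))
    noise_dead <- with_seed(derive_seed(config$seed, "sensor_dead"),
                            stats::rnorm(n, sd = config$sensor_noise_rms))
  }
  list(
    live = lfp_recording(parts$neural + parts$artifact + noise_live, config$fs,
                         parts$events, label = "live", ground_truth = config),
    dead = lfp_recording(parts$artifact + noise_dead, config$fs,
                         parts$events, label = "dead", ground_truth = config)
  )
}

#' Simulate a multi-group cohort of recordings
#'
#' One neural-only recording per subject; each group scales the oscillator
#' RMS amplitudes by named multipliers (e.g. an amyloid-pathology group with
#' all bands at 0.5, a treated group with gamma restored to 1). Subject
#' seeds are derived deterministically from `(base$seed, label, index)` via
#' a documented rolling hash, so cohorts are reproducible and collision-free.
#'
#' @param group_specs list of groups, each a list with `label`,
#'   `n_subjects` (>= 2) and `multipliers` (named numeric over oscillator
#'   names; omitted names default to 1).
#' @param base a [sim_config()] providing every other parameter.
#' @return list of [lfp_recording()] objects, one per subject, each carrying
#'   its `group` and a `ground_truth` with the applied multipliers.
#' @export
simulate_cohort <- function(group_specs, base) {
  stopifnot(inherits(base, "SimConfig"))
  labels <- vapply(group_specs, function(g) g$label, "")
  if (anyDuplicated(labels))
    stop("duplicate group labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  osc_names <- vapply(base$oscillators, function(o) o$name, "")
  out <- list()
  for (g in group_specs) {
    n_sub <- as.integer(g$n_subjects)
    if (n_sub < 2L) stop("each group needs n_subjects >= 2", call. = FALSE)
    mult <- g$multipliers
    if (is.null(mult)) mult <- numeric(0)
    if (length(mult) && (is.null(names(mult)) || !all(names(mult) %in% osc_names)))
      stop(sprintf("group '%s': multipliers name unknown bands: %s", g$label,
                   paste(setdiff(names(mult), osc_names), collapse = ", ")),
           call. = FALSE)
    if (any(mult < 0)) stop("multipliers must be >= 0", call. = FALSE)
    full <- stats::setNames(rep(1, length(osc_names)), osc_names)
    full[names(mult)] <- mult
    osc <- base$oscillators
    for (i in seq_along(osc)) osc[[i]]$rms_amplitude <-
      osc[[i]]$rms_amplitude * full[[osc[[i]]$name]]
    for (i in seq_len(n_sub)) {
      cfg <- base
      cfg$oscillators <- osc
      cfg$seed <- derive_seed(base$seed, g$label, i)
      parts <- simulate_components(cfg)
      gt <- cfg
      gt$multipliers <- full
      out[[length(out) + 1L]] <- lfp_recording(
        parts$neural, cfg$fs, parts$events,
        label = sprintf("%s_%d", g$label, i), group = g$label,
        ground_truth = gt)
    }
  }
  out
}
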