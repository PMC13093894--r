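# Pulsed-ultrasound dose arithmetic: duty cycle, temporal-average vs
# pulse-average intensity, plane-wave peak pressure, mechanical index, and
# the regulatory-bound checks (diagnostic Isppa ceiling 190 W/cm^2;
# inertial-cavitation MI threshold 1.9).

FDA_ISPPA_LIMIT <- 190   # W/cm^2, diagnostic ultrasound ceiling
MI_THRESHOLD <- 1.9      # inertial cavitation threshold

#' Pulsed-ultrasound stimulation scheme
#'
#' Exactly one of `i_spta` (spatial-peak temporal-average) or `i_sppa`
#' (spatial-peak pulse-average) intensity must be given; the other is derived
#' through the duty cycle. The duty cycle here is the within-sonication value
#' `prf * burst_duration` (not diluted by the inter-stimulus interval) — the
#' only reading under which a ~2.14 W/cm^2 Ispta and ~42.6 W/cm^2 Isppa are
#' mutually consistent at 5% duty.
#'
#' @param center_freq_mhz carrier frequency in MHz (default 0.5).
#' @param prf pulse repetition frequency in Hz (default 40).
#' @param burst_duration tone-burst duration in s (default 1.25e-3).
#' @param sonication_duration s of pulsing per trial (default 1).
#' @param inter_stimulus_interval s between sonications (default 10).
#' @param i_spta,i_sppa intensity in W/cm^2 (supply exactly one).
#' @param session_minutes,sessions_per_day,total_days treatment regimen
#'   (defaults: 20 min, twice daily, 14 d).
#' @return an object of class `PulseScheme`.
#' @export
pulse_scheme <- function(center_freq_mhz = 0.5, prf = 40,
                         burst_duration = 1.25e-3, sonication_duration = 1,
                         inter_stimulus_interval = 10, i_spta = NULL,
                         i_sppa = NULL, session_minutes = 20,
                         sessions_per_day = 2, total_days = 14) {
  for (nm in c("center_freq_mhz", "prf", "burst_duration",
               "sonication_duration", "inter_stimulus_interval"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  if (prf * burst_duration > 1)
    stop("duty cycle prf * burst_duration exceeds 1 (bursts overlap)", call. = FALSE)
  if (is.null(i_spta) == is.null(i_sppa))
    stop("supply exactly one of `i_spta` or `i_sppa`", call. = FALSE)
  primary <- if (is.null(i_sppa)) "i_spta" else "i_sppa"
  val <- if (primary == "i_spta") i_spta else i_sppa
  stopifnot_scalar(val, primary, positive = TRUE)
  structure(list(center_freq_mhz = center_freq_mhz, prf = prf,
                 burst_duration = burst_duration,
                 sonication_duration = sonication_duration,
                 inter_stimulus_interval = inter_stimulus_interval,
                 i_spta = i_spta, i_sppa = i_sppa, intensity_primary = primary,
                 session_minutes = session_minutes,
                 sessions_per_day = sessions_per_day, total_days = total_days),
            class = "PulseScheme")
}

#' Within-sonication duty cycle
#'
#' `prf * burst_duration`; in (0, 1], with 1 the continuous-wave limit.
#'
#' @param scheme a [pulse_scheme()].
#' @return dimensionless duty cycle.
#' @export
duty_cycle <- function(scheme) {
  stopifnot(inherits(scheme, "PulseScheme"))
  scheme$prf * scheme$burst_duration
}

#' Convert between temporal-average and pulse-average intensity
#'
#' `i_spta = i_sppa * duty_cycle`. Whichever intensity the scheme supplies
#' is primary; the other is derived.
#'
#' @param scheme a [pulse_scheme()].
#' @return list with `i_spta`, `i_sppa` (W/cm^2), `duty_cycle` and
#'   `primary`.
#' @export
convert_intensity <- function(scheme) {
  dc <- duty_cycle(scheme)
  if (scheme$intensity_primary == "i_spta")
    list(i_spta = scheme$i_spta, i_sppa = scheme$i_spta / dc,
         duty_cycle = dc, primary = "i_spta")
  else
    list(i_spta = scheme$i_sppa * dc, i_sppa = scheme$i_sppa,
         duty_cycle = dc, primary = "i_sppa")
}

#' Plane-wave peak pressure from pulse-average intensity
#'
#' Under a plane-wave assumption `p = sqrt(2 * Z * I)` with acoustic
#' impedance Z (default 1.5 MRayl, soft tissue / water).
#'
#' @param i_sppa pulse-average intensity in W/cm^2.
#' @param acoustic_impedance_mrayl impedance in MRayl.
#' @return peak pressure in MPa.
#' @export
peak_pressure_from_isppa <- function(i_sppa, acoustic_impedance_mrayl = 1.5) {
  stopifnot_scalar(i_sppa, "i_sppa", positive = TRUE)
  stopifnot_scalar(acoustic_impedance_mrayl, "acoustic_impedance_mrayl",
                   positive = TRUE)
  sqrt(2 * (acoustic_impedance_mrayl * 1e6) * (i_sppa * 1e4)) / 1e6
}

#' Mechanical index
#'
#' `MI = p / sqrt(f)` with peak (negative) pressure p in MPa and center
#' frequency f in MHz; the standard cavitation-risk proxy with regulatory
#' ceiling 1.9.
#'
#' @param peak_pressure_mpa peak pressure in MPa.
#' @param center_freq_mhz center frequency in MHz.
#' @return dimensionless mechanical index.
#' @export
mechanical_index <- function(peak_pressure_mpa, center_freq_mhz) {
  stopifnot_scalar(peak_pressure_mpa, "peak_pressure_mpa", positive = TRUE)
  stopifnot_scalar(center_freq_mhz, "center_freq_mhz", positive = TRUE)
  peak_pressure_mpa / sqrt(center_freq_mhz)
}

#' Full dose report for a pulse scheme
#'
#' Derives all dose quantities and evaluates the safety bounds:
#' `fda_isppa_ok` (Isppa <= 190 W/cm^2) and `mi_ok` (MI < 1.9). No skull
#' derating is applied (free-field characterization).
#'
#' @param scheme a [pulse_scheme()].
#' @param acoustic_impedance_mrayl plane-wave impedance (MRayl).
#' @return an object of class `DoseReport`.
#' @export
dose_report <- function(scheme, acoustic_impedance_mrayl = 1.5) {
  ci <- convert_intensity(scheme)
  pp <- peak_pressure_from_isppa(ci$i_sppa, acoustic_impedance_mrayl)
  mi <- mechanical_index(pp, scheme$center_freq_mhz)
  structure(list(
    duty_cycle = ci$duty_cycle, i_spta = ci$i_spta, i_sppa = ci$i_sppa,
    intensity_primary = ci$primary, peak_pressure_mpa = pp,
    mechanical_index = mi, fda_isppa_ok = ci$i_sppa <= FDA_ISPPA_LIMIT,
    mi_ok = mi < MI_THRESHOLD,
    within_sonication_fraction = scheme$sonication_duration /
      (scheme$sonication_duration + scheme$inter_stimulus_interval),
    acoustic_impedance_mrayl = acoustic_impedance_mrayl,
    center_freq_mhz = scheme$center_freq_mhz),
    class = "DoseReport")
}

#' @export
print.DoseReport <- function(x, ...) {
  cat(sprintf(paste0(
    "<DoseReport> duty cycle %.3g | Ispta %.4g W/cm^2 | Isppa %.4g W/cm^2 (primary: %s)\n",
    "  peak pressure %.3g MPa @ %.3g MHz -> MI %.3g\n",
    "  Isppa <= %g W/cm^2: %s | MI < %g: %s | sonication fraction %.4g\n"),
    x$duty_cycle, x$i_spta, x$i_sppa, x$intensity_primary,
    x$peak_pressure_mpa, x$center_freq_mhz, x$mechanical_index,
    FDA_ISPPA_LIMIT, x$fda_isppa_ok, MI_THRESHOLD, x$mi_ok,
    x$within_sonication_fraction))
  invisible(x)
}

#' The four named treatment protocols
#'
#' TUS1-TUS4: Ispta 0.33 or 2.14 W/cm^2 crossed with 7 or 14 treatment
#' days; all other pulse parameters shared (0.5 MHz, 40-Hz PRF, 1.25-ms
#' bursts, 1-s sonication, 10-s ISI, 20 min twice daily).
#'
#' @return named list of [pulse_scheme()] objects.
#' @export
tus_protocols <- function() {
  list(
    TUS1 = pulse_scheme(i_spta = 0.33, total_days = 7),
    TUS2 = pulse_scheme(i_spta = 2.14, total_days = 7),
    TUS3 = pulse_scheme(i_spta = 0.33, total_days = 14),
    TUS4 = pulse_scheme(i_spta = 2.14, total_days = 14)
  )
}
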