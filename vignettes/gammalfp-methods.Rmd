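---
title: "Methods: band power, phase-amplitude coupling, entrainment and dose arithmetic in gammalfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, phase-amplitude coupling, entrainment and dose arithmetic in gammalfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammalfp)
```

# Scope

`gammalfp` analyzes single-channel local field potential (LFP) recordings
acquired during 40-Hz pulsed transcranial ultrasound stimulation (TUS), the
paradigm used to entrain hippocampal gamma oscillations in mouse models of
amyloid pathology. It covers four analysis stages — Welch band power, Tort
phase-amplitude coupling (PAC), inter-trial phase coherence (ITPC) with
paired live/dead artifact subtraction, and pulsed-ultrasound dose
arithmetic — plus a synthetic LFP generator with known ground truth that
makes every stage testable without animal data. It does no biophysical
neuron or acoustic-field modeling, no multichannel analysis, and no
statistics beyond the two-branch group-comparison rule described below.

# Spectral analysis

Power spectral density is estimated by Welch's method: the trace is cut
into 1-s Hann-tapered segments with 50% overlap, each segment is linearly
detrended, and one-sided periodograms are averaged. The 1-s default gives
1-Hz resolution — the coarsest granularity at which the canonical band
edges are distinguishable; both window length and overlap are tunable.
The density is normalized so that its Riemann sum over $[0, f_s/2]$ equals
the mean tapered variance of the detrended segments. For signals whose
power lies within the resolvable range this equals the sample variance to
a few percent (asserted by the tests); for steep $1/f^e$ processes the raw
variance additionally contains sub-window drift that no 1-s-window
estimator can represent, and for $e$ approaching 2 leakage from that
unresolved power biases absolute levels even above 1 Hz. Band *ratios*
remain comparative, but absolute PSD levels for near-Brownian signals are
outside this estimator's validity envelope — a known limitation.

Band powers use the canonical partition delta $[1,4)$, theta $[4,8)$,
alpha $[8,13)$, beta $[13,30)$, gamma $[30,70)$ Hz. Edges are half-open so
the five bands tile $[1,70)$ with no double counting; a component at
exactly 4 Hz belongs to theta. Absolute power per band is the Riemann sum
of the density over grid points with $\mathrm{low} \le f < \mathrm{high}$:
this realizes the half-open convention exactly and makes band powers
additive to the $[1,70)$ total at $10^{-9}$ relative precision
(trapezoidal quadrature would split shared grid points between adjacent
bands). "Total power" means power over $[1,70)$ — the union of the defined
bands — not over the full Nyquist range, because the band table pairs the
total with the five bands. Since the source analyses do not state whether
powers were normalized, both absolute and relative (fraction of the
$[1,70)$ total) powers are always emitted.

# Phase-amplitude coupling

PAC is quantified by the Tort modulation index. The trace is band-passed
at the phase band (default theta $[4,8)$ or delta $[1,4)$) and at the
amplitude band (gamma $[30,70)$); instantaneous phase and envelope come
from the Hilbert analytic signal. Phases are binned into $n=18$ equal bins
over $(-\pi, \pi]$ (20° bins, the convention of the original formulation;
the sources state no bin count), the envelope is averaged per bin and
normalized to a distribution $p$, and

$$\mathrm{MI} = \frac{\log n - H(p)}{\log n}, \qquad
  H(p) = -\sum_j p_j \log p_j,$$

the Kullback-Leibler divergence of $p$ from uniform, normalized to
$[0,1]$. Phase 0 is the peak of the band-passed oscillation (cosine
convention) — preferred-phase reports depend on this and it is therefore
fixed in the documentation. Empty phase bins contribute $p_j = 0$ with
$0 \log 0 \equiv 0$ and are flagged. One second is trimmed from each end
before binning to exclude filter edge transients.

Significance for a single recording uses time-shift surrogates: the
envelope is circularly shifted against the phase series by uniform random
offsets of at least 1 s, preserving both marginals' autocorrelation
(unlike phase shuffling), and the observed MI is compared with the null's
95th percentile. Shift surrogates are powerless against strictly periodic
drivers — shifting merely rotates the preferred phase — which is why the
synthetic generator's driver is narrow-band noise, not a sinusoid (below).

The band-pass filter is a zero-phase FFT-domain mask: unity in the band,
raised-cosine transitions of one quarter of the nearer edge, zero beyond —
so attenuation one octave outside the band is total, exceeding the 20-dB
contract, and the impulse response is time-symmetric. The contract
(zero phase, stop-band attenuation) is normative; the realization is not.

# Entrainment analysis

Recordings are segmented into trials at stimulation onsets with a
$(-0.2, +1.0)$-s window covering the 1-s sonication (the sources give the
sonication duration but no epoch definition). Onsets whose window would
overrun the recording are dropped and counted, never zero-padded: padding
would bias ITPC upward at the edges.

The time-frequency representation (TFR) uses complex Morlet wavelets,
7 cycles, on a linear 1-Hz grid over 1-100 Hz — the field default when
only "a time-frequency representation" is specified, supporting both power
and phase. Wavelets are L2-normalized, so white noise yields a flat
expected power profile. Frequencies below the reciprocal trial length are
rejected as unresolvable.

The electromagnetic pulse artifact of the transducer is removed by
subtracting the trial-averaged power TFR of a paired post-mortem ("dead")
recording — artifact only, same stimulation — from the live TFR,
element-wise and floored at zero. Subtraction operates on power, not
complex coefficients, because live and dead are separate sessions whose
phases are not mutually aligned. The known cost: the live TFR contains a
cross term between the artifact and any phase-locked neural response that
power subtraction cannot remove; it scales linearly with artifact
amplitude and shrinks with the number of non-locked trials. At the
generator's default amplitudes the residual is well under the 5% tolerance
the tests assert; a tenfold artifact would scale it tenfold, so power
subtraction is *not* exact in construction even on simulated pairs.

ITPC at the pulse repetition frequency (PRF) is the resultant vector
length of the per-trial Hilbert phases: each trial is band-passed at
PRF ± 5 Hz (a 10-Hz default bandwidth — wide enough for the pulse
response, narrow enough to exclude theta/alpha leakage; unstated in the
sources), and

$$\mathrm{ITPC}(t) = \Bigl| \frac{1}{N} \sum_{k=1}^{N} e^{i\theta_k(t)} \Bigr|,$$

which is 1 under perfect locking and has expectation
$\tfrac{1}{2}\sqrt{\pi/N}$ under uniform phases. The defining sum is read
with the modulus (the "mean vector length"), as the accompanying text
states, even though the bare formula line omits the modulus sign. Whether
ITPC should be computed on raw or artifact-cleaned live trials is
ambiguous in the sources; both paths are exposed (`itpc_on = "raw"`
default, or `"cleaned"`, which subtracts the dead trial average in the
time domain — valid because the artifact is stimulus-locked).

# Dose arithmetic

The pulse scheme is 0.5-MHz carrier, 40-Hz PRF, 1.25-ms tone bursts, 1-s
sonication, 10-s inter-stimulus interval. The duty cycle is the
within-sonication value $\mathrm{PRF} \times \mathrm{burst} = 0.05$, not
diluted by the inter-stimulus interval: only this reading makes the
published temporal-average/pulse-average intensity pair (2.14 and
~42.6 W/cm², a 5% ratio) mutually consistent. The two intensities convert
via $I_\mathrm{spta} = I_\mathrm{sppa} \times \mathrm{duty}$; whichever is
supplied is primary and the other is derived ($2.14 / 0.05 = 42.8$, within
0.5% of the printed 42.6 — a rounding inconsistency in the source that the
package reports without privileging either figure).

Peak pressure is estimated under a plane-wave assumption,
$p = \sqrt{2 Z I_\mathrm{sppa}}$, with acoustic impedance
$Z = 1.5\ \mathrm{MRayl}$ (soft tissue/water, overridable) — a declared
assumption, since no pressure is published. The mechanical index is
$\mathrm{MI} = p[\mathrm{MPa}] / \sqrt{f[\mathrm{MHz}]}$. Safety flags
check $I_\mathrm{sppa} \le 190\ \mathrm{W/cm^2}$ (the diagnostic
regulatory ceiling) and $\mathrm{MI} < 1.9$ (the inertial-cavitation
threshold): for the strongest protocol, MI $\approx 1.60$. No skull
derating is applied, matching free-field characterization.

# The synthetic generator

The generator emulates the recording conditions the analyses assume:
1-kHz sampling, 5-min sessions, 1-s sonications every 11 s (27 trials),
with five additive components:

* **$1/f^e$ background** (default $e = 1$, RMS 0.3), FFT-shaped Gaussian
  noise.
* **Band-limited oscillators** for the five canonical bands (default RMS
  0.90, 0.70, 0.45, 0.35, 0.40 from delta to gamma), realized as
  zero-phase-filtered Gaussian noise rather than sinusoids so PSD
  estimates behave as on real data. Filter transitions sit *inside* the
  nominal band, so each component's power stays in its own band.
* **A PAC pair**: a narrow-band noise driver at the phase frequency and a
  gamma carrier whose envelope follows
  $1 + \kappa \cos(\varphi_\mathrm{driver} - \varphi_0)$,
  $\kappa \in [0,1]$. The carrier is rendered inset by the driver
  frequency at each band edge so modulation sidebands stay inside the
  analysis band — otherwise the analysis filter clips them and the
  measured MI under-reads its closed-form value by ~20%.
* **A stimulus-locked evoked component**: an oscillation at the PRF inside
  each sonication window, phase offset drawn per trial from a von Mises
  distribution with concentration $\kappa_{vM}$, giving the analytic
  locking ground truth $R = I_1(\kappa_{vM}) / I_0(\kappa_{vM})$.
* **A deterministic artifact**: a ~4-ms biphasic damped-sine transient
  repeated at the PRF, rendered identically into the live and dead
  recordings (the sources describe the artifact only as an
  electromagnetic pulse at the PRF; shape and amplitude are declared
  defaults, not inferred).

A configuration plus its integer seed determines the output bitwise;
cohort subject seeds derive from (base seed, group label, subject index)
through a documented rolling hash modulo a 31-bit prime. Cohorts scale
oscillator RMS per group (e.g. all bands at 0.5 for a pathology group,
gamma restored to 1.0 for a treated group), and each recording carries its
generating configuration as ground truth.

Two deliberate idealizations bound what a green test establishes. First,
the background is weak relative to the oscillators: this makes generator
multipliers recoverable as squared power ratios (the module's purpose),
whereas real LFP is far more background-dominated, so real-data effect
sizes will be smaller than synthetic ones. Second, components are
additive and stationary; no nonstationarity, movement artifact, volume
conduction or electrode drift is modeled. Green tests establish that the
estimators recover known ground truth under the stated noise model — not
that any biological claim holds.

# Group comparison

Metrics are compared across groups with the two-branch rule: per-group
Shapiro-Wilk normality at $\alpha = 0.05$; if every group passes, a
one-way ANOVA (equal-variance F test), otherwise Kruskal-Wallis. The
source phrasing ("ANOVA ..., followed by Kruskal-Wallis for nonparametric
datasets") is read as a branch, not a sequence — running both would
double-test. Degenerate constant groups fail the gate and fall through to
the rank branch, where all-identical data yields $p = 1$. Post-hoc
pairwise comparisons are out of scope (no procedure is named in the
sources), and no multiple-testing correction is applied across bands; all
raw p-values are reported so users can correct externally.

# Numerical notes

* FFT-domain filtering is circular; the PAC stage trims 1 s per edge, and
  tone-based tests evaluate interior samples.
* `welch_psd` requires at least two windows; bands beyond the PSD support,
  bands touching 0 or Nyquist, and TFR frequencies below the reciprocal
  window length are rejected with explanatory errors.
* MI is invariant to global amplitude scaling exactly, and to preferred-
  phase rotation exactly only for whole-bin rotations (binning error
  otherwise, second-order in bin width).
* ITPC of $N$ identical trials is 1 to machine precision regardless of
  content; antiphase pairs cancel to ~0 away from filter edges.
* The von Mises sampler is the Best-Fisher rejection method; $\kappa = 0$
  short-circuits to the uniform distribution.
* All randomness is confined to explicit seed arguments; generators
  restore the caller's RNG state.

# Known limitations

* Power-TFR artifact subtraction leaves phase-locked cross terms (see
  above); regression or component-based removal is explicitly out of
  scope.
* Absolute PSD levels for spectral exponents near 2 are biased by
  unresolved sub-window power.
* The dose module's pressure and MI rest on the plane-wave impedance
  assumption; with a measured pressure, `mechanical_index()` can be used
  directly.
* The surrogate PAC test assumes an aperiodic driver; for strictly
  periodic low-frequency rhythms its null is conservative to the point of
  uselessness.
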