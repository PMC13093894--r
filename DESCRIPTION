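Package: gammalfp
Title: Gamma-Band LFP Analysis for 40-Hz Pulsed Ultrasound Neuromodulation
Version: 0.1.0
Authors@R: person("LFP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal local field potential (LFP)
    recordings acquired during 40-Hz pulsed transcranial ultrasound
    stimulation. Provides Welch power spectral density estimation with
    canonical band-power decomposition (delta through gamma),
    phase-amplitude coupling via the Tort modulation index, inter-trial
    phase coherence with paired live/dead artifact subtraction in
    time-frequency space, pulsed-ultrasound dose arithmetic (duty cycle,
    Ispta/Isppa, mechanical index) with regulatory-bound checks, and a
    synthetic LFP generator with known ground truth for validating every
    stage without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
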