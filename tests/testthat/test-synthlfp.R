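fs <- 1000

test_that("pink noise meets its length, RMS, slope and determinism contract", {
  for (case in list(list(exp = 0, slope = 0), list(exp = 1, slope = -1))) {
    x <- generate_pink_noise(120, fs, exponent = case$exp, rms = 1, seed = 42)
    expect_length(x, 120 * fs)
    expect_lt(abs(sd(x) - 1), 0.05)
    # slope fit on an independent naive periodogram oracle, 2-100 Hz
    psd <- naive_psd_oracle(x, fs, L = 2000)
    sel <- psd$freqs >= 2 & psd$freqs <= 100
    b <- coef(lm(log(psd$density[sel]) ~ log(psd$freqs[sel])))[[2]]
    expect_lt(abs(b - case$slope), 0.2)
  }
  expect_identical(generate_pink_noise(5, fs, 1, 1, seed = 7),
                   generate_pink_noise(5, fs, 1, 1, seed = 7))
  expect_false(identical(generate_pink_noise(5, fs, 1, 1, seed = 7),
                         generate_pink_noise(5, fs, 1, 1, seed = 8)))
  expect_error(generate_pink_noise(-1, fs), "duration")
  expect_error(generate_pink_noise(5, fs, exponent = 3), "exponent")
})

test_that("spec constructors enforce their invariants", {
  expect_error(oscillator_spec(2, 5, 1), "0 Hz")
  expect_error(pac_spec(6, c(30, 70), 1.5), "coupling_strength")
  expect_error(pac_spec(35, c(30, 70), 0.5), "phase_freq")
  expect_error(entrainment_spec(40, 0.5, -1), "locking_concentration")
  expect_error(trial_schedule(1, 10, duration = 300, n_trials = 28), "overflow")
  expect_error(sim_config(fs = 100), "twice the highest")
})

test_that("PAC component ground truth is recoverable downstream", {
  # kappa = 0: MI indistinguishable from its time-shift surrogate null
  x0 <- generate_pac_component(pac_spec(6, c(30, 70), 0), 60, fs,
                               base_rms = 0.5, seed = 3)
  null <- pac_surrogate_test(x0, c(4, 8), c(30, 70), n_surrogates = 100,
                             seed = 5, fs = fs)
  expect_false(null$significant)
  # monotone in coupling strength at fixed seed
  mi <- vapply(c(0.4, 0.8), function(k)
    tort_mi(generate_pac_component(pac_spec(6, c(30, 70), k), 60, fs, 0.5,
                                   seed = 11),
            c(4, 8), c(30, 70), fs = fs)$mi, 0)
  expect_gt(mi[2], mi[1])
  # kappa = 1 within 10% of the closed-form binning oracle
  x1 <- generate_pac_component(pac_spec(6, c(30, 70), 1), 60, fs, 0.5, seed = 11)
  r1 <- tort_mi(x1, c(4, 8), c(30, 70), n_bins = 18, fs = fs)
  expect_lt(abs(r1$mi - tort_oracle_mi(1, 18)) / tort_oracle_mi(1, 18), 0.10)
  expect_error(generate_pac_component(pac_spec(6, c(400, 600), 1), 10, fs),
               "Nyquist")
})

test_that("entrained trials respect the schedule and lock as configured", {
  sched <- trial_schedule(1, 10, duration = 300)
  expect_equal(sched$n_trials, 27)  # floor((300 - 0.5) / 11)
  g <- generate_entrained_trials(entrainment_spec(40, 0.5, 1e6), sched, fs,
                                 seed = 5)
  expect_length(g$events, 27)
  expect_equal(unique(round(diff(g$events), 9)), 11)
  # zero outside sonication windows
  mask <- rep(TRUE, length(g$samples))
  for (on in g$events) mask[(round(on * fs) + 1):(round((on + 1) * fs))] <- FALSE
  expect_true(all(g$samples[mask] == 0))
  expect_true(any(g$samples != 0))
  # near-perfect locking -> ITPC ~ 1 during sonication
  rec <- lfp_recording(g$samples, fs, g$events)
  s <- itpc(segment_trials(rec), 40)
  expect_gt(mean(s$itpc[s$times >= 0.1 & s$times <= 0.9]), 0.99)
})

test_that("live/dead pairs satisfy the construction identities", {
  cfg <- sim_config(duration = 40, fs = fs, seed = 9,
                    pac = pac_spec(6, c(30, 70), 0.5),
                    entrainment = entrainment_spec(40, 0.3, 5),
                    artifact = artifact_spec(40, 0.5),
                    schedule = trial_schedule(1, 10, duration = 40))
  pair <- simulate_recording_pair(cfg)
  parts <- simulate_components(cfg)
  # exact additivity and cancellation with sensor noise off
  expect_equal(max(abs(pair$live$samples - pair$dead$samples - parts$neural)), 0,
               tolerance = 1e-12)
  expect_identical(pair$live$events, pair$dead$events)
  expect_equal(parts$neural,
               parts$components$pink + parts$components$oscillators +
                 parts$components$pac + parts$components$evoked)
  # artifact off -> dead is flat
  cfg0 <- cfg; cfg0$artifact <- NULL
  expect_true(all(simulate_recording_pair(cfg0)$dead$samples == 0))
  # neural off -> live == dead
  cfgn <- sim_config(duration = 40, fs = fs, seed = 9, pink_rms = 0,
                     oscillators = list(), artifact = artifact_spec(40, 0.5),
                     schedule = trial_schedule(1, 10, duration = 40))
  pn <- simulate_recording_pair(cfgn)
  expect_identical(pn$live$samples, pn$dead$samples)
  # PRF mismatch warns but proceeds
  cfgw <- cfg; cfgw$artifact <- artifact_spec(35, 0.5)
  expect_warning(simulate_recording_pair(cfgw), "PRF")
})

test_that("cohort simulation is deterministic, labeled, and validated", {
  base <- sim_config(duration = 6, fs = fs, seed = 3,
                     schedule = trial_schedule(1, 4, duration = 6))
  groups <- list(list(label = "A", n_subjects = 2, multipliers = NULL),
                 list(label = "B", n_subjects = 2, multipliers = c(gamma = 0.5)),
                 list(label = "C", n_subjects = 2, multipliers = c(gamma = 0)))
  co <- simulate_cohort(groups, base)
  expect_length(co, 6)
  expect_identical(vapply(co, function(r) r$group, ""),
                   rep(c("A", "B", "C"), each = 2))
  expect_equal(co[[3]]$ground_truth$multipliers[["gamma"]], 0.5)
  expect_identical(lapply(co, `[[`, "samples"),
                   lapply(simulate_cohort(groups, base), `[[`, "samples"))
  # distinct subjects get distinct seeds/traces
  expect_false(identical(co[[1]]$samples, co[[2]]$samples))
  expect_error(simulate_cohort(c(groups, groups[1]), base), "duplicate")
  expect_error(simulate_cohort(list(list(label = "A", n_subjects = 1)), base),
               "n_subjects")
  expect_error(
    simulate_cohort(list(list(label = "A", n_subjects = 2,
                              multipliers = c(sigma = 1)),
                         list(label = "B", n_subjects = 2)), base),
    "unknown bands")
})

test_that("each oscillator concentrates >= 90% of its power in its band", {
  # 5-s Welch windows: resolution matched to the narrowest (3 Hz) band
  for (o in default_oscillators()) {
    x <- generate_oscillator(o, 60, fs, seed = 13)
    psd <- welch_psd(x, window_length = 5, fs = fs)
    sel <- psd$freqs >= o$center_freq - o$bandwidth / 2 &
      psd$freqs < o$center_freq + o$bandwidth / 2
    expect_gt(sum(psd$density[sel]) / sum(psd$density), 0.90)
  }
})
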