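fs <- 1000

test_that("trial segmentation is exact and drops (never pads) edge onsets", {
  sched <- trial_schedule(1, 10, duration = 300)
  g <- generate_entrained_trials(entrainment_spec(40, 0.5, 10), sched, fs,
                                 seed = 2)
  rec <- lfp_recording(g$samples, fs, g$events)
  tr <- segment_trials(rec, c(0.2, 1))
  expect_equal(dim(tr$trials), c(27, 1200))
  expect_equal(tr$n_dropped, 0)
  # onset too close to the start is dropped with a message
  rec0 <- lfp_recording(rnorm(5 * fs), fs, events = c(0, 2))
  expect_message(tr0 <- segment_trials(rec0, c(0.2, 1)), "dropped 1")
  expect_equal(nrow(tr0$trials), 1)
  # constant recording -> identical rows
  recc <- lfp_recording(rep(1, 5 * fs), fs, events = c(1, 2, 3))
  trc <- segment_trials(recc, c(0.2, 1))
  expect_equal(trc$trials[1, ], trc$trials[3, ])
  expect_error(segment_trials(lfp_recording(rnorm(fs), fs), c(0.2, 1)),
               "no stimulation events")
  expect_error(segment_trials(lfp_recording(rnorm(fs), fs, events = 0.1),
                              c(0.5, 1)), "every window overruns")
})

test_that("the Morlet TFR localizes tones and scales quadratically", {
  tt <- (0:1199) / fs
  trials <- make_trialset(t(replicate(5, sin(2 * pi * 40 * tt))), fs, pre = 0.2)
  tfr <- compute_tfr(trials, freqs = 5:100, keep_coefficients = FALSE)
  spec <- colMeans(tfr$power)
  expect_equal(tfr$freqs[which.max(spec)], 40)
  trials2 <- trials; trials2$trials <- 2 * trials$trials
  tfr2 <- compute_tfr(trials2, freqs = 5:100, keep_coefficients = FALSE)
  expect_equal(tfr2$power, 4 * tfr$power, tolerance = 1e-12)
  # white noise: roughly flat across frequencies with L2-normalized wavelets
  set.seed(6)
  wn <- make_trialset(matrix(rnorm(20 * 1200), 20), fs, pre = 0.2)
  spec_wn <- colMeans(compute_tfr(wn, freqs = 5:100,
                                  keep_coefficients = FALSE)$power)
  expect_lt(max(spec_wn) / min(spec_wn), 3)
  expect_error(compute_tfr(trials, freqs = c(0.5, 40)), "unresolvable")
  expect_error(compute_tfr(trials, freqs = c(40, 600)), "fs/2")
})

test_that("artifact TFR subtraction obeys its identities and floors at zero", {
  tt <- (0:1199) / fs
  set.seed(3)
  trials <- make_trialset(matrix(rnorm(5 * 1200), 5), fs, pre = 0.2)
  tfr <- compute_tfr(trials, freqs = 10:60, keep_coefficients = FALSE)
  zero <- subtract_artifact_tfr(tfr, tfr)
  expect_true(all(zero$power == 0))
  dead0 <- tfr; dead0$power[] <- 0
  expect_equal(subtract_artifact_tfr(tfr, dead0)$power, tfr$power)
  dead2 <- tfr; dead2$power <- 2 * tfr$power
  expect_true(all(subtract_artifact_tfr(tfr, dead2)$power == 0))
  mism <- compute_tfr(trials, freqs = 10:50, keep_coefficients = FALSE)
  expect_error(subtract_artifact_tfr(tfr, mism), "grids")
})

test_that("ITPC equals the resultant vector length with its symmetries", {
  # identical trials -> exactly 1 everywhere, regardless of content
  set.seed(9)
  one <- rnorm(600)
  same <- make_trialset(t(replicate(5, one)), fs)
  s1 <- itpc(same, 40)
  expect_equal(s1$itpc, rep(1, 600), tolerance = 1e-12)
  # two trials in exact antiphase -> ~ 0
  anti <- tone_trials(c(0, pi), 40, fs, 0.6)
  expect_lt(max(itpc(anti, 40)$itpc[100:500]), 0.02)
  # bounds on arbitrary random trials (property check)
  for (r in 1:10) {
    set.seed(r)
    ts <- make_trialset(matrix(rnorm(8 * 500), 8), fs)
    v <- itpc(ts, 40)$itpc
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
  }
  # invariant to trial order and to a common phase rotation
  ph <- c(0.3, 1.2, -2, 2.5)
  base <- itpc(tone_trials(ph, 40, fs, 0.6), 40)$itpc
  perm <- itpc(tone_trials(ph[c(3, 1, 4, 2)], 40, fs, 0.6), 40)$itpc
  rot <- itpc(tone_trials(ph + 0.9, 40, fs, 0.6), 40)$itpc
  expect_equal(perm, base, tolerance = 1e-9)
  expect_equal(rot[100:500], base[100:500], tolerance = 1e-6)
  expect_error(itpc(make_trialset(matrix(rnorm(500), 1), fs), 40),
               "at least 2 trials")
  expect_error(itpc(same, 40, bandwidth = 2000), "fs/2")
})

test_that("the entrainment report detects 40-Hz entrainment through the artifact", {
  cfg <- sim_config(duration = 150, fs = fs, seed = 12,
                    entrainment = entrainment_spec(40, 1, 50),
                    artifact = artifact_spec(40, 0.5),
                    schedule = trial_schedule(1, 10, duration = 150))
  pair <- simulate_recording_pair(cfg)
  rep <- entrainment_report(pair$live, pair$dead, prf = 40)
  expect_true(rep$peak_at_prf)
  expect_equal(rep$peak_freq, 40)
  expect_gt(rep$mean_itpc_sonication, 0.8)
  # no locking: ITPC falls to near the uniform-phase expectation
  cfg0 <- cfg
  cfg0$entrainment <- entrainment_spec(40, 1, 0)
  pair0 <- simulate_recording_pair(cfg0)
  rep0 <- entrainment_report(pair0$live, pair0$dead, prf = 40)
  N <- rep0$itpc$n_trials
  expect_lt(rep0$mean_itpc_sonication,
            expected_uniform_itpc(N) + 3 * sqrt((1 - pi / 4) / N))
  # mismatched events are rejected
  bad <- pair$dead; bad$events <- bad$events + 0.5
  expect_error(entrainment_report(pair$live, bad), "event times differ")
  # no events -> rejected
  live_noev <- pair$live; live_noev$events <- numeric(0)
  dead_noev <- pair$dead; dead_noev$events <- numeric(0)
  expect_error(entrainment_report(live_noev, dead_noev), "no stimulation events")
})
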