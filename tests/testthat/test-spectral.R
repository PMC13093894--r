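fs <- 1000
t20 <- (0:(20 * fs - 1)) / fs

test_that("Welch PSD recovers tone power and attributes it to the right band", {
  psd <- welch_psd(sin(2 * pi * 40 * t20), fs = fs)
  expect_equal(psd$df, 1)
  expect_lt(abs(sum(psd$density) * psd$df - 0.5) / 0.5, 0.02)  # A^2/2
  bp <- band_power(psd)
  expect_gt(bp$rel_power[bp$name == "gamma"], 0.95)
  # 10 Hz -> alpha dominates; 4 Hz exactly -> theta owns the shared edge
  bp10 <- band_power(welch_psd(sin(2 * pi * 10 * t20), fs = fs))
  expect_gt(bp10$rel_power[bp10$name == "alpha"], 0.95)
  # Hann leakage puts ~1/6 of an on-edge tone's power into each neighboring
  # bin; the 4-Hz grid point itself belongs to theta (half-open edges)
  bp4 <- band_power(welch_psd(sin(2 * pi * 4 * t20), fs = fs))
  expect_gt(bp4$rel_power[bp4$name == "theta"], 0.8)
  expect_lt(bp4$rel_power[bp4$name == "delta"], 0.2)
  expect_identical(bp4$name[which.max(bp4$rel_power)], "theta")
})

test_that("white noise gives a flat, variance-consistent density", {
  set.seed(2)
  x <- rnorm(60 * fs)
  psd <- welch_psd(x, fs = fs)
  expect_lt(abs(sum(psd$density) * psd$df - var(x)) / var(x), 0.05)
  sel <- psd$freqs >= 10 & psd$freqs <= 400
  expect_lt(max(abs(psd$density[sel] - 1 / (fs / 2))) / (1 / (fs / 2)), 0.4)
})

test_that("Welch matches a naive periodogram-averaging oracle on fixed noise", {
  oracle_bp <- function(x) {
    o <- naive_psd_oracle(x, fs, L = fs)
    band_power(structure(list(freqs = o$freqs, density = o$density,
                              df = o$df, fs = fs), class = "PsdEstimate"))
  }
  # white noise: bands with >= 4 bins agree within 10%; the 3-bin delta band
  # has ~sqrt(1/(3*60)) sampling error per estimator, so 20% there
  w <- generate_pink_noise(60, fs, exponent = 0, rms = 1, seed = 17)
  bw <- band_power(welch_psd(w, fs = fs)); bow <- oracle_bp(w)
  dev_w <- abs(bw$abs_power - bow$abs_power) / bow$abs_power
  expect_true(all(dev_w[bw$name != "delta"] < 0.10))
  expect_lt(dev_w[bw$name == "delta"], 0.20)
  # pink noise: theta and above agree within 10%; below ~4 Hz the boxcar
  # oracle's own leakage from sub-Hz power dominates (the expected
  # taper-choice bias), so delta is excluded from the comparison
  p <- generate_pink_noise(60, fs, exponent = 1, rms = 1, seed = 17)
  bp <- band_power(welch_psd(p, fs = fs)); bo <- oracle_bp(p)
  hi <- bp$name != "delta"
  expect_true(all(abs(bp$abs_power[hi] - bo$abs_power[hi]) /
                    bo$abs_power[hi] < 0.10))
})

test_that("band powers obey scaling, offset-invariance and the partition", {
  x <- generate_pink_noise(30, fs, 1, 1, seed = 23)
  bp <- band_power(welch_psd(x, fs = fs))
  # scaling by c multiplies absolute powers by c^2 exactly
  bp3 <- band_power(welch_psd(3 * x, fs = fs))
  expect_equal(bp3$abs_power, 9 * bp$abs_power, tolerance = 1e-12)
  expect_equal(bp3$rel_power, bp$rel_power, tolerance = 1e-12)
  # mean offset is removed by detrending
  bpo <- band_power(welch_psd(x + 5, fs = fs))
  expect_equal(bpo$abs_power, bp$abs_power, tolerance = 1e-9)
  # half-open bands partition [1, 70): sum == total to 1e-9 relative
  expect_lt(abs(sum(bp$abs_power) - attr(bp, "total_power")) /
              attr(bp, "total_power"), 1e-9)
  expect_equal(sum(bp$rel_power), 1, tolerance = 1e-9)
})

test_that("invalid spectral inputs are rejected with clear messages", {
  expect_error(welch_psd(rnorm(500), fs = fs), "too short")
  psd <- welch_psd(rnorm(4000), fs = fs)
  expect_error(band_power(psd, data.frame(name = "x", low = 400, high = 600)),
               "beyond the PSD support")
  expect_error(band_power(psd, data.frame(name = "x", low = 8, high = 4)),
               "low < high")
  expect_error(cohort_band_summary(list()), "no recordings")
})

test_that("cohort summaries aggregate correctly and preserve ground-truth order", {
  rec <- lfp_recording(generate_pink_noise(10, fs, 1, 1, seed = 2), fs,
                       label = "solo")
  cs <- cohort_band_summary(list(rec))
  bp <- band_power(welch_psd(rec))
  expect_equal(cs$subjects$abs_power, bp$abs_power)
  # identical recordings in one group -> zero dispersion
  rec2 <- rec; rec2$label <- "solo2"
  rec$group <- rec2$group <- "G"
  cs2 <- cohort_band_summary(list(rec, rec2))
  expect_true(all(cs2$summary$sd_abs == 0))
  # AD deficit in all bands, gamma-selective restoration in TUS
  base <- sim_config(duration = 20, fs = fs, seed = 5,
                     schedule = trial_schedule(1, 10, duration = 20))
  half <- c(delta = 0.5, theta = 0.5, alpha = 0.5, beta = 0.5, gamma = 0.5)
  co <- simulate_cohort(list(
    list(label = "WT", n_subjects = 2, multipliers = NULL),
    list(label = "AD", n_subjects = 2, multipliers = half),
    list(label = "TUS", n_subjects = 2,
         multipliers = replace(half, "gamma", 1))), base)
  sm <- cohort_band_summary(co)$summary
  gam <- setNames(sm$mean_abs[sm$name == "gamma"], sm$group[sm$name == "gamma"])
  the <- setNames(sm$mean_abs[sm$name == "theta"], sm$group[sm$name == "theta"])
  expect_gt(min(gam["WT"], gam["TUS"]), 1.5 * gam["AD"])    # gamma restored
  expect_lt(abs(gam["WT"] - gam["TUS"]) / gam["WT"], 0.25)  # WT ~ TUS in gamma
  expect_gt(the["WT"], 1.5 * max(the["AD"], the["TUS"]))    # theta not restored
})
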