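noiseless_avg <- function(depth, duration = 1, neural = 1, cm = 0) {
  stim <- fm_stimulus_spec(depth_hz = depth, duration_s = duration)
  resp <- simulate_fm_epochs(eeg_sim_spec(neural_gain = neural, cm_gain = cm,
                                          noise_sd = 0), stim, 1)
  rectified_average(resp)
}

test_that("rectified average: cancellation, 2F periodicity, single-epoch sum", {
  # microphonic-only input cancels exactly
  expect_equal(max(abs(noiseless_avg(10, 0.2, neural = 0, cm = 3))), 0)
  # rectified-only input is periodic at twice the carrier
  avg <- noiseless_avg(0, duration = 1)
  n <- length(avg)
  mag <- Mod(fft(as.numeric(avg)))[2:(n %/% 2)]
  expect_equal(which.max(mag) * 25000 / n, 1000)
  # one epoch per polarity: average equals the sample-wise sum
  stim <- fm_stimulus_spec(depth_hz = 5, duration_s = 0.1)
  resp <- simulate_fm_epochs(eeg_sim_spec(noise_sd = 0), stim, 1)
  expect_equal(as.numeric(rectified_average(resp)),
               resp$epochs_pos[1, ] + resp$epochs_neg[1, ])
})

test_that("heterodyne recovers the modulation depth within 2% of the oracle", {
  for (d in c(2, 5, 8, 10)) {
    avg <- noiseless_avg(d)
    h <- heterodyne(avg)
    expect_equal(h$depth_est_hz, d, tolerance = 0.02)
    # cross-check against finite-difference instantaneous frequency
    expect_equal(h$depth_est_hz, excursion_oracle(avg, 25000),
                 tolerance = 0.02)
  }
  # deepest condition recovered to 1%
  expect_equal(heterodyne(noiseless_avg(10))$depth_est_hz, 10,
               tolerance = 0.01)
})

test_that("heterodyne: pure tone gives ~0 phase modulation; scaling invariance", {
  avg0 <- noiseless_avg(0)
  expect_lt(heterodyne(avg0)$phase_amp_rad, 0.05)
  avg <- noiseless_avg(8)
  h1 <- heterodyne(avg)
  h2 <- heterodyne(waveform(2 * as.numeric(avg), 25000))
  expect_equal(h2$depth_est_hz, h1$depth_est_hz, tolerance = 1e-10)
  expect_error(heterodyne(waveform(rep(0, 25000), 25000)), "zero-energy")
})

test_that("heterodyne isolates the neural component from the microphonic", {
  # depth estimate invariant to microphonic gain, present only with neural gain
  ests <- vapply(c(0, 5, 50), function(cm)
    heterodyne(noiseless_avg(8, neural = 0.5, cm = cm))$depth_est_hz,
    numeric(1))
  expect_lt(diff(range(ests)) / mean(ests), 1e-6)
  expect_equal(ests[1], 8, tolerance = 0.02)
})

test_that("estimated phase amplitude is monotone in the generating depth", {
  amps <- vapply(c(2, 5, 8, 10), function(d)
    heterodyne(noiseless_avg(d))$phase_amp_rad, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("bootstrap: degenerate and seeded behavior", {
  stim <- fm_stimulus_spec(depth_hz = 8, duration_s = 0.5)
  clean <- simulate_fm_epochs(eeg_sim_spec(noise_sd = 0), stim, 12)
  b <- bootstrap_fmfr(clean, n_draw = 10, n_rep = 5, seed = 1)
  # noiseless: all subsamples identical, equals the single-pass result
  expect_equal(b$phase_amp_rad,
               heterodyne(rectified_average(clean))$phase_amp_rad,
               tolerance = 1e-12)
  noisy <- simulate_fm_epochs(eeg_sim_spec(noise_sd = 1, seed = 4), stim, 25)
  b1 <- bootstrap_fmfr(noisy, n_draw = 15, n_rep = 10, seed = 7)
  b2 <- bootstrap_fmfr(noisy, n_draw = 15, n_rep = 10, seed = 7)
  expect_identical(b1$phase_amp_rad, b2$phase_amp_rad)
  expect_error(bootstrap_fmfr(clean, n_draw = 100, n_rep = 2), "fewer epochs")
})

test_that("bootstrap repetition variance shrinks with recording noise", {
  stim <- fm_stimulus_spec(depth_hz = 8, duration_s = 0.5)
  sds <- vapply(c(0.3, 1.5), function(ns) {
    resp <- simulate_fm_epochs(eeg_sim_spec(noise_sd = ns, seed = 5), stim, 30)
    sd(bootstrap_fmfr(resp, n_draw = 15, n_rep = 30,
                      seed = 2)$rep_phase_amp_rad)
  }, numeric(1))
  expect_lt(sds[1], sds[2])
})

test_that("FMFR growth normalization preserves shape and rejects bad input", {
  amps <- c("2" = 0.5, "5" = 1.5, "8" = 2.4, "10" = 2.6)
  g <- fmfr_growth(amps, amp_at_depth0 = 2)
  expect_equal(g$x, c(2, 5, 8, 10))
  expect_equal(g$y, unname(amps) / 2)
  expect_true(all(diff(g$y) > 0))           # order preserved
  flat <- fmfr_growth(c("2" = 2, "5" = 2, "8" = 2, "10" = 2), 2)
  expect_equal(flat$y, rep(1, 4))
  expect_error(fmfr_growth(amps, 0), "denominator")
})

test_that("pure-tone 2F magnitude is positive for a rectified response", {
  stim <- fm_stimulus_spec(depth_hz = 0, duration_s = 0.2)
  resp <- simulate_fm_epochs(eeg_sim_spec(noise_sd = 0), stim, 1)
  expect_gt(pure_tone_locking(resp), 0.1)
})
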