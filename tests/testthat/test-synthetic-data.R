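test_that("FM epoch simulator separates linear and rectified components", {
  stim <- fm_stimulus_spec(depth_hz = 10, duration_s = 0.2)
  s <- as.numeric(make_fm_tone(stim))
  # pure linear (microphonic-like) component cancels in the polarity sum
  cm <- simulate_fm_epochs(eeg_sim_spec(neural_gain = 0, cm_gain = 2,
                                        noise_sd = 0), stim, 1)
  expect_equal(cm$epochs_pos[1, ] + cm$epochs_neg[1, ], rep(0, length(s)))
  # pure rectified component sums to gain * |s|
  ne <- simulate_fm_epochs(eeg_sim_spec(neural_gain = 1.5, cm_gain = 0,
                                        noise_sd = 0), stim, 1)
  expect_equal(ne$epochs_pos[1, ] + ne$epochs_neg[1, ], 1.5 * abs(s))
})

test_that("FM epoch simulator dimensions and determinism", {
  stim <- fm_stimulus_spec(depth_hz = 5, duration_s = 0.05)
  eeg <- eeg_sim_spec(noise_sd = 1, seed = 11)
  r1 <- simulate_fm_epochs(eeg, stim, 200)
  expect_equal(nrow(r1$epochs_pos), 200)
  expect_equal(nrow(r1$epochs_neg), 200)
  expect_equal(ncol(r1$epochs_pos), round(0.05 * 25000))
  r2 <- simulate_fm_epochs(eeg, stim, 200)
  expect_identical(r1$epochs_pos, r2$epochs_pos)
  expect_equal(r1$ground_truth$depth_hz, 5)
})

test_that("IPD recording: no binaural component without an interaural difference", {
  eeg <- eeg_sim_spec(neural_gain = 1, noise_sd = 0)
  dur <- 2 / 6.8 * 20
  for (spec in list(ipd_stimulus_spec(per_ear_shift_deg = 0, duration_s = dur),
                    ipd_stimulus_spec(per_ear_shift_deg = 90, duration_s = dur,
                                      control_mode = "same_polarity"))) {
    rec <- simulate_ipd_recording(eeg, spec, binaural_gain = 1)
    sa <- spectral_amplitudes(epoch_and_average(rec, n_epochs = 20))
    expect_lt(sa$ipdfr_amp, 1e-4)
    expect_equal(rec$ground_truth$sensitivity, 0)
  }
})

test_that("IPD recording: EFR constant across shifts while IPDFR grows", {
  eeg <- eeg_sim_spec(neural_gain = 1, noise_sd = 0)
  dur <- 2 / 6.8 * 20
  shifts <- c(0, 22.5, 45, 90)
  res <- lapply(shifts, function(s) {
    rec <- simulate_ipd_recording(
      eeg, ipd_stimulus_spec(per_ear_shift_deg = s, duration_s = dur), 1)
    spectral_amplitudes(epoch_and_average(rec, n_epochs = 20))
  })
  efr <- vapply(res, function(r) r$efr_amp, numeric(1))
  ipd <- vapply(res, function(r) r$ipdfr_amp, numeric(1))
  expect_lt(diff(range(efr)) / mean(efr), 1e-5)
  expect_true(all(diff(ipd) > 0))
})

test_that("observer: anchored at 70.71%, saturates, and replays under a seed", {
  obs <- observer_spec(true_threshold = 10, slope = 4, guess_rate = 0.5)
  expect_equal(observer_p_correct(obs, 10), sqrt(0.5))
  expect_equal(observer_p_correct(obs, 1e9), 1, tolerance = 1e-6)
  expect_equal(observer_p_correct(obs, 1e-9), 0.5, tolerance = 1e-6)
  obs2 <- observer_spec(3, slope = 1, guess_rate = digits_guess_rate(),
                        lapse_rate = 0.05, scale = "linear")
  expect_equal(observer_p_correct(obs2, 3), sqrt(0.5))
  expect_equal(observer_p_correct(obs2, 100), 0.95, tolerance = 1e-6)
  set.seed(42); a <- simulate_observer_response(obs, rep(10, 50))
  set.seed(42); b <- simulate_observer_response(obs, rep(10, 50))
  expect_identical(a, b)
})

test_that("pupil session: silent generator yields zero fractional change", {
  ses <- simulate_pupil_session(snr_schedule = c(9, 6, 3, 0),
                                trials_per_block = 2, effort_gain = 0,
                                blink_rate = 0, spike_rate = 0, noise_sd = 0,
                                drift_amp_mm = 0, seed = 1)
  fc <- fractional_change(ses)
  expect_equal(fc$peak_frac, rep(0, 4), tolerance = 1e-12)
  expect_equal(ses$ground_truth$peak_frac, rep(0, 4))
})

test_that("pupil session: 30 Hz sampling, monotone ground truth, determinism", {
  ses <- simulate_pupil_session(snr_schedule = c(9, 6, 3, 0), seed = 3)
  expect_equal(ses$sample_rate_hz, 30)
  expect_equal(diff(ses$trace$time[1:2]), 1 / 30)
  # harder SNR -> larger generating peak
  expect_true(all(diff(ses$ground_truth$peak_frac) > 0))
  ses2 <- simulate_pupil_session(snr_schedule = c(9, 6, 3, 0), seed = 3)
  expect_identical(ses$trace$diameter, ses2$trace$diameter)
})

test_that("ABR simulator: construction read-back on the noiseless average", {
  amps <- c(0.3, 0.15, 0.35, 0.2, 0.4)
  resp <- simulate_abr(wave_amplitudes = amps, noise_sd = 0,
                       n_per_polarity = 2, seed = 1)
  avg <- abr_average(resp)
  pk <- pick_wave1(avg)
  expect_equal(pk$wave1_amp, amps[1], tolerance = 0.02)
  expect_equal(pk$peak_latency_ms, 1.6, tolerance = 0.1)
  expect_error(simulate_abr(wave_latencies_ms = c(2, 1.5, 3, 4, 5)))
})

test_that("ABR simulator: default epoch count and polarity artifact cancellation", {
  resp <- simulate_abr(noise_sd = 0, artifact_gain = 10, seed = 1)
  expect_equal(nrow(resp$epochs_pos), 1000)
  expect_equal(nrow(resp$epochs_neg), 1000)
  # huge polarity-flipping artifact must not move the two-polarity average
  clean <- simulate_abr(noise_sd = 0, artifact_gain = 0, n_per_polarity = 1)
  expect_equal(as.numeric(abr_average(resp)),
               as.numeric(abr_average(clean)), tolerance = 1e-12)
})

test_that("cohort simulator: determinism, calibration targets, validation", {
  co1 <- simulate_cohort(cohort_spec(seed = 9))
  co2 <- simulate_cohort(cohort_spec(seed = 9))
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 23)
  R <- attr(co1, "population_r")
  expect_equal(R["fm_thr", "speech_thr"], 0.85, tolerance = 0.005)
  expect_equal(R["fmfr_slope", "speech_thr"], 0.49, tolerance = 0.005)
  expect_equal(R["pupil_slope", "speech_thr"], 0.53, tolerance = 0.005)
  # physiological markers mutually uncorrelated in the population
  mk <- c("fmfr_slope", "ipdfr_slope", "pupil_slope", "abr_w1")
  off <- R[mk, mk][upper.tri(diag(4))]
  expect_true(all(abs(off) < 1e-12))
  bad <- default_cohort_loadings(); bad["fmfr_slope", ] <- c(1.2, 0, 0)
  expect_error(cohort_spec(loadings = bad), "invalid spec")
})

test_that("cohort simulator: zero loadings give uncorrelated samples", {
  zero <- default_cohort_loadings() * 0
  rs <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_spec(n_subjects = 23, loadings = zero,
                                      outcome_loadings = c(0, 0, 0),
                                      seed = s))
    cor(co$fm_thr, co$speech_thr)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(23 * 40))
})
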