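test_that("staircase stepping follows the 2-down-1-up rule with factor schedule", {
  cfg <- staircase_config("fm")                     # start 75, factors 1.5/1.2
  st <- staircase_init(cfg)
  st <- staircase_step(st, TRUE)
  expect_equal(st$level, 75)                        # one correct: no move yet
  st <- staircase_step(st, TRUE)
  expect_equal(st$level, 50)                        # 75 / 1.5
  st <- staircase_step(st, FALSE)                   # up: first reversal
  expect_equal(st$level, 75)
  expect_equal(st$reversals, 50)
  # drive to the coarse/fine regime switch: after the 5th reversal the
  # next move uses 1.2
  responses <- c(TRUE, TRUE, FALSE,                 # reversals 2, 3
                 TRUE, TRUE, FALSE)                 # reversals 4, 5
  for (r in responses) st <- staircase_step(st, r)
  expect_equal(length(st$reversals), 5)
  lvl <- st$level
  st <- staircase_step(st, FALSE)                   # 6th reversal: fine factor
  expect_equal(st$level, lvl * 1.2)
})

test_that("run value is the geometric mean of the last six reversal levels", {
  obs <- observer_spec(true_threshold = 10, slope = 4, guess_rate = 0.5)
  tr <- run_staircase(staircase_config("fm"), obs, seed = 3)
  expect_equal(length(tr$reversals), 12)            # 5 coarse + 7 fine
  expect_equal(tr$run_value, exp(mean(log(tail(tr$reversals, 6)))))
  # hand-checked geometric mean
  expect_equal(exp(mean(log(c(4, 1, 4, 1, 4, 1)))), 2)
})

test_that("deterministic observer brackets its step-limited threshold", {
  # correct iff level >= 10: equilibrium within one fine step of 10
  obs <- observer_spec(true_threshold = 10, slope = 200, guess_rate = 0)
  for (s in 1:5) {
    rv <- run_staircase(staircase_config("fm"), obs, seed = s)$run_value
    expect_gte(rv, 10 / 1.2)
    expect_lte(rv, 10 * 1.2)
  }
})

test_that("staircase converges near the 70.7% point of the psychometric", {
  obs <- observer_spec(true_threshold = 10, slope = 4, guess_rate = 0.5)
  pc <- vapply(1:150, function(s)
    observer_p_correct(obs, run_staircase(staircase_config("fm"), obs,
                                          seed = s)$run_value),
    numeric(1))
  expect_equal(mean(pc), sqrt(0.5), tolerance = 0.04)
  # multiplicative updates never drive the level non-positive
  tr <- run_staircase(staircase_config("ipd"), obs, seed = 1)
  expect_true(all(tr$trials$level > 0))
})

test_that("run collection: CV stopping rule, run cap, and median threshold", {
  # near-deterministic observer: three tight runs stop immediately
  obs <- observer_spec(true_threshold = 10, slope = 200, guess_rate = 0)
  rs <- collect_runs(staircase_config("fm"), obs, seed = 1)
  expect_equal(rs$n_runs, 3)
  expect_lte(rs$cv, 0.2)
  expect_equal(rs$threshold, median(rs$run_values))
  # erratic observer keeps CV high: capped at six runs
  noisy <- observer_spec(true_threshold = 10, slope = 0.4, guess_rate = 0.5)
  rs2 <- collect_runs(staircase_config("fm"), noisy, seed = 5)
  if (rs2$cv > 0.2) expect_equal(rs2$n_runs, 6)
  expect_equal(rs2$threshold, median(rs2$run_values))
})

test_that("speech protocol arithmetic: trial and SNR bookkeeping", {
  obs <- observer_spec(3, slope = 0.8, guess_rate = digits_guess_rate(),
                       scale = "linear")
  ses <- run_speech_session(speech_protocol(), obs, seed = 2)
  test_stage <- ses[ses$stage == "test", ]
  expect_equal(nrow(test_stage), 320)               # 40 blocks x 8 trials
  scored <- test_stage[test_stage$role == "test", ]
  expect_equal(nrow(scored), 200)
  counts <- table(scored$snr_db)
  expect_equal(unname(counts[as.character(c(0, 3, 6, 9))]),
               rep(50L, 4), ignore_attr = TRUE)
  # each SNR appears in exactly 10 test blocks
  blocks_per_snr <- table(unique(scored[c("block", "snr_db")])$snr_db)
  expect_true(all(blocks_per_snr == 10))
  expect_equal(sum(test_stage$role == "refresher"), 120)
})

test_that("speech threshold: recovery, clamping, and above-range flag", {
  prot <- speech_protocol()
  obs <- observer_spec(3, slope = 0.8, guess_rate = digits_guess_rate(),
                       scale = "linear")
  srts <- vapply(1:5, function(s)
    speech_threshold(run_speech_session(prot, obs, seed = s))$srt_db,
    numeric(1))
  expect_equal(mean(srts), 3, tolerance = 0.5 / 3)  # +-0.5 dB
  # ceiling observer: fitted crossing below 0 dB is marked 0
  ceiling_obs <- observer_spec(-30, slope = 0.8,
                               guess_rate = digits_guess_rate(),
                               scale = "linear")
  res0 <- speech_threshold(run_speech_session(prot, ceiling_obs, seed = 1))
  expect_equal(res0$srt_db, 0)
  expect_false(res0$above_range)
  # chance observer: no crossing within range
  chance_obs <- observer_spec(100, slope = 0.8,
                              guess_rate = digits_guess_rate(),
                              scale = "linear")
  resc <- speech_threshold(run_speech_session(prot, chance_obs, seed = 1))
  expect_true(resc$above_range)
  expect_true(is.na(resc$srt_db))
})

test_that("speech threshold estimator is shift-equivariant", {
  prot <- speech_protocol()
  est <- function(thr) mean(vapply(1:4, function(s)
    speech_threshold(run_speech_session(
      prot, observer_spec(thr, slope = 0.8, guess_rate = digits_guess_rate(),
                          scale = "linear"), seed = s))$srt_db, numeric(1)))
  expect_equal(est(6) - est(3), 3, tolerance = 0.25)
})

test_that("perfect observers score 100% at every SNR", {
  prot <- speech_protocol(n_blocks = 8)
  obs <- observer_spec(-50, slope = 5, guess_rate = digits_guess_rate(),
                       scale = "linear")
  ses <- run_speech_session(prot, obs, seed = 1)
  expect_true(all(ses$correct[ses$stage == "test"]))
})
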