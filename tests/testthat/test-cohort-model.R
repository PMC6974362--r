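test_that("Pearson matrix: exact, antisymmetric, and degenerate cases", {
  d <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6))
  pm <- pearson_matrix(d)
  expect_equal(pm$r["x", "y"], 1)
  d2 <- data.frame(x = c(1, 2, 3, 1.5), y = -c(1, 2, 3, 1.5))
  expect_equal(pearson_matrix(d2)$r["x", "y"], -1)
  set.seed(2)
  d3 <- data.frame(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(pearson_matrix(d3)$r["a", "b"]), 0.1)
  d4 <- data.frame(x = rnorm(10), z = rep(1, 10))
  expect_true(is.na(pearson_matrix(d4)$r["x", "z"]))   # undefined-r flag
  expect_error(pearson_matrix(data.frame(x = c(1, 2), y = c(1, 2))),
               "fewer than 3")
})

test_that("adjusted R2: identities, hand arithmetic, and guards", {
  expect_equal(adjusted_r2(0.37, 20, 0), 0.37)          # p = 0: unchanged
  expect_equal(adjusted_r2(1, 15, 3), 1)
  expect_equal(adjusted_r2(0.5, 15, 2), 1 - 0.5 * 14 / 12)
  expect_equal(adjusted_r2(0.5, 15, 2), 0.41667, tolerance = 1e-4)
  expect_error(adjusted_r2(0.5, 4, 3), "exceed")
  # always <= R2, equality only at p = 0 or R2 = 1
  expect_lt(adjusted_r2(0.5, 15, 2), 0.5)
})

test_that("OLS R2 matches the normal-equations oracle to 1e-10", {
  set.seed(17)
  for (i in 1:5) {
    d <- data.frame(y = rnorm(12), a = rnorm(12), b = rnorm(12), c = rnorm(12))
    fm <- forward_model(d, "y", c("a", "b", "c"))
    top3 <- fm$predictor[1:3]
    expect_equal(fm$r2[3], ols_r2_oracle(d[top3], d$y), tolerance = 1e-10)
    expect_equal(fm$r2[1], ols_r2_oracle(d[fm$predictor[1]], d$y),
                 tolerance = 1e-10)
    expect_true(all(fm$adj_r2 <= fm$r2 + 1e-12))
    # single-predictor step consistent with adjusted_r2()
    expect_equal(fm$adj_r2[1], adjusted_r2(fm$r2[1], nrow(d), 1))
  }
})

test_that("forward selection ranks pupil first on the default cohort", {
  co <- simulate_cohort(cohort_spec(n_subjects = 400, seed = 12))
  fm <- forward_model(co, "speech_thr",
                      c("fmfr_slope", "ipdfr_slope", "pupil_slope",
                        "abr_w1", "ehf_thr"))
  expect_equal(fm$predictor[1], "pupil_slope")
  expect_equal(fm$predictor[2], "fmfr_slope")
  expect_true(all(diff(fm$r2) >= -1e-12))               # R2 never decreases
})

test_that("a pure-noise predictor typically lowers adjusted R2", {
  # adjusted R2 drops whenever the added predictor's partial F < 1, which a
  # pure-noise regressor satisfies ~2/3 of the time (median F(1, n-3) < 1);
  # the raw R2, by contrast, never decreases
  set.seed(5)
  deltas <- vapply(1:50, function(i) {
    n <- 15
    d <- data.frame(y = rnorm(n), x = rnorm(n), junk = rnorm(n))
    d$y <- d$y + d$x
    r2_1 <- summary(lm(y ~ x, d))$r.squared
    r2_2 <- summary(lm(y ~ x + junk, d))$r.squared
    expect_gte(r2_2, r2_1)
    adjusted_r2(r2_2, n, 2) - adjusted_r2(r2_1, n, 1)
  }, numeric(1))
  expect_lt(median(deltas), 0)
  expect_gt(mean(deltas < 0), 0.5)
})

test_that("pairwise models: symmetry, collinearity error, best pair", {
  co <- simulate_cohort(cohort_spec(n_subjects = 400, seed = 3))
  pw <- pairwise_models(co, "speech_thr",
                        c("fmfr_slope", "pupil_slope", "abr_w1"))
  # unordered pairs: one row per combination, order of listing irrelevant
  expect_equal(nrow(pw), 3)
  key <- apply(pw[, c("var1", "var2")], 1, function(r)
    paste(sort(r), collapse = "+"))
  expect_equal(anyDuplicated(key), 0)
  best <- pw[1, ]
  expect_setequal(c(best$var1, best$var2), c("fmfr_slope", "pupil_slope"))
  co$copy <- co$fmfr_slope
  expect_error(pairwise_models(co, "speech_thr", c("fmfr_slope", "copy")),
               "singular")
})

test_that("complete-case handling drops rows with missing markers", {
  co <- simulate_cohort(cohort_spec(n_subjects = 30, seed = 4))
  co$pupil_slope[1:7] <- NA                   # unusable pupil subjects
  fm <- forward_model(co, "speech_thr", c("fmfr_slope", "pupil_slope"))
  expect_equal(unique(fm$n), 23)
})

test_that("marker-outcome correlations are recovered across seeded cohorts", {
  # mean Fisher z over cohorts vs analytic expectation atanh(rho) + rho/(2(n-1))
  n <- 23; n_coh <- 60
  z <- matrix(NA_real_, n_coh, 3)
  for (s in seq_len(n_coh)) {
    co <- simulate_cohort(cohort_spec(n_subjects = n, seed = 1000 + s))
    z[s, ] <- atanh(c(cor(co$fm_thr, co$speech_thr),
                      cor(co$fmfr_slope, co$speech_thr),
                      cor(co$pupil_slope, co$speech_thr)))
  }
  rho <- c(0.85, 0.49, 0.53)
  expected <- atanh(rho) + rho / (2 * (n - 1))
  se <- 1 / sqrt((n - 3) * n_coh)
  expect_true(all(abs(colMeans(z) - expected) < 3 * se))
})
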