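test_that("a curve fitted between a sample and itself is the identity", {
  set.seed(41)
  x <- rnorm(2000, 70, 12)
  cv <- fit_bias_curve(x, x, variable = "weight")
  expect_lt(max(abs(predict_bias(cv, seq(0.01, 0.99, 0.01)))), 1e-6)
  expect_equal(apply_bias_correction(x, cv), x, tolerance = 1e-6)
})

test_that("a pure +2 kg shift is recovered at every quantile", {
  set.seed(42)
  sr <- rnorm(3000, 68, 11)
  cv <- fit_bias_curve(sr, sr + 2.0, variable = "weight")
  expect_lt(max(abs(predict_bias(cv, seq(0.05, 0.95, 0.05)) - 2.0)), 0.05)
  expect_equal(apply_bias_correction(70, cv), 72, tolerance = 0.05)
  corrected <- apply_bias_correction(sr, cv)
  expect_equal(mean(corrected) - mean(sr), 2.0, tolerance = 0.02)
})

test_that("a multiplicative bias gives a monotone increasing curve", {
  set.seed(43)
  sr <- rnorm(3000, 70, 10)
  cv <- fit_bias_curve(sr, 1.05 * sr, variable = "weight")
  b <- predict_bias(cv, seq(0.05, 0.95, 0.05))
  expect_true(all(diff(b) > 0))
})

test_that("corrected deciles match the measured sample's deciles", {
  set.seed(44)
  true_w <- rlnorm(10000, log(72), 0.2)
  sr <- true_w - (1.5 + 0.03 * (true_w - 65)) + rnorm(10000, 0, 1)
  meas <- rlnorm(10000, log(72), 0.2)
  cv <- fit_bias_curve(sr, meas, variable = "weight")
  corrected <- apply_bias_correction(sr, cv)
  dq <- quantile(corrected, seq(0.1, 0.9, 0.1)) -
    quantile(meas, seq(0.1, 0.9, 0.1))
  expect_lt(max(abs(dq)), 0.6)
})

test_that("sample-size floor and BMI arithmetic are enforced", {
  expect_error(fit_bias_curve(rnorm(10), rnorm(100), variable = "weight"),
               "at least 30")
  d <- data.frame(corrected_weight = 90, corrected_height = 1.70,
                  survey_weight = 1)
  expect_equal(obesity_prevalence(d)$prevalence, 1)  # BMI 31.1
  d2 <- data.frame(corrected_weight = 80, corrected_height = 1.70,
                   survey_weight = 1)
  expect_equal(obesity_prevalence(d2)$prevalence, 0)
  d3 <- data.frame(corrected_weight = 80, corrected_height = 0,
                   survey_weight = 1)
  expect_error(obesity_prevalence(d3), "height")
})

test_that("all-lean cohort has prevalence 0 with degenerate CI", {
  d <- data.frame(corrected_weight = rep(60, 50),
                  corrected_height = rep(1.7, 50),
                  survey_weight = 1)
  p <- obesity_prevalence(d, n_boot = 50L, seed = 1)
  expect_equal(p$prevalence, 0)
  expect_equal(p$ci, c(0, 0))
})

test_that("correcting under-reported weight raises obesity prevalence", {
  icfg <- small_individual_config(6000L)
  ind <- generate_individuals(icfg, seed = 7)
  ref <- generate_individuals(icfg, seed = 8)
  ind <- correct_anthropometry(ind, ref)
  p_sr <- obesity_prevalence(ind, use_corrected = FALSE)$prevalence
  p_c <- obesity_prevalence(ind, use_corrected = TRUE)$prevalence
  expect_gt(p_c, p_sr)
  # corrected prevalence near the calibrated 25.2%
  expect_lt(abs(p_c - 0.252), 0.03)
})
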