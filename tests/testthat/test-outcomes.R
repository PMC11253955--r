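make_prev_fixture <- function(n = 1500L, dkcal = -20, seed = 19L) {
  coh <- make_cohort(n, seed = seed)
  ref <- make_cohort(n, seed = seed + 1L)
  coh <- correct_anthropometry(coh, ref)
  st <- initialize_state(coh$sex, coh$age, coh$corrected_weight,
                         coh$corrected_height)
  tr <- simulate_population(st, dkcal)
  list(coh = coh, tr = tr)
}

test_that("zero caloric change gives a flat prevalence series", {
  fx <- make_prev_fixture(400L, dkcal = 0)
  ps <- prevalence_series(fx$tr, fx$coh)
  expect_equal(ps$absolute_change_pp, rep(0, 10), tolerance = 1e-9)
  expect_equal(ps$baseline_prevalence, ps$scenario_prevalence,
               tolerance = 1e-9)
})

test_that("prevalence identities and bounds hold", {
  fx <- make_prev_fixture()
  ps <- prevalence_series(fx$tr, fx$coh)
  expect_true(all(ps$baseline_prevalence >= 0 & ps$baseline_prevalence <= 1))
  expect_true(all(ps$scenario_prevalence >= 0 & ps$scenario_prevalence <= 1))
  expect_equal(ps$relative_change_pct,
               ps$absolute_change_pp / (100 * ps$baseline_prevalence) * 100,
               tolerance = 1e-12)
  # a sustained deficit cannot raise prevalence
  expect_true(all(ps$absolute_change_pp <= 0))
})

test_that("cases averted multiply prevalence reduction by the projection", {
  ps <- structure(data.frame(year = 1:3,
                             baseline_prevalence = 0.25,
                             scenario_prevalence = 0.24,
                             absolute_change_pp = -1,
                             relative_change_pct = -4),
                  class = c("prevalence_series", "data.frame"))
  proj <- generate_projection(100e6, 2021:2023, growth = 0)
  ca <- cases_averted(ps, proj)
  expect_equal(ca$cases_averted, rep(1e6, 3))
  expect_equal(ca$cumulative_cases_averted, cumsum(rep(1e6, 3)))
  ps0 <- ps; ps0$absolute_change_pp <- 0
  expect_equal(cases_averted(ps0, proj)$cases_averted, rep(0, 3))
  expect_error(cases_averted(ps, proj[1:2, ]), "years")
})

test_that("a larger tax averts at least as many cases every year", {
  fx20 <- make_prev_fixture(1200L, dkcal = -17.3, seed = 23L)
  st <- initialize_state(fx20$coh$sex, fx20$coh$age,
                         fx20$coh$corrected_weight, fx20$coh$corrected_height)
  tr30 <- simulate_population(st, -25.9)
  ps20 <- prevalence_series(fx20$tr, fx20$coh)
  ps30 <- prevalence_series(tr30, fx20$coh)
  proj <- generate_projection(147.9e6, 2021:2030)
  ca20 <- cases_averted(ps20, proj)
  ca30 <- cases_averted(ps30, proj)
  expect_true(all(ca30$cases_averted >= ca20$cases_averted - 1e-9))
  expect_true(all(ca20$cases_averted >= 0))
})

test_that("bootstrap uncertainty is seeded, centred and shrinks with n", {
  coh <- make_cohort(1600L, seed = 29L)
  stat <- function(d) sum(d$survey_weight * d$kcal_ssb) / sum(d$survey_weight)
  b1 <- bootstrap_uncertainty(coh, stat, n_reps = 120L, seed = 3)
  b2 <- bootstrap_uncertainty(coh, stat, n_reps = 120L, seed = 3)
  expect_identical(b1$reps, b2$reps)
  expect_true(b1$ci[1, 1] <= b1$point && b1$point <= b1$ci[2, 1])
  small <- coh[1:400, ]
  bs <- bootstrap_uncertainty(small, stat, n_reps = 120L, seed = 3)
  ratio <- diff(bs$ci[, 1]) / diff(b1$ci[, 1])
  # quartering n should roughly double the CI width (~1/sqrt(n))
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 3.0)
})
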