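test_that("household generation is deterministic under a fixed seed", {
  cfg <- small_household_config(500L)
  a <- generate_households(cfg, seed = 5)
  b <- generate_households(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_households(cfg, seed = 6)
  expect_false(identical(a, c))
})

test_that("zero-purchase thinning and weight rescaling behave as configured", {
  zp <- stats::setNames(rep(0, 11), all_categories())
  cfg <- small_household_config(800L, zero_purchase_prob = zp)
  hh <- generate_households(cfg, seed = 1)
  for (cc in all_categories()) {
    expect_true(all(hh[[paste0("qty_", cc)]] > 0), info = cc)
  }
  # default thinning produces roughly the configured zero shares
  hh2 <- generate_households(small_household_config(5000L), seed = 2)
  z <- mean(hh2$qty_ssb == 0)
  expect_lt(abs(z - (1 - 18876 / 57920)), 0.03)
  # weights sum to the represented-household total (within 0.1%)
  expect_lt(abs(sum(hh2$survey_weight) - 59783430) / 59783430, 0.001)
  expect_true(all(hh2$survey_weight > 0))
})

test_that("expenditure and quantity are zero together", {
  hh <- generate_households(small_household_config(1000L), seed = 3)
  for (cc in beverage_categories()) {
    q <- hh[[paste0("qty_", cc)]]
    e <- hh[[paste0("exp_", cc)]]
    expect_identical(q == 0, e == 0, info = cc)
  }
})

test_that("invalid generator configuration names the offending field", {
  expect_error(synthetic_household_config(n_households = 0),
               "n_households")
  expect_error(synthetic_household_config(own_elasticity = c(-1, NA, -1)),
               "own_elasticity")
  zp <- stats::setNames(rep(1.2, 11), all_categories())
  expect_error(synthetic_household_config(zero_purchase_prob = zp),
               "zero_purchase_prob")
  expect_error(synthetic_individual_config(ssb_kcal_mean = -5), "intake")
})

test_that("individual generation hits configured group intake means", {
  ind <- generate_individuals(small_individual_config(20000L), seed = 4)
  expect_true(all(ind$age >= 20))
  m <- stratified_means(ind, "kcal_ssb", "income_tertile", n_boot = 0L)
  expect_equal(m$mean, c(53.5, 74.0, 86.7), tolerance = 0.08)
  msex <- stratified_means(ind, "kcal_ssb", "sex", n_boot = 0L)
  expect_equal(msex$mean, c(65.1, 79.5), tolerance = 0.08)
  expect_lt(abs(sum(ind$survey_weight) - 147852423) / 147852423, 0.001)
})

test_that("zero bias model makes self-report equal truth; n = 1 works", {
  cfg <- small_individual_config(
    500L,
    weight_bias = list(female = c(0, 0), male = c(0, 0)),
    height_bias = c(female = 0, male = 0),
    report_noise = c(weight = 0, height = 0))
  ind <- generate_individuals(cfg, seed = 9)
  expect_equal(ind$self_reported_weight, ind$weight)
  expect_equal(ind$self_reported_height, ind$height)

  one <- generate_individuals(small_individual_config(1L), seed = 1)
  expect_identical(nrow(one), 1L)
  expect_true(one$height > 0 && one$weight > 0 && one$kcal_ssb >= 0)
})

test_that("population projection follows the stated growth law", {
  p0 <- generate_projection(147.9e6, 2021:2030, growth = 0)
  expect_equal(p0$adults, rep(147.9e6, 10))
  p1 <- generate_projection(100, 2021:2022, growth = 0.01)
  expect_equal(p1$adults[2], 1.01 * p1$adults[1])
  pm <- generate_projection(100, 2021:2026, growth = -0.02)
  expect_true(all(diff(pm$adults) < 0))
  expect_error(generate_projection(0, 2021:2025), "start")
  expect_error(generate_projection(100, integer(0)), "years")
})
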