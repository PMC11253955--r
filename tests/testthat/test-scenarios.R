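test_that("SSB caloric change follows baseline x rate x pass-through x elasticity", {
  s20 <- tax_scenario(0.20)
  expect_equal(ssb_caloric_change(53.5, -1.241, s20), -13.2787, tolerance = 1e-6)
  expect_equal(ssb_caloric_change(86.7, -1.126, s20), -19.52484, tolerance = 1e-8)
  expect_equal(ssb_caloric_change(100, -1, tax_scenario(0.2, pass_through = 0.5)),
               -10)
  expect_equal(ssb_caloric_change(0, -1.2, s20), 0)
  # truncation: post-tax intake never negative
  expect_equal(ssb_caloric_change(10, -10, tax_scenario(0.9)), -10)
  expect_error(tax_scenario(0), "rate")
  expect_error(tax_scenario(0.2, pass_through = 2), "pass_through")
})

test_that("linearity: the 30% change is exactly 1.5x the 20% change", {
  ind <- generate_individuals(small_individual_config(400L), seed = 3)
  em <- reference_elasticity_matrix()
  d20 <- individual_caloric_change(ind, em, tax_scenario(0.20, include_substitution = TRUE))
  d30 <- individual_caloric_change(ind, em, tax_scenario(0.30, include_substitution = TRUE))
  expect_equal(d30, 1.5 * d20, tolerance = 1e-12)
})

test_that("substitution sums per-category cross effects and respects zero calories", {
  s20 <- tax_scenario(0.20, include_substitution = TRUE)
  expect_equal(substitution_caloric_change(
    c(alcoholic = 20), c(alcoholic = -0.122), s20), -0.488)
  expect_equal(substitution_caloric_change(
    c(alcoholic = 20, unsweetened = 10),
    c(alcoholic = 0, unsweetened = 0), s20), 0)
  # zero-kcal beverage contributes nothing whatever its elasticity
  expect_equal(substitution_caloric_change(
    c(lightdiet = 0), c(lightdiet = 5), s20), 0)
  expect_error(substitution_caloric_change(
    c(alcoholic = 20), c(unsweetened = 0.1), s20), "mismatch")
})

test_that("caloric reduction is monotone in rate and baseline intake", {
  rates <- c(0.1, 0.2, 0.3, 0.4)
  red <- vapply(rates, function(r) {
    -ssb_caloric_change(70, -1.2, tax_scenario(r))
  }, numeric(1))
  expect_true(all(diff(red) > 0))
  base <- c(10, 40, 70, 100)
  red2 <- -ssb_caloric_change(base, -1.2, tax_scenario(0.2))
  expect_true(all(diff(red2) > 0))
})

test_that("population caloric table is invariant to weight rescaling", {
  ind <- generate_individuals(small_individual_config(500L), seed = 5)
  em <- reference_elasticity_matrix()
  t1 <- population_caloric_table(ind, em, tax_scenario(0.2))
  ind2 <- ind
  ind2$survey_weight <- 2 * ind2$survey_weight
  t2 <- population_caloric_table(ind2, em, tax_scenario(0.2))
  expect_equal(t1$delta_ssb, t2$delta_ssb, tolerance = 1e-12)
  expect_equal(t1$baseline_kcal, t2$baseline_kcal, tolerance = 1e-12)
})

test_that("published-inputs table reproduces the tertile and national cells", {
  tab <- reference_caloric_change_table()
  expect_equal(tab$delta_20[1:3], c(-13.3, -17.5, -19.5), tolerance = 0.005)
  expect_equal(tab$delta_30[1:3], c(-19.9, -26.3, -29.3), tolerance = 0.002)
  expect_equal(tab$delta_20[4], -16.9, tolerance = 0.003)
  expect_equal(tab$delta_30[4], -25.3, tolerance = 0.002)
})
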