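test_that("unit values implement expenditure / quantity with missing flags", {
  hh <- generate_households(small_household_config(300L), seed = 2)
  pv <- unit_values(hh)
  q <- hh$qty_ssb; e <- hh$exp_ssb
  expect_equal(pv$price_ssb[q > 0], e[q > 0] / q[q > 0])
  expect_true(all(is.na(pv$price_ssb[q == 0])))
  # scale invariance: doubling both leaves prices unchanged
  hh2 <- hh
  hh2$qty_ssb <- 2 * hh2$qty_ssb
  hh2$exp_ssb <- 2 * hh2$exp_ssb
  expect_equal(unit_values(hh2)$price_ssb, pv$price_ssb)
  # all-zero category is an error
  hh3 <- hh
  hh3$qty_ssb[] <- 0; hh3$exp_ssb[] <- 0
  expect_error(unit_values(hh3), "no price information")
})

test_that("price imputation uses enclosing-region medians with escalation", {
  df <- data.frame(
    household_id = 1:7,
    state = c(1, 1, 1, 1, 2, 2, 2),
    metro_area = c(11, 11, 11, 12, 21, 21, 21),
    price_ssb = c(2, 3, 10, NA, 4, 5, NA)
  )
  out <- impute_prices(df, min_obs = 3L)
  # household 4: metro 12 empty -> state 1 has {2,3,10} -> median 3
  expect_equal(out$price_ssb[4], 3)
  # household 7: metro 21 and state 2 have only 2 obs -> national median
  expect_equal(out$price_ssb[7], median(c(2, 3, 10, 4, 5)))
  # observed prices untouched
  expect_equal(out$price_ssb[c(1:3, 5:6)], df$price_ssb[c(1:3, 5:6)])
  # nothing missing -> identity
  full <- df; full$price_ssb[c(4, 7)] <- 1
  expect_identical(impute_prices(full, min_obs = 3L), full)
})

test_that("weighted fit equals a brute-force normal-equations solve", {
  hh <- generate_households(small_household_config(400L), seed = 8)
  # restrict the price set: in a 400-household sample the rarely purchased
  # categories have an (imputed) near-constant price, which is collinear
  # log income keeps the normal equations well conditioned for the oracle
  spec <- elasticity_spec(tertile_interaction = FALSE,
                          price_categories = c("ssb", "unsweetened", "meat"),
                          controls = c("n_members", "n_children"),
                          cluster = "state", income_form = "log")
  fit_tab <- fit_demand(hh, spec)
  fit <- attr(fit_tab, "fit")
  X <- model.matrix(fit)
  y <- fit$model$.logq
  w <- fit$weights
  b <- wls_oracle(X, y, w)
  expect_equal(unname(coef(fit)), unname(b), tolerance = 1e-8)
  # and the reported elasticity is the log-price coefficient
  expect_equal(fit_tab$estimate, unname(coef(fit)["log_price_ssb"]))
})

test_that("quantities generated independent of price give elasticity near zero", {
  cfg <- small_household_config(
    8000L,
    own_elasticity = c(0, 0, 0),
    cross_elasticity = list(unsweetened = c(0, 0, 0),
                            alcoholic = c(0, 0, 0),
                            lightdiet = c(0, 0, 0)))
  hh <- generate_households(cfg, seed = 21)
  et <- fit_demand(hh, elasticity_spec(cluster = "state"))
  expect_true(all(abs(et$estimate) <= 3 * et$se))
})

test_that("embedded tertile elasticities are recovered within 3 SEs", {
  cfg <- synthetic_household_config(n_households = 20000L)
  hh <- generate_households(cfg, seed = 31)
  et <- fit_demand(hh, elasticity_spec(cluster = "state"))
  truth <- c(-1.241, -1.186, -1.126)
  expect_true(all(abs(et$estimate - truth) <= 3 * et$se))
  expect_true(all(et$se > 0))
  expect_identical(et$n_obs, rep(sum(hh$qty_ssb > 0), 3L))
})

test_that("elasticity matrix stacks all beverage categories and nests the basic fit", {
  hh <- generate_households(synthetic_household_config(n_households = 20000L),
                            seed = 32)
  em <- elasticity_matrix(hh, elasticity_spec(cluster = "state"))
  expect_identical(nrow(em), 12L)
  expect_setequal(unique(em$category), beverage_categories())
  m <- elasticity_table_to_matrix(em)
  expect_identical(dim(m), c(4L, 3L))
  # single-tertile spec collapses to the pooled regression: one row
  pooled <- fit_demand(hh, elasticity_spec(tertile_interaction = FALSE,
                                           cluster = "state"))
  expect_identical(nrow(pooled), 1L)
  # pooled estimate lies inside the span of the tertile estimates
  ssb <- em$estimate[em$category == "ssb"]
  expect_gt(pooled$estimate, min(ssb) - 0.1)
  expect_lt(pooled$estimate, max(ssb) + 0.1)
})

test_that("few clusters triggers the fragility warning; errors are informative", {
  hh <- generate_households(small_household_config(2000L), seed = 12)
  expect_warning(
    fit_demand(hh, elasticity_spec(price_categories = c("ssb", "meat"))),
    "fragile")
  # n below parameter count -> error (no-zeros config so every price is observed)
  zp <- stats::setNames(rep(0, 11), all_categories())
  tiny <- generate_households(small_household_config(30L, zero_purchase_prob = zp),
                              seed = 13)
  expect_error(suppressWarnings(fit_demand(tiny, elasticity_spec())),
               "parameter count|collinear")
})
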