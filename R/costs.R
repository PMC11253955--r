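#' Cost parameters for the savings model
#'
#' Defaults are the published Brazilian figures: US$ 38.76 billion/year of
#' overweight+obesity costs (US$ 16.19 B direct, US$ 22.57 B indirect,
#' societal perspective), 87% attributable to obesity, 37.2 million
#' baseline obesity cases, a CPI inflation factor carrying 2019 US$ to
#' 2021 US$ (942.5 / 906.92), a 5% annual discount rate, a 3-year
#' no-benefit lag and a 10-year horizon.
#'
#' @param total_ow_ob_cost Total annual overweight+obesity cost, US$/yr.
#' @param direct_cost,indirect_cost Direct / indirect split (must sum to
#'   the total within rounding).
#' @param obesity_share Fraction of the cost attributable to obesity.
#' @param baseline_obesity_cases Baseline obesity cases (persons).
#' @param inflation_factor Ratio converting costs to the target price year.
#' @param discount_rate Annual discount rate.
#' @param lag_years Years with no cost benefit. Must be < `horizon_years`.
#' @param horizon_years Simulation horizon.
#' @return List of class `cost_parameters`.
#' @export
cost_parameters <- function(total_ow_ob_cost = 38.76e9,
                            direct_cost = 16.19e9,
                            indirect_cost = 22.57e9,
                            obesity_share = 0.87,
                            baseline_obesity_cases = 37.2e6,
                            inflation_factor = 942.5 / 906.92,
                            discount_rate = 0.05,
                            lag_years = 3L,
                            horizon_years = 10L) {
  if (abs(direct_cost + indirect_cost - total_ow_ob_cost) >
      0.01 * total_ow_ob_cost) {
    config_error("direct_cost/indirect_cost",
                 "must sum to total_ow_ob_cost within rounding")
  }
  if (obesity_share <= 0 || obesity_share > 1) {
    config_error("obesity_share", "must lie in (0, 1]")
  }
  if (lag_years >= horizon_years) {
    config_error("lag_years", "must be smaller than horizon_years")
  }
  structure(list(
    total_ow_ob_cost = total_ow_ob_cost, direct_cost = direct_cost,
    indirect_cost = indirect_cost, obesity_share = obesity_share,
    baseline_obesity_cases = baseline_obesity_cases,
    inflation_factor = inflation_factor, discount_rate = discount_rate,
    lag_years = as.integer(lag_years),
    horizon_years = as.integer(horizon_years)
  ), class = "cost_parameters")
}

#' Annual cost attributable to obesity
#'
#' Product of the total overweight+obesity cost and the obesity share.
#' @param total Total annual overweight+obesity cost.
#' @param share Obesity-attributable fraction, in (0, 1].
#' @return Annual obesity cost (same units as `total`).
#' @export
obesity_attributable_cost <- function(total, share) {
  if (share <= 0 || share > 1) stop("share must lie in (0, 1]")
  total * share
}

#' Annual cost per obesity case
#'
#' @param attributable_cost Annual obesity-attributable cost.
#' @param cases Number of obesity cases. Must be > 0.
#' @param inflation_factor Optional ratio to restate the cost in another
#'   price year (default 1 = no restatement).
#' @return Cost per case per year.
#' @export
cost_per_case <- function(attributable_cost, cases, inflation_factor = 1) {
  if (cases <= 0) stop("cases must be > 0")
  attributable_cost / cases * inflation_factor
}

#' Discounted cumulative cost savings with a no-benefit lag
#'
#' Yearly savings are cases averted times the annual cost per case, zeroed
#' for the first `lag_years` years, discounted to year 0 with an
#' end-of-year convention (year y divided by (1+r)^y), and summed over the
#' horizon. Direct and indirect components are carried separately in
#' proportion to the configured cost split, so that they sum exactly to
#' the total.
#'
#' @param yearly_cases_averted Numeric vector, cases averted in years
#'   1..horizon. Length must equal `params$horizon_years`.
#' @param cost_per_case Annual cost per obesity case. Must be >= 0.
#' @param params A [cost_parameters()].
#' @return List with `total_discounted`, `total_undiscounted`,
#'   `direct_discounted`, `indirect_discounted`, and `ledger` (data.frame
#'   `year`, `cases_averted`, `nominal_savings`, `discount_factor`,
#'   `discounted_savings`).
#' @export
cumulative_savings <- function(yearly_cases_averted, cost_per_case,
                               params = cost_parameters()) {
  stopifnot(inherits(params, "cost_parameters"))
  if (cost_per_case < 0) stop("negative cost per case")
  H <- params$horizon_years
  if (length(yearly_cases_averted) != H) {
    stop(sprintf("need %d yearly values, got %d", H,
                 length(yearly_cases_averted)))
  }
  year <- seq_len(H)
  nominal <- ifelse(year <= params$lag_years, 0,
                    yearly_cases_averted * cost_per_case)
  df <- (1 + params$discount_rate)^(-year)
  disc <- nominal * df
  dshare <- params$direct_cost / params$total_ow_ob_cost
  list(
    total_discounted = sum(disc),
    total_undiscounted = sum(nominal),
    direct_discounted = sum(disc) * dshare,
    indirect_discounted = sum(disc) * (1 - dshare),
    ledger = data.frame(year = year, cases_averted = yearly_cases_averted,
                        nominal_savings = nominal, discount_factor = df,
                        discounted_savings = disc)
  )
}
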