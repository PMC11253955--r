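#' Define a tax scenario
#'
#' An ad valorem SSB tax scenario: the tax rate, the fraction of the tax
#' passed through to consumer prices (default full pass-through, the
#' standard assumption in this modelling literature), and whether
#' cross-price substitution by other beverages is included.
#'
#' @param rate Ad valorem tax fraction (e.g. 0.20 or 0.30). Must be > 0.
#' @param pass_through Fraction of the tax reflected in prices, in (0, 1.5].
#' @param include_substitution Include cross-beverage caloric changes?
#' @return List of class `tax_scenario`.
#' @export
tax_scenario <- function(rate = 0.20, pass_through = 1.0,
                         include_substitution = FALSE) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    config_error("rate", "must be a single positive fraction")
  }
  if (pass_through <= 0 || pass_through > 1.5) {
    config_error("pass_through", "must lie in (0, 1.5]")
  }
  structure(list(rate = rate, pass_through = pass_through,
                 include_substitution = isTRUE(include_substitution)),
            class = "tax_scenario")
}

#' Caloric change from SSB under a tax
#'
#' Under the linearity assumption (tax effects on consumption proportional
#' to the price change), the daily caloric change from taxed beverages is
#'   delta = baseline * rate * pass_through * elasticity,
#' truncated so post-tax intake never goes negative.
#'
#' @param baseline_kcal Baseline SSB intake, kcal/day (scalar or vector).
#' @param own_elasticity Own-price elasticity (scalar or vector matched to
#'   `baseline_kcal`).
#' @param scenario A [tax_scenario()].
#' @return Caloric change, kcal/day (negative for a demand reduction).
#' @export
ssb_caloric_change <- function(baseline_kcal, own_elasticity,
                               scenario = tax_scenario()) {
  stopifnot(inherits(scenario, "tax_scenario"))
  if (any(baseline_kcal < 0)) stop("baseline_kcal must be >= 0")
  d <- baseline_kcal * scenario$rate * scenario$pass_through * own_elasticity
  pmax(d, -baseline_kcal)
}

#' Caloric change from other beverages via cross-price elasticities
#'
#' Sums, over the non-SSB beverage categories, the caloric change induced
#' by the SSB price increase:
#'   delta_b = baseline_b * rate * pass_through * cross_elasticity_b,
#' each truncated at `-baseline_b`. A zero-calorie beverage contributes
#' nothing regardless of its elasticity.
#'
#' @param baseline_kcal Named numeric vector, or matrix with one column per
#'   category (rows = individuals), of baseline kcal/day by category.
#' @param cross_elasticities Named numeric vector of cross-price
#'   elasticities w.r.t. SSB price; names must match `baseline_kcal`.
#' @param scenario A [tax_scenario()].
#' @return Total caloric change, kcal/day (scalar, or vector over rows).
#' @export
substitution_caloric_change <- function(baseline_kcal, cross_elasticities,
                                        scenario = tax_scenario()) {
  stopifnot(inherits(scenario, "tax_scenario"))
  if (is.matrix(baseline_kcal) || is.data.frame(baseline_kcal)) {
    b <- as.matrix(baseline_kcal)
  } else {
    b <- matrix(baseline_kcal, nrow = 1L,
                dimnames = list(NULL, names(baseline_kcal)))
  }
  cats <- colnames(b)
  if (is.null(cats) || !setequal(cats, names(cross_elasticities))) {
    stop("category mismatch between baseline kcal (",
         paste(cats, collapse = ", "), ") and cross elasticities (",
         paste(names(cross_elasticities), collapse = ", "), ")")
  }
  if (any(b < 0)) stop("baseline kcal must be >= 0")
  d <- sweep(b, 2L,
             scenario$rate * scenario$pass_through * cross_elasticities[cats],
             `*`)
  d <- pmax(d, -b)
  tot <- rowSums(d)
  if (length(tot) == 1L) unname(tot) else tot
}

#' Per-person daily caloric change under a scenario
#'
#' Applies tertile-specific own-price (and, if the scenario includes
#' substitution, cross-price) elasticities to each individual's baseline
#' beverage intake.
#'
#' @param individuals Adult cohort with `kcal_ssb`, `kcal_<category>` and
#'   `income_tertile` columns.
#' @param elasticity Category x tertile matrix (rows must include "ssb";
#'   see [reference_elasticity_matrix()] / [elasticity_table_to_matrix()]).
#' @param scenario A [tax_scenario()].
#' @return Numeric vector of kcal/day changes, one per individual.
#' @export
individual_caloric_change <- function(individuals,
                                      elasticity = reference_elasticity_matrix(),
                                      scenario = tax_scenario()) {
  ti <- as.integer(factor(individuals$income_tertile,
                          levels = income_tertiles()))
  d <- ssb_caloric_change(individuals$kcal_ssb, elasticity["ssb", ti], scenario)
  if (scenario$include_substitution) {
    other <- setdiff(rownames(elasticity), "ssb")
    have <- other[paste0("kcal_", other) %in% names(individuals)]
    if (length(have)) {
      b <- as.matrix(individuals[, paste0("kcal_", have), drop = FALSE])
      colnames(b) <- have
      cross <- elasticity[have, , drop = FALSE]
      # per-individual tertile-specific cross elasticities
      dsub <- rowSums(pmax(b * scenario$rate * scenario$pass_through *
                             t(cross[, ti, drop = FALSE]), -b))
      d <- d + dsub
    }
  }
  d
}

#' Stratified caloric-change summary table
#'
#' A summary of expected per-person daily caloric changes under a scenario:
#' survey-weighted means (with optional bootstrap CIs) of the SSB and, if
#' included, other-beverage caloric changes, by stratum and nationally.
#' The national mean is, by construction of the weighted mean, the
#' population-share-weighted mean of the stratum values.
#'
#' @param individuals Adult cohort (see [individual_caloric_change()]).
#' @param elasticity Category x tertile elasticity matrix.
#' @param scenario A [tax_scenario()].
#' @param strata Stratifying columns to report (each in turn).
#' @param n_boot Bootstrap replicates for CIs (0 to skip).
#' @param seed Bootstrap seed.
#' @return data.frame with `group`, `stratum`, weighted mean baseline SSB
#'   kcal, mean SSB caloric change, mean other-beverage change (when the
#'   scenario includes substitution) and CI columns.
#' @export
population_caloric_table <- function(individuals,
                                     elasticity = reference_elasticity_matrix(),
                                     scenario = tax_scenario(),
                                     strata = c("sex", "age_group", "income_tertile"),
                                     n_boot = 0L, seed = 1L) {
  own_scen <- tax_scenario(scenario$rate, scenario$pass_through, FALSE)
  individuals$.d_ssb <- individual_caloric_change(individuals, elasticity, own_scen)
  individuals$.d_other <- if (scenario$include_substitution) {
    individual_caloric_change(individuals, elasticity, scenario) - individuals$.d_ssb
  } else {
    rep(0, nrow(individuals))
  }
  groups <- c(list(total = NULL), stats::setNames(as.list(strata), strata))
  out <- lapply(names(groups), function(gname) {
    base <- stratified_means(individuals, "kcal_ssb", groups[[gname]],
                             n_boot = n_boot, seed = seed)
    dssb <- stratified_means(individuals, ".d_ssb", groups[[gname]],
                             n_boot = n_boot, seed = seed + 1L)
    doth <- stratified_means(individuals, ".d_other", groups[[gname]],
                             n_boot = n_boot, seed = seed + 2L)
    data.frame(group = gname, stratum = base$stratum,
               baseline_kcal = base$mean,
               baseline_lo = base$ci_lower, baseline_hi = base$ci_upper,
               delta_ssb = dssb$mean,
               delta_ssb_lo = dssb$ci_lower, delta_ssb_hi = dssb$ci_upper,
               delta_other = doth$mean,
               delta_other_lo = doth$ci_lower, delta_other_hi = doth$ci_upper,
               n = base$n)
  })
  do.call(rbind, out)
}

#' Caloric-change cells from published group inputs
#'
#' Deterministic arithmetic path: applies [ssb_caloric_change()] to
#' published tertile baseline intakes and elasticities and aggregates the
#' national mean with the published population shares.
#'
#' @param rates Tax rates to tabulate.
#' @param inputs As returned by [brazil_reference_inputs()].
#' @return data.frame with `tertile`, `population_millions`,
#'   `baseline_kcal`, and one `delta_<rate>` column per rate; final row is
#'   the population-weighted national total.
#' @export
reference_caloric_change_table <- function(rates = c(0.20, 0.30),
                                           inputs = brazil_reference_inputs()) {
  tert <- inputs$intake[inputs$intake$group == "tertile", ]
  el <- inputs$elasticities
  own <- el$estimate[el$category == "ssb"]
  out <- data.frame(tertile = c(tert$stratum, "total"),
                    population_millions = c(tert$population_millions,
                                            sum(tert$population_millions)),
                    baseline_kcal = c(tert$ssb_kcal_day,
                                      wmean(tert$ssb_kcal_day,
                                            tert$population_millions)))
  for (r in rates) {
    d <- ssb_caloric_change(tert$ssb_kcal_day, own, tax_scenario(rate = r))
    out[[sprintf("delta_%d", round(100 * r))]] <-
      c(d, wmean(d, tert$population_millions))
  }
  out
}
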