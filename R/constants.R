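#' Beverage categories used throughout the model
#'
#' The four beverage groups into which purchase and intake records are
#' aggregated: sugar-sweetened beverages ("ssb"), unsweetened beverages
#' (milk, water, 100% fruit juices; "unsweetened"), alcoholic beverages
#' ("alcoholic") and low-calorie / artificially sweetened beverages
#' ("lightdiet").
#'
#' @return Character vector of length 4.
#' @export
beverage_categories <- function() {
  c("ssb", "unsweetened", "alcoholic", "lightdiet")
}

#' Food categories used as price controls
#'
#' Seven food groups whose prices enter the demand regressions as controls:
#' fruits, in natura food, in natura meat, snacks, sugar, other processed
#' food and other food items.
#'
#' @return Character vector of length 7.
#' @export
food_categories <- function() {
  c("fruits", "in_natura", "meat", "snacks", "sugar", "processed", "other_food")
}

#' All purchase categories (4 beverages + 7 foods)
#' @return Character vector of length 11.
#' @export
all_categories <- function() {
  c(beverage_categories(), food_categories())
}

#' Income tertile labels (low / middle / high)
#' @return Character vector of length 3.
#' @export
income_tertiles <- function() {
  c("low", "middle", "high")
}

#' Published national inputs for the Brazilian SSB tax model
#'
#' Reference estimates published for Brazil that let the arithmetic stages of
#' the model (caloric-change scenarios, cost derivations) run without any
#' estimation step, and that calibrate the synthetic-data generator:
#'
#' * `elasticities`: own- and cross-price elasticities of the four beverage
#'   groups with respect to SSB price, by income tertile, with standard
#'   errors, p-values and per-category estimation sample sizes, estimated
#'   from the 2017-2018 Brazilian Household Budget Survey (POF).
#' * `intake`: baseline caloric intake from SSB (kcal/person/day) and adult
#'   population (millions) by stratum (total, sex, age group, income
#'   tertile), from the POF single 24-h recall.
#' * `obesity`: baseline adult obesity prevalence (%) by stratum, from
#'   bias-corrected self-reported anthropometry.
#' * `costs`: annual overweight+obesity cost for Brazil (societal
#'   perspective, 2019 US$), its direct/indirect split, the share
#'   attributable to obesity, baseline obesity cases, the CPI inflation
#'   factor to 2021 US$, discount rate, no-benefit lag and horizon.
#' * survey frame sizes: sampled and represented households and adults.
#'
#' @return A named list with components `elasticities` (data.frame),
#'   `intake` (data.frame), `obesity` (data.frame), `costs` (list),
#'   `households_sampled`, `households_represented`, `adults_sampled`,
#'   `adults_represented`.
#' @export
brazil_reference_inputs <- function() {
  tert <- income_tertiles()

  elasticities <- data.frame(
    category = rep(beverage_categories(), each = 3L),
    tertile  = factor(rep(tert, times = 4L), levels = tert),
    estimate = c(-1.241, -1.186, -1.126,    # ssb (own-price)
                 0.046,  0.030,  0.066,     # unsweetened
                 -0.122, -0.076, -0.141,    # alcoholic
                 -0.174,  0.094,  0.201),   # light/diet
    se       = c(0.015, 0.019, 0.022,
                 0.017, 0.021, 0.025,
                 0.053, 0.047, 0.048,
                 0.124, 0.110, 0.084),
    p_value  = c(1e-4, 1e-4, 1e-4,
                 0.006, 0.150, 0.007,
                 0.022, 0.108, 0.003,
                 0.160, 0.397, 0.018),
    n_obs    = rep(c(18876L, 27488L, 4263L, 383L), each = 3L),
    stringsAsFactors = FALSE
  )

  intake <- data.frame(
    stratum  = c("total", "female", "male", "age20_39", "age40_59", "age60p",
                 "low", "middle", "high"),
    group    = c("total", "sex", "sex", "age", "age", "age",
                 "tertile", "tertile", "tertile"),
    population_millions = c(147.9, 78.2, 69.6, 62.2, 53.9, 31.7,
                            47.4, 49.1, 51.4),
    ssb_kcal_day = c(71.8, 65.1, 79.5, 92.2, 62.9, 46.9,
                     53.5, 74.0, 86.7),
    stringsAsFactors = FALSE
  )

  obesity <- data.frame(
    stratum = c("total", "female", "male", "age20_39", "age40_59", "age60p",
                "low", "middle", "high"),
    prevalence_pct = c(25.2, 28.8, 21.2, 21.8, 29.3, 24.8, 22.3, 26.2, 27.0),
    stringsAsFactors = FALSE
  )

  costs <- list(
    total_ow_ob_cost = 38.76e9,   # US$/yr, overweight + obesity, societal
    direct_cost      = 16.19e9,
    indirect_cost    = 22.57e9,
    obesity_share    = 0.87,      # fraction of the above attributable to obesity
    baseline_obesity_cases = 37.2e6,
    # CPI 2019 -> 2021; derived from the published per-case costs 906.92 -> 942.5
    inflation_factor = 942.5 / 906.92,
    discount_rate = 0.05,
    lag_years     = 3L,
    horizon_years = 10L
  )

  list(
    elasticities = elasticities,
    intake = intake,
    obesity = obesity,
    costs = costs,
    households_sampled     = 57920L,
    households_represented = 59783430,
    adults_sampled         = 37689L,
    adults_represented     = 147852423
  )
}

#' Published SSB elasticities in matrix form (category x tertile)
#'
#' Convenience accessor returning the published beverage price elasticities
#' with respect to SSB price as a 4 x 3 matrix (rows = beverage categories,
#' columns = income tertiles).
#'
#' @return Numeric matrix with dimnames `beverage_categories()` x
#'   `income_tertiles()`.
#' @export
reference_elasticity_matrix <- function() {
  el <- brazil_reference_inputs()$elasticities
  m <- matrix(el$estimate, nrow = 4L, byrow = TRUE,
              dimnames = list(beverage_categories(), income_tertiles()))
  m
}

#' Parameters of the adult dynamic energy-balance (Hall) model
#'
#' Constants of the adult body-composition and energy-partition model of
#' Hall and colleagues (dynamic simulation of fat mass, lean tissue,
#' glycogen, extracellular fluid and adaptive thermogenesis under a
#' sustained caloric perturbation). All energies are kcal, masses kg,
#' times days. Sources, equation by equation:
#'
#' * `rho_F` = 39.5 MJ/kg and `rho_L` = 7.6 MJ/kg: energy densities of fat
#'   and lean-tissue change (Hall 2011 adult model).
#' * `rho_G` = 17.6 MJ/kg: glycogen energy density.
#' * `eta_F` = 0.75 MJ/kg, `eta_L` = 0.96 MJ/kg: biochemical costs of fat
#'   and lean tissue deposition.
#' * `gamma_F` = 13 kJ/kg/d, `gamma_L` = 92 kJ/kg/d: regression
#'   coefficients of resting metabolic rate on fat and lean mass.
#' * `beta_TEF` = 0.1: thermic effect of feeding on the intake change.
#' * `beta_AT` = 0.14, `tau_AT` = 14 d: magnitude and time constant of
#'   adaptive thermogenesis.
#' * `forbes_c` = 10.4 kg: Forbes constant of the fat/lean partition,
#'   entering as p = C/(C + F) with C = 10.4 * rho_L / rho_F.
#' * `glycogen_init` = 0.5 kg, `glycogen_water` = 2.7 kg water per kg
#'   glycogen (so each kg of glycogen carries 3.7 kg of body weight).
#' * `xi_Na` = 3000 mg/L/d, `xi_CI` = 4000 mg/d, `na_conc` = 3220 mg/L:
#'   extracellular-fluid sodium/carbohydrate sub-model.
#' * `carb_frac_baseline` = 0.5: baseline carbohydrate share of energy
#'   intake; `carb_frac_change` = 1: the modelled caloric change is sugar
#'   (SSB), so the whole change is carbohydrate.
#' * `rmr`: Livingston-Kohlstadt resting metabolic rate,
#'   RMR = c * W^p - a * age, with (c, p, a) = (293, 0.4330, 5.92) for men
#'   and (248, 0.4356, 5.09) for women, kcal/day.
#' * `fat_mass`: sex-specific initial fat mass regressions on age and
#'   log(BMI) used by the Hall adult model,
#'   F = W/100 * (0.14 age + 37.31 ln(BMI) - 103.94) for men and
#'   F = W/100 * (0.14 age + 39.96 ln(BMI) - 102.01) for women.
#' * `ecf_fraction` = 0.32: initial extracellular fluid as a fraction of
#'   fat-free mass (ECW of roughly 44% of total body water, itself roughly
#'   73% of FFM); an initialisation convention with negligible effect on
#'   simulated weight *changes*.
#' * `pal` = 1.5: default physical activity level (sedentary adults).
#'
#' @param pal Physical activity level, multiplier on resting metabolic
#'   rate. Must be >= 1. Default 1.5 (sedentary).
#' @return A named list of class `hall_parameters`.
#' @export
hall_parameters <- function(pal = 1.5) {
  stopifnot(is.numeric(pal), length(pal) == 1L, is.finite(pal), pal >= 1)
  kcal <- function(kj) kj / 4.184
  p <- list(
    rho_F   = kcal(39500),   # 9440.7 kcal/kg
    rho_L   = kcal(7600),    # 1816.4 kcal/kg
    rho_G   = kcal(17600),   # 4206.5 kcal/kg
    eta_F   = kcal(750),     # 179.3 kcal/kg
    eta_L   = kcal(960),     # 229.4 kcal/kg
    gamma_F = kcal(13),      # 3.11 kcal/kg/d
    gamma_L = kcal(92),      # 21.99 kcal/kg/d
    beta_TEF = 0.10,
    beta_AT  = 0.14,
    tau_AT   = 14,
    forbes_c = 10.4,
    glycogen_init  = 0.5,
    glycogen_water = 2.7,
    xi_Na   = 3000,
    xi_CI   = 4000,
    na_conc = 3220,
    carb_frac_baseline = 0.5,
    carb_frac_change   = 1.0,
    ecf_fraction = 0.32,
    rmr_male   = c(c = 293, p = 0.4330, a = 5.92),
    rmr_female = c(c = 248, p = 0.4356, a = 5.09),
    fat_male   = c(age = 0.14, logbmi = 37.31, intercept = -103.94),
    fat_female = c(age = 0.14, logbmi = 39.96, intercept = -102.01),
    pal = pal
  )
  structure(p, class = "hall_parameters")
}
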