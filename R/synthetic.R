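#' Configuration for the synthetic household-purchase generator
#'
#' Builds the configuration of a POF-like synthetic purchase file: one week
#' of household acquisitions of 4 beverage and 7 food categories, with
#' log-normal unit prices carrying regional (state and metropolitan-area)
#' components, right-skewed per-capita income, sociodemographic controls,
#' positive survey weights rescaled to a represented household total, and
#' log-log demand with income-tertile-specific elasticities of each beverage
#' with respect to SSB price embedded as ground truth.
#'
#' Defaults reproduce the study conditions: the published own-price SSB
#' elasticities (-1.241, -1.186, -1.126) and cross-price elasticities by
#' tertile; zero-purchase probabilities back-derived from the per-category
#' estimation sample sizes over 57,920 households (e.g. SSB: 1 - 18876/57920);
#' and a represented total of 59,783,430 households.
#'
#' @param n_households Number of households to generate.
#' @param represented_households Sum the survey weights are rescaled to.
#' @param own_elasticity Length-3 numeric, SSB own-price elasticity by
#'   income tertile (low, middle, high).
#' @param cross_elasticity Named list over the non-SSB beverage categories,
#'   each a length-3 numeric of cross-price elasticities w.r.t. SSB price.
#' @param food_price_effect Coefficient of each food-category log price in
#'   every beverage demand equation (constant across tertiles).
#' @param price_meanlog,price_sdlog Location (named by category, recycled)
#'   and scale of household-level log unit prices.
#' @param region_price_sd Standard deviation of state-level price effects.
#' @param n_states,metros_per_state Regional hierarchy sizes.
#' @param zero_purchase_prob Named numeric, probability a household buys
#'   nothing in a category (independent Bernoulli thinning).
#' @param noise_sd Residual s.d. of log quantity (free parameter of the
#'   demand system; not reported in the source surveys).
#' @param income_meanlog,income_sdlog Log-normal per-capita income.
#' @param income_coef Coefficients (eta1, eta2) of income and income^2 in
#'   the demand equations.
#' @return List of class `ssb_household_config`.
#' @export
synthetic_household_config <- function(n_households = 57920L,
                                       represented_households = 59783430,
                                       own_elasticity = c(-1.241, -1.186, -1.126),
                                       cross_elasticity = list(
                                         unsweetened = c(0.046, 0.030, 0.066),
                                         alcoholic   = c(-0.122, -0.076, -0.141),
                                         lightdiet   = c(-0.174, 0.094, 0.201)
                                       ),
                                       food_price_effect = -0.05,
                                       price_meanlog = c(ssb = log(3), unsweetened = log(2.5),
                                                         alcoholic = log(8), lightdiet = log(4),
                                                         fruits = log(4), in_natura = log(3),
                                                         meat = log(15), snacks = log(10),
                                                         sugar = log(3), processed = log(8),
                                                         other_food = log(6)),
                                       price_sdlog = 0.25,
                                       region_price_sd = 0.08,
                                       n_states = 27L,
                                       metros_per_state = 3L,
                                       zero_purchase_prob = c(
                                         ssb = 1 - 18876 / 57920,
                                         unsweetened = 1 - 27488 / 57920,
                                         alcoholic = 1 - 4263 / 57920,
                                         lightdiet = 1 - 383 / 57920,
                                         fruits = 0.3, in_natura = 0.1, meat = 0.2,
                                         snacks = 0.4, sugar = 0.3, processed = 0.2,
                                         other_food = 0.1
                                       ),
                                       noise_sd = 0.5,
                                       income_meanlog = log(1200),
                                       income_sdlog = 0.8,
                                       income_coef = c(2e-5, -2e-10)) {
  n_households <- check_count(n_households, "n_households")
  check_finite(own_elasticity, "own_elasticity")
  if (length(own_elasticity) != 3L) {
    config_error("own_elasticity", "must have one value per income tertile (3)")
  }
  for (nm in names(cross_elasticity)) {
    check_finite(cross_elasticity[[nm]], paste0("cross_elasticity$", nm))
    if (length(cross_elasticity[[nm]]) != 3L) {
      config_error(paste0("cross_elasticity$", nm), "must have 3 tertile values")
    }
  }
  miss <- setdiff(all_categories(), names(zero_purchase_prob))
  if (length(miss)) {
    config_error("zero_purchase_prob",
                 paste("is missing categories:", paste(miss, collapse = ", ")))
  }
  check_prob(zero_purchase_prob, "zero_purchase_prob")
  if (!is.numeric(noise_sd) || noise_sd < 0) config_error("noise_sd", "must be >= 0")
  if (represented_households <= 0) {
    config_error("represented_households", "must be positive")
  }
  price_meanlog <- rep_len(price_meanlog, length(all_categories()))
  names(price_meanlog) <- all_categories()
  structure(list(
    n_households = n_households,
    represented_households = represented_households,
    own_elasticity = own_elasticity,
    cross_elasticity = cross_elasticity,
    food_price_effect = food_price_effect,
    price_meanlog = price_meanlog,
    price_sdlog = price_sdlog,
    region_price_sd = region_price_sd,
    n_states = as.integer(n_states),
    metros_per_state = as.integer(metros_per_state),
    zero_purchase_prob = zero_purchase_prob[all_categories()],
    noise_sd = noise_sd,
    income_meanlog = income_meanlog,
    income_sdlog = income_sdlog,
    income_coef = income_coef
  ), class = "ssb_household_config")
}

#' Generate a synthetic household purchase file
#'
#' Draws a POF-like weekly purchase table with embedded demand elasticities.
#' For each household, latent log unit prices of the 11 categories are the
#' sum of a category location, a state-level effect and household noise;
#' beverage log quantities follow the constant-elasticity demand system
#'   log q_b = alpha_b + e_b(tertile) * log p_ssb
#'           + sum_foods beta_f * log p_f + eta1 inc + eta2 inc^2 + X theta + eps,
#' with the tertile assigned at the weighted tertiles of per-capita income.
#' A category-specific Bernoulli draw zeroes out quantity and expenditure
#' (the zero-purchase households); otherwise expenditure = price * quantity,
#' so unit values recover the latent price exactly.
#'
#' @param cfg A `synthetic_household_config()`.
#' @param seed Integer seed; identical `(cfg, seed)` gives byte-identical
#'   output.
#' @return data.frame with one row per household: `household_id`, `state`,
#'   `metro_area`, `income_per_capita`, `survey_weight`, `income_tertile`,
#'   household-head controls, and `qty_*` / `exp_*` columns per category.
#' @export
generate_households <- function(cfg = synthetic_household_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ssb_household_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_households
  cats <- all_categories()
  bevs <- beverage_categories()
  foods <- food_categories()

  state <- sample.int(cfg$n_states, n, replace = TRUE)
  metro_area <- state * 10L + sample.int(cfg$metros_per_state, n, replace = TRUE)

  # state-level price effects, one per state x category
  state_eff <- matrix(stats::rnorm(cfg$n_states * length(cats), 0, cfg$region_price_sd),
                      nrow = cfg$n_states, dimnames = list(NULL, cats))
  logp <- sapply(cats, function(cc) {
    cfg$price_meanlog[[cc]] + state_eff[state, cc] +
      stats::rnorm(n, 0, cfg$price_sdlog)
  })

  income <- stats::rlnorm(n, cfg$income_meanlog, cfg$income_sdlog)
  w <- stats::rgamma(n, shape = 5, rate = 1)
  w <- w * (cfg$represented_households / sum(w))
  tert <- assign_income_tertiles(income, w)
  ti <- as.integer(tert)

  head_gender <- stats::rbinom(n, 1L, 0.42)
  head_schooling_years <- pmin(stats::rpois(n, 9L), 20L)
  head_race <- factor(sample(c("white", "black", "mixed", "other"), n,
                             replace = TRUE, prob = c(0.42, 0.10, 0.44, 0.04)))
  head_marital <- stats::rbinom(n, 1L, 0.55)
  n_members <- 1L + stats::rpois(n, 1.9)
  n_children <- pmin(stats::rpois(n, 0.7), n_members - 1L)

  # small, fixed control effects shared by all beverage equations
  ctrl_eff <- 0.05 * head_gender - 0.01 * head_schooling_years +
    0.15 * log(n_members) + 0.05 * n_children +
    cfg$income_coef[1L] * income + cfg$income_coef[2L] * income^2

  alpha <- c(ssb = log(2.5), unsweetened = log(3), alcoholic = log(1.5),
             lightdiet = log(1))
  lp_ssb_c <- logp[, "ssb"] - cfg$price_meanlog[["ssb"]]

  out <- data.frame(
    household_id = seq_len(n), state = state, metro_area = metro_area,
    income_per_capita = income, survey_weight = w, income_tertile = tert,
    head_gender = head_gender, head_schooling_years = head_schooling_years,
    head_race = head_race, head_marital = head_marital,
    n_members = n_members, n_children = n_children
  )

  food_term <- as.vector(
    (logp[, foods, drop = FALSE] -
       matrix(cfg$price_meanlog[foods], n, length(foods), byrow = TRUE)) %*%
      rep(cfg$food_price_effect, length(foods))
  )

  for (b in bevs) {
    e_b <- if (b == "ssb") cfg$own_elasticity else cfg$cross_elasticity[[b]]
    logq <- alpha[[b]] + e_b[ti] * lp_ssb_c + food_term + ctrl_eff +
      stats::rnorm(n, 0, cfg$noise_sd)
    q <- exp(logq)
    zero <- stats::runif(n) < cfg$zero_purchase_prob[[b]]
    q[zero] <- 0
    out[[paste0("qty_", b)]] <- q
    out[[paste0("exp_", b)]] <- q * exp(logp[, b])
  }
  for (f in foods) {
    q <- stats::rlnorm(n, 0.5, 0.6)
    zero <- stats::runif(n) < cfg$zero_purchase_prob[[f]]
    q[zero] <- 0
    out[[paste0("qty_", f)]] <- q
    out[[paste0("exp_", f)]] <- q * exp(logp[, f])
  }
  out
}

#' Configuration for the synthetic adult-individual generator
#'
#' Builds the configuration of a POF-like adult file: sex, age group,
#' income tertile, survey weights rescaled to the represented adult
#' population, beverage caloric intake from a single 24-h recall, true
#' ("measured-like") weight and height, and self-reported anthropometry
#' with sex-specific reporting bias (women under-report weight and
#' over-report height more than men).
#'
#' Intake is gamma-distributed with a multiplicative mean structure
#' `national_mean * tertile_factor * sex_factor * age_factor`; the default
#' factors reproduce the published group means (tertiles 53.5 / 74.0 /
#' 86.7, sexes 65.1 / 79.5, ages 92.2 / 62.9 / 46.9, national 71.8
#' kcal/person/day). True BMI is sex-specific log-normal calibrated so
#' obesity prevalence (BMI >= 30) hits the published 28.8% (women) and
#' 21.2% (men), 25.2% overall.
#'
#' @param n_individuals Number of adults (20+) to generate.
#' @param represented_persons Sum the survey weights are rescaled to.
#' @param p_female Probability of female sex.
#' @param age_group_probs Probabilities of age groups 20-39 / 40-59 / 60+.
#' @param tertile_probs Probabilities of the low / middle / high tertile.
#' @param ssb_kcal_mean National mean SSB intake, kcal/person/day.
#' @param tertile_intake_factor,sex_intake_factor,age_intake_factor
#'   Multiplicative group factors on the national mean.
#' @param intake_shape Gamma shape of individual intake (right skew; values
#'   < 1 put substantial mass near zero, as single-day recalls do).
#' @param other_bev_kcal 3 x 3 matrix (rows unsweetened / alcoholic /
#'   lightdiet, columns tertiles) of mean caloric intake from the other
#'   beverage groups.
#' @param ssb_kcal_per_ml Caloric density used to convert kcal to ml.
#' @param height_mean,height_sd Sex-named normal height parameters (m).
#' @param bmi_obesity_target Sex-named target obesity prevalence used to
#'   locate the log-normal BMI distribution.
#' @param bmi_sdlog Sex-named log-sd of BMI.
#' @param weight_bias Sex-named list `c(intercept, slope)`: under-report of
#'   weight in kg at 65 kg and its increase per kg of true weight.
#' @param height_bias Sex-named over-report of height in m.
#' @param report_noise Named `c(weight=, height=)` s.d. of reporting noise.
#' @return List of class `ssb_individual_config`.
#' @export
synthetic_individual_config <- function(n_individuals = 37689L,
                                        represented_persons = 147852423,
                                        p_female = 78.2 / 147.9,
                                        age_group_probs = c(62.2, 53.9, 31.7) / 147.8,
                                        tertile_probs = c(47.4, 49.1, 51.4) / 147.9,
                                        ssb_kcal_mean = 71.8,
                                        tertile_intake_factor = c(53.5, 74.0, 86.7) / 71.8,
                                        sex_intake_factor = c(female = 65.1, male = 79.5) / 71.8,
                                        age_intake_factor = c(92.2, 62.9, 46.9) / 71.8,
                                        intake_shape = 0.5,
                                        other_bev_kcal = rbind(
                                          unsweetened = c(20, 30, 35),
                                          alcoholic   = c(20, 25, 40),
                                          lightdiet   = c(1, 2, 3)
                                        ),
                                        ssb_kcal_per_ml = 0.4,
                                        height_mean = c(female = 1.61, male = 1.73),
                                        height_sd = c(female = 0.065, male = 0.07),
                                        bmi_obesity_target = c(female = 0.288, male = 0.212),
                                        bmi_sdlog = c(female = 0.18, male = 0.16),
                                        weight_bias = list(female = c(1.3, 0.03),
                                                           male = c(0.8, 0.02)),
                                        height_bias = c(female = 0.013, male = 0.008),
                                        report_noise = c(weight = 1.0, height = 0.008)) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  check_prob(p_female, "p_female")
  if (any(c(ssb_kcal_mean, tertile_intake_factor, sex_intake_factor,
            age_intake_factor) < 0)) {
    config_error("intake means", "must be non-negative")
  }
  if (any(other_bev_kcal < 0)) config_error("other_bev_kcal", "must be non-negative")
  if (ssb_kcal_per_ml <= 0) config_error("ssb_kcal_per_ml", "must be positive")
  check_prob(bmi_obesity_target, "bmi_obesity_target")
  age_group_probs <- age_group_probs / sum(age_group_probs)
  tertile_probs <- tertile_probs / sum(tertile_probs)
  structure(list(
    n_individuals = n_individuals,
    represented_persons = represented_persons,
    p_female = p_female,
    age_group_probs = age_group_probs,
    tertile_probs = tertile_probs,
    ssb_kcal_mean = ssb_kcal_mean,
    tertile_intake_factor = tertile_intake_factor,
    sex_intake_factor = sex_intake_factor,
    age_intake_factor = age_intake_factor,
    intake_shape = intake_shape,
    other_bev_kcal = other_bev_kcal,
    ssb_kcal_per_ml = ssb_kcal_per_ml,
    height_mean = height_mean,
    height_sd = height_sd,
    bmi_obesity_target = bmi_obesity_target,
    bmi_sdlog = bmi_sdlog,
    weight_bias = weight_bias,
    height_bias = height_bias,
    report_noise = report_noise
  ), class = "ssb_individual_config")
}

#' Generate a synthetic adult cohort
#'
#' Draws a cohort of adults (20 years and older) with survey weights,
#' beverage intakes and both true and self-reported anthropometry. The
#' self-report model is
#'   weight_sr = weight - (b0 + b1 (weight - 65)) + noise,
#'   height_sr = height + b_h + noise,
#' with sex-specific coefficients (larger weight under-report and height
#' over-report in women). Setting all bias coefficients and `report_noise`
#' to zero makes self-reported equal true anthropometry exactly.
#'
#' @param cfg A `synthetic_individual_config()`.
#' @param seed Integer seed.
#' @return data.frame with one row per adult: identifiers, `sex`,
#'   `age`, `age_group`, `income_tertile`, `survey_weight`, true
#'   `weight` / `height`, `self_reported_weight` / `self_reported_height`,
#'   and `kcal_*` / `ml_*` intake columns for the four beverage groups.
#' @export
generate_individuals <- function(cfg = synthetic_individual_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ssb_individual_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_individuals

  sex <- factor(ifelse(stats::runif(n) < cfg$p_female, "female", "male"),
                levels = c("female", "male"))
  age_group <- factor(sample(c("20-39", "40-59", "60+"), n, replace = TRUE,
                             prob = cfg$age_group_probs),
                      levels = c("20-39", "40-59", "60+"))
  age <- ifelse(age_group == "20-39", stats::runif(n, 20, 40),
                ifelse(age_group == "40-59", stats::runif(n, 40, 60),
                       stats::runif(n, 60, 80)))
  tert <- factor(sample(income_tertiles(), n, replace = TRUE,
                        prob = cfg$tertile_probs),
                 levels = income_tertiles())

  w <- stats::rgamma(n, shape = 5, rate = 1)
  w <- w * (cfg$represented_persons / sum(w))

  si <- as.integer(sex); ai <- as.integer(age_group); ti <- as.integer(tert)

  mu <- cfg$ssb_kcal_mean * cfg$tertile_intake_factor[ti] *
    cfg$sex_intake_factor[si] * cfg$age_intake_factor[ai]
  kcal_ssb <- stats::rgamma(n, shape = cfg$intake_shape,
                            scale = mu / cfg$intake_shape)
  kcal_other <- sapply(rownames(cfg$other_bev_kcal), function(b) {
    m <- cfg$other_bev_kcal[b, ti]
    stats::rgamma(n, shape = cfg$intake_shape, scale = m / cfg$intake_shape)
  })

  # plausibility truncation mirrors standard survey anthropometry cleaning
  height <- stats::rnorm(n, cfg$height_mean[si], cfg$height_sd[si])
  height <- pmin(pmax(height, 1.40), 2.10)
  # locate the log-normal BMI so P(BMI >= 30) equals the sex target
  meanlog <- log(30) - stats::qnorm(1 - cfg$bmi_obesity_target) * cfg$bmi_sdlog
  bmi <- stats::rlnorm(n, meanlog[si], cfg$bmi_sdlog[si])
  bmi <- pmin(pmax(bmi, 16), 60)
  weight <- bmi * height^2

  wb <- do.call(rbind, cfg$weight_bias)[levels(sex), , drop = FALSE]
  sr_weight <- weight - (wb[si, 1L] + wb[si, 2L] * (weight - 65)) +
    stats::rnorm(n, 0, cfg$report_noise[["weight"]])
  sr_height <- height + cfg$height_bias[si] +
    stats::rnorm(n, 0, cfg$report_noise[["height"]])
  sr_weight <- pmax(sr_weight, 25)
  sr_height <- pmax(sr_height, 1.2)

  out <- data.frame(
    person_id = seq_len(n), sex = sex, age = age, age_group = age_group,
    income_tertile = tert, survey_weight = w,
    weight = weight, height = height,
    self_reported_weight = sr_weight, self_reported_height = sr_height,
    kcal_ssb = kcal_ssb
  )
  for (b in colnames(kcal_other)) out[[paste0("kcal_", b)]] <- kcal_other[, b]
  out$ml_ssb <- kcal_ssb / cfg$ssb_kcal_per_ml
  out
}

#' Synthetic adult population projection
#'
#' Geometric stand-in for official population projections over the
#' simulation horizon.
#'
#' @param start Adult population in the first year. Must be > 0.
#' @param years Integer vector of contiguous calendar years.
#' @param growth Annual growth rate (may be negative).
#' @return data.frame with columns `year` and `adults`.
#' @export
generate_projection <- function(start = 147852423, years = 2021:2030,
                                growth = 0.01) {
  if (!is.numeric(start) || start <= 0) config_error("start", "must be > 0")
  if (length(years) == 0L) config_error("years", "must be a non-empty range")
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L)) {
    config_error("years", "must be contiguous")
  }
  data.frame(year = years,
             adults = start * (1 + growth)^(seq_along(years) - 1L))
}
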