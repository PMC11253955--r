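#' Initialize Hall-model body states at energy balance
#'
#' Builds the state of the adult dynamic energy-balance model for one or
#' more individuals. Resting metabolic rate comes from the
#' Livingston-Kohlstadt regression (sex-specific power law in weight minus
#' a linear age term); baseline energy intake is set to PAL x RMR so every
#' individual starts exactly at energy balance (a zero caloric perturbation
#' then leaves weight constant by construction). Initial fat mass uses the
#' sex-specific age/log(BMI) regressions of the Hall adult model; glycogen
#' starts at 0.5 kg (with 2.7 kg bound water per kg), extracellular fluid
#' at a fixed fraction of fat-free mass, and the lean-tissue compartment
#' absorbs the remainder of body weight.
#'
#' @param sex Character/factor vector, "female"/"male".
#' @param age Ages in years.
#' @param weight Body weights, kg.
#' @param height Heights, m.
#' @param params A [hall_parameters()] list (carries PAL).
#' @param guards Named list of plausible-adult ranges used for validation:
#'   `weight`, `height`, `age` (each `c(min, max)`).
#' @return data.frame of class `hall_state`, one row per individual, with
#'   compartments `fat`, `lean`, `glycogen`, `ecf`, `at`, and derived
#'   quantities `bw0`, `height`, `rmr`, `ei_baseline`, `ci_baseline`,
#'   `k_rmr` (RMR intercept), `delta_pa` (physical-activity coefficient,
#'   kcal/kg/day), `k_gly` (glycogen rate constant), `ecf0`.
#' @export
initialize_state <- function(sex, age, weight, height,
                             params = hall_parameters(),
                             guards = list(weight = c(28, 300),
                                           height = c(1.2, 2.3),
                                           age = c(18, 110))) {
  stopifnot(inherits(params, "hall_parameters"))
  n <- max(length(sex), length(age), length(weight), length(height))
  sex <- rep_len(as.character(sex), n)
  age <- rep_len(age, n); weight <- rep_len(weight, n)
  height <- rep_len(height, n)
  for (fld in names(guards)) {
    v <- switch(fld, weight = weight, height = height, age = age)
    bad <- which(v < guards[[fld]][1L] | v > guards[[fld]][2L] | !is.finite(v))
    if (length(bad)) {
      stop(sprintf("out-of-range %s for individual(s) %s (allowed %g-%g)",
                   fld, paste(utils::head(bad, 5L), collapse = ", "),
                   guards[[fld]][1L], guards[[fld]][2L]))
    }
  }
  if (!all(sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  female <- sex == "female"
  bmi <- weight / height^2

  rmr_c <- ifelse(female, params$rmr_female["c"], params$rmr_male["c"])
  rmr_p <- ifelse(female, params$rmr_female["p"], params$rmr_male["p"])
  rmr_a <- ifelse(female, params$rmr_female["a"], params$rmr_male["a"])
  rmr <- rmr_c * weight^rmr_p - rmr_a * age
  rmr <- pmax(rmr, 500)

  fc <- ifelse(female, params$fat_female["logbmi"], params$fat_male["logbmi"])
  fi <- ifelse(female, params$fat_female["intercept"], params$fat_male["intercept"])
  fat <- weight / 100 * (0.14 * age + fc * log(bmi) + fi)
  fat <- pmin(pmax(fat, 0.05 * weight), 0.6 * weight)

  glyc <- params$glycogen_init
  ecf0 <- params$ecf_fraction * (weight - fat)
  lean <- weight - fat - (1 + params$glycogen_water) * glyc - ecf0
  if (any(lean <= 0)) stop("implied lean mass non-positive; check anthropometry")

  ei0 <- params$pal * rmr
  ci0 <- params$carb_frac_baseline * ei0
  # the thermic effect of feeding (beta_TEF * EI) is carried separately in
  # the expenditure, so physical activity is the (1 - beta_TEF) PAL excess
  delta_pa <- ((1 - params$beta_TEF) * params$pal - 1) * rmr / weight
  k_rmr <- rmr - params$gamma_F * fat - params$gamma_L * lean
  k_gly <- ci0 / glyc^2

  out <- data.frame(
    sex = sex, age = age, bw0 = weight, height = height,
    fat = fat, lean = lean, glycogen = glyc, ecf = ecf0, at = 0,
    rmr = rmr, ei_baseline = ei0, ci_baseline = ci0,
    k_rmr = k_rmr, delta_pa = delta_pa, k_gly = k_gly, ecf0 = ecf0
  )
  class(out) <- c("hall_state", "data.frame")
  attr(out, "params") <- params
  out
}

# Right-hand side of the Hall system, vectorized over individuals.
# y = c(F, L, G, ECF, AT); parms carries per-individual baselines and dEI.
.hall_deriv <- function(t, y, parms) {
  p <- parms$p
  n <- parms$n
  Fm  <- y[seq_len(n)]
  Lm  <- y[n + seq_len(n)]
  G   <- y[2L * n + seq_len(n)]
  ECF <- y[3L * n + seq_len(n)]
  AT  <- y[4L * n + seq_len(n)]
  dEI <- parms$dEI

  EI <- parms$ei0 + dEI
  CI <- parms$ci0 + p$carb_frac_change * dEI

  dG  <- (CI - parms$k_gly * G^2) / p$rho_G
  dAT <- (p$beta_AT * dEI - AT) / p$tau_AT
  dECF <- (-p$xi_CI * (1 - CI / parms$ci0) -
             p$xi_Na * (ECF - parms$ecf0)) / p$na_conc

  BW <- Fm + Lm + (1 + p$glycogen_water) * G + ECF
  cF <- p$forbes_c * p$rho_L / p$rho_F
  part <- cF / (cF + Fm)                      # Forbes share to lean
  A0 <- parms$k_rmr + p$gamma_F * Fm + p$gamma_L * Lm +
    parms$delta_pa * BW + p$beta_TEF * EI + AT
  R <- (EI - A0 - p$rho_G * dG) /
    (1 + p$eta_F * (1 - part) / p$rho_F + p$eta_L * part / p$rho_L)
  dF <- (1 - part) * R / p$rho_F
  dL <- part * R / p$rho_L
  list(c(dF, dL, dG, dECF, dAT))
}

# residual energy imbalance (kcal/day) at a state snapshot
.hall_imbalance <- function(y, parms) {
  d <- .hall_deriv(0, y, parms)[[1L]]
  n <- parms$n
  p <- parms$p
  p$rho_F * d[seq_len(n)] + p$rho_L * d[n + seq_len(n)] +
    p$rho_G * d[2L * n + seq_len(n)]
}

.hall_parms <- function(state, delta_kcal, params) {
  n <- nrow(state)
  list(p = params, n = n,
       dEI = rep_len(delta_kcal, n),
       ei0 = state$ei_baseline, ci0 = state$ci_baseline,
       ecf0 = state$ecf0, k_rmr = state$k_rmr,
       delta_pa = state$delta_pa, k_gly = state$k_gly)
}

#' Simulate body-weight trajectories for a cohort
#'
#' Integrates the Hall system of ordinary differential equations (fat
#' mass, lean tissue, glycogen, extracellular fluid, adaptive
#' thermogenesis) for every individual simultaneously under a sustained
#' per-person caloric change applied as a step at day 0. Integration uses
#' an adaptive Runge-Kutta scheme (Dormand-Prince via [deSolve::ode()])
#' with the maximum step capped at 1 day; the run is fully deterministic.
#'
#' @param state A [initialize_state()] data.frame.
#' @param delta_kcal Sustained caloric change, kcal/day; scalar or one
#'   value per individual.
#' @param horizon_days Simulation horizon (default 3650 = 10 years).
#' @param times Output grid in days (default yearly plus day 0).
#' @return Object of class `hall_trajectories`: list with `times`,
#'   `weight` (individuals x times matrix, kg), `bmi`, `delta_kcal`,
#'   `final_state` (state vector at the horizon) and `imbalance`
#'   (residual energy imbalance, kcal/day, at the horizon).
#' @export
simulate_population <- function(state, delta_kcal, horizon_days = 3650,
                                times = seq(0, horizon_days, by = 365)) {
  stopifnot(inherits(state, "hall_state"))
  if (any(!is.finite(delta_kcal))) stop("delta_kcal must be finite")
  n <- nrow(state)
  parms <- .hall_parms(state, delta_kcal, attr_params(state))
  y0 <- c(state$fat, state$lean, state$glycogen, state$ecf, state$at)
  if (max(times) > 0) {
    sol <- deSolve::ode(y = y0, times = sort(unique(c(0, times))),
                        func = .hall_deriv, parms = parms,
                        method = "ode45", hmax = 1,
                        rtol = 1e-7, atol = 1e-7)
    if (attr(sol, "istate")[1L] < 0) {
      stop("ODE solver failed; see diagnostics above (deSolve istate < 0)")
    }
  } else {
    sol <- matrix(c(0, y0), nrow = 1L)
  }
  tt <- sol[, 1L]
  keep <- tt %in% times
  Y <- sol[keep, -1L, drop = FALSE]
  idxF <- seq_len(n); idxL <- n + idxF; idxG <- 2L * n + idxF
  idxE <- 3L * n + idxF
  p <- parms$p
  W <- t(Y[, idxF, drop = FALSE] + Y[, idxL, drop = FALSE] +
           (1 + p$glycogen_water) * Y[, idxG, drop = FALSE] +
           Y[, idxE, drop = FALSE])
  colnames(W) <- paste0("day", tt[keep])
  bmi <- W / state$height^2
  yT <- Y[nrow(Y), ]
  structure(list(times = tt[keep], weight = W, bmi = bmi,
                 delta_kcal = rep_len(delta_kcal, n),
                 final_state = yT,
                 imbalance = .hall_imbalance(yT, parms)),
            class = "hall_trajectories")
}

# recover the parameter set a state was built with; subsetting a data.frame
# can drop attributes, in which case PAL is re-derived (ei_baseline = pal*rmr)
attr_params <- function(state) {
  p <- attr(state, "params")
  if (inherits(p, "hall_parameters")) return(p)
  hall_parameters(pal = state$ei_baseline[1L] / state$rmr[1L])
}

#' Simulate a single individual's daily weight trajectory
#'
#' Convenience wrapper around [simulate_population()] for one individual
#' with a daily output grid.
#'
#' @param state Single-row [initialize_state()] result.
#' @param delta_kcal Sustained caloric change, kcal/day.
#' @param horizon_days Horizon in days (default 3650).
#' @param times Output grid (default every day).
#' @return data.frame with `day`, `weight`, `bmi`.
#' @export
simulate_individual <- function(state, delta_kcal, horizon_days = 3650,
                                times = seq(0, horizon_days, by = 1)) {
  stopifnot(nrow(state) == 1L)
  tr <- simulate_population(state, delta_kcal, horizon_days, times)
  data.frame(day = tr$times, weight = tr$weight[1L, ], bmi = tr$bmi[1L, ],
             row.names = NULL)
}

#' Aggregated (group-mean) Hall simulation
#'
#' Sensitivity-analysis mode: instead of one trajectory per individual,
#' the model is run on group-average pseudo-individuals (e.g. sex x age
#' group x income tertile cells), each receiving the group's mean caloric
#' change. Group means are survey-weighted.
#'
#' @param individuals Cohort with `sex`, corrected anthropometry and
#'   `survey_weight`.
#' @param delta_kcal Per-individual caloric changes (same order).
#' @param by Grouping columns (default sex x age group x tertile).
#' @param params [hall_parameters()].
#' @param horizon_days Horizon.
#' @param expected_groups If non-NULL and the realized group count
#'   differs, a warning (not an error) is emitted.
#' @return data.frame with the group keys, group size, weighted mean
#'   anthropometry, mean `delta_kcal`, and `weight_change` at the horizon.
#' @export
simulate_groups <- function(individuals, delta_kcal,
                            by = c("sex", "age_group", "income_tertile"),
                            params = hall_parameters(),
                            horizon_days = 3650,
                            expected_groups = NULL) {
  g <- interaction(individuals[, by, drop = FALSE], drop = TRUE)
  if (!is.null(expected_groups) && nlevels(g) != expected_groups) {
    warning(sprintf("group scheme produced %d groups (expected %d)",
                    nlevels(g), expected_groups), call. = FALSE)
  }
  w <- individuals$survey_weight
  agg <- do.call(rbind, lapply(levels(g), function(lv) {
    i <- which(g == lv)
    data.frame(
      group = lv, n = length(i),
      sex = as.character(individuals$sex[i][1L]),
      age = wmean(individuals$age[i], w[i]),
      weight = wmean(individuals$corrected_weight[i], w[i]),
      height = wmean(individuals$corrected_height[i], w[i]),
      delta_kcal = wmean(delta_kcal[i], w[i])
    )
  }))
  st <- initialize_state(agg$sex, agg$age, agg$weight, agg$height, params)
  tr <- simulate_population(st, agg$delta_kcal, horizon_days,
                            times = c(0, horizon_days))
  agg$weight_change <- tr$weight[, ncol(tr$weight)] - tr$weight[, 1L]
  agg
}
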