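# Shared fixtures and independent oracles, built in code at test time.

# small household config with fuller categories so tiny samples stay identifiable
small_household_config <- function(n = 2000L, ...) {
  synthetic_household_config(n_households = n, ...)
}

small_individual_config <- function(n = 2000L, ...) {
  synthetic_individual_config(n_individuals = n, ...)
}

# a compact adult cohort for Hall-model tests
make_cohort <- function(n = 200L, seed = 11L) {
  generate_individuals(small_individual_config(n), seed = seed)
}

# Independent fixed-step Euler integrator of the energy-balance system,
# written against the same published constants but sharing no code with the
# package's solver. State order: fat, lean, glycogen, ecf, at.
euler_hall <- function(state_row, delta_kcal, horizon_days = 3650, dt = 0.1,
                       record_days = seq(0, horizon_days, by = 365)) {
  kcal <- function(kj) kj / 4.184
  rho_F <- kcal(39500); rho_L <- kcal(7600); rho_G <- kcal(17600)
  eta_F <- kcal(750); eta_L <- kcal(960)
  gamma_F <- kcal(13); gamma_L <- kcal(92)
  beta_TEF <- 0.1; beta_AT <- 0.14; tau_AT <- 14
  forbes <- 10.4 * rho_L / rho_F
  xi_Na <- 3000; xi_CI <- 4000; na_conc <- 3220

  y <- c(state_row$fat, state_row$lean, state_row$glycogen,
         state_row$ecf, state_row$at)
  ei0 <- state_row$ei_baseline; ci0 <- state_row$ci_baseline
  k_rmr <- state_row$k_rmr; delta_pa <- state_row$delta_pa
  k_gly <- state_row$k_gly; ecf0 <- state_row$ecf0
  EI <- ei0 + delta_kcal
  CI <- ci0 + delta_kcal           # change is all carbohydrate (sugar)

  out <- numeric(length(record_days))
  names(out) <- record_days
  t <- 0; ri <- 1L
  nsteps <- round(horizon_days / dt)
  for (s in 0:nsteps) {
    if (ri <= length(record_days) && abs(t - record_days[ri]) < dt / 2) {
      out[ri] <- y[1] + y[2] + 3.7 * y[3] + y[4]
      ri <- ri + 1L
    }
    dG <- (CI - k_gly * y[3]^2) / rho_G
    dAT <- (beta_AT * delta_kcal - y[5]) / tau_AT
    dECF <- (-xi_CI * (1 - CI / ci0) - xi_Na * (y[4] - ecf0)) / na_conc
    BW <- y[1] + y[2] + 3.7 * y[3] + y[4]
    p <- forbes / (forbes + y[1])
    A0 <- k_rmr + gamma_F * y[1] + gamma_L * y[2] + delta_pa * BW +
      beta_TEF * EI + y[5]
    R <- (EI - A0 - rho_G * dG) /
      (1 + eta_F * (1 - p) / rho_F + eta_L * p / rho_L)
    y <- y + dt * c((1 - p) * R / rho_F, p * R / rho_L, dG, dECF, dAT)
    t <- t + dt
  }
  out
}

# brute-force weighted least squares oracle: solve t(X) W X b = t(X) W y
wls_oracle <- function(X, y, w) {
  XtW <- t(X * w)
  drop(solve(XtW %*% X, XtW %*% y))
}
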