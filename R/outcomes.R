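#' Obesity-prevalence trajectory under a scenario
#'
#' Converts simulated BMI trajectories into a yearly obesity-prevalence
#' series. The baseline prevalence is the weighted share with BMI >= 30 at
#' day 0 and is held constant over the horizon (steady-state assumption);
#' the scenario prevalence is read from the trajectory at each 365-day
#' mark. Relative change is absolute change divided by baseline.
#'
#' @param trajectories A [simulate_population()] result whose `times`
#'   include day 0 and the yearly marks.
#' @param individuals The simulated cohort (for `survey_weight`).
#' @param horizon_years Years to report (default 10).
#' @param cutoff BMI threshold.
#' @return data.frame of class `prevalence_series`: `year`,
#'   `baseline_prevalence`, `scenario_prevalence`, `absolute_change_pp`
#'   (percentage points, negative = reduction), `relative_change_pct`.
#' @export
prevalence_series <- function(trajectories, individuals, horizon_years = 10L,
                              cutoff = 30) {
  w <- individuals$survey_weight
  if (is.null(w)) stop("individuals must carry survey weights")
  yrs <- seq_len(horizon_years)
  need <- c(0, yrs * 365)
  if (!all(need %in% trajectories$times)) {
    stop("trajectories must include day 0 and every 365-day mark up to the horizon")
  }
  col0 <- match(0, trajectories$times)
  base <- wmean(as.numeric(trajectories$bmi[, col0] >= cutoff), w)
  scen <- vapply(yrs, function(y) {
    cy <- match(y * 365, trajectories$times)
    wmean(as.numeric(trajectories$bmi[, cy] >= cutoff), w)
  }, numeric(1L))
  out <- data.frame(
    year = yrs,
    baseline_prevalence = base,
    scenario_prevalence = scen,
    absolute_change_pp = (scen - base) * 100,
    relative_change_pct = if (base > 0) (scen - base) / base * 100 else NA_real_
  )
  class(out) <- c("prevalence_series", "data.frame")
  out
}

#' Obesity cases averted against a population projection
#'
#' Multiplies each year's absolute prevalence reduction by that year's
#' projected adult population (year-10 "stock" accounting: the cases
#' averted in a year are the prevalence difference applied to that year's
#' population).
#'
#' @param series A [prevalence_series()] result.
#' @param projection data.frame `year`, `adults` (see
#'   [generate_projection()]); its rows are matched to the series years in
#'   order.
#' @return data.frame `year`, `adults`, `cases_averted` (positive =
#'   averted) and `cumulative_cases_averted`.
#' @export
cases_averted <- function(series, projection) {
  if (nrow(projection) < nrow(series)) {
    stop(sprintf("projection covers %d years but the series needs %d",
                 nrow(projection), nrow(series)))
  }
  proj <- projection[seq_len(nrow(series)), ]
  cases <- -series$absolute_change_pp / 100 * proj$adults
  data.frame(year = series$year, adults = proj$adults,
             cases_averted = cases,
             cumulative_cases_averted = cumsum(cases))
}

#' Bootstrap uncertainty for a pipeline statistic
#'
#' Percentile confidence intervals from a nonparametric bootstrap over
#' individuals (rows resampled with replacement, carrying their survey
#' weights), for any statistic of the cohort.
#'
#' @param individuals Cohort data.frame.
#' @param statistic Function `(individuals) -> numeric` (scalar or vector).
#' @param n_reps Bootstrap replicates (>= 100 recommended).
#' @param seed Seed.
#' @param conf Confidence level.
#' @return List with `point` (statistic on the original cohort), `ci`
#'   (matrix with lower/upper rows) and `reps` (replicate matrix).
#' @export
bootstrap_uncertainty <- function(individuals, statistic, n_reps = 200L,
                                  seed = 1L, conf = 0.95) {
  point <- statistic(individuals)
  set.seed(as.integer(seed))
  reps <- vapply(seq_len(n_reps), function(r) {
    s <- sample.int(nrow(individuals), replace = TRUE)
    as.numeric(statistic(individuals[s, , drop = FALSE]))
  }, numeric(length(point)))
  reps <- matrix(reps, nrow = length(point))
  alpha <- (1 - conf) / 2
  ci <- apply(reps, 1L, stats::quantile, probs = c(alpha, 1 - alpha))
  list(point = point, ci = ci, reps = reps)
}
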