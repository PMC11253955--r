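#' Fit a quantile-difference bias curve for self-reported anthropometry
#'
#' Aligns the distribution of a self-reported variable to a measured
#' reference survey by quantile mapping: on a grid of probabilities the
#' bias is the difference between the measured and self-reported weighted
#' quantiles, bias(p) = Q_measured(p) - Q_selfreport(p), and a cubic
#' smoothing spline (generalized cross-validation by default) smooths the
#' grid into a continuous bias function of the quantile position. Curves
#' are fitted separately by sex, since women under-report weight and
#' over-report height more than men.
#'
#' @param self_reported Numeric vector of self-reported values.
#' @param measured Numeric vector from the measured reference survey.
#' @param sex Label stored on the curve ("female"/"male").
#' @param variable Label, `"weight"` (kg) or `"height"` (m).
#' @param n_quantiles Size of the probability grid (equally spaced on
#'   (0, 1); default 99, i.e. 0.01..0.99).
#' @param self_weights,measured_weights Optional survey weights for the
#'   weighted quantiles.
#' @param spar Optional smoothing parameter for [stats::smooth.spline()];
#'   `NULL` (default) selects it by generalized cross-validation;
#'   a fixed value gives fully reproducible smoothing.
#' @param min_n Minimum observations required in each sample.
#' @return Object of class `bias_curve`: the grid, fitted bias, the spline
#'   and the self-reported quantile function used to place new values.
#' @export
fit_bias_curve <- function(self_reported, measured, sex = "all",
                           variable = c("weight", "height"),
                           n_quantiles = 99L,
                           self_weights = NULL, measured_weights = NULL,
                           spar = NULL, min_n = 30L) {
  variable <- match.arg(variable)
  self_reported <- self_reported[!is.na(self_reported)]
  measured <- measured[!is.na(measured)]
  if (length(self_reported) < min_n || length(measured) < min_n) {
    stop(sprintf("bias curve for %s/%s needs at least %d observations per sample (have %d and %d)",
                 sex, variable, min_n, length(self_reported), length(measured)))
  }
  probs <- seq_len(n_quantiles) / (n_quantiles + 1)
  q_self <- weighted_quantile(self_reported, self_weights, probs)
  q_meas <- weighted_quantile(measured, measured_weights, probs)
  bias <- unname(q_meas - q_self)
  sp <- if (is.null(spar)) {
    stats::smooth.spline(probs, bias, cv = FALSE)       # GCV
  } else {
    stats::smooth.spline(probs, bias, spar = spar)
  }
  structure(list(sex = sex, variable = variable, probs = probs,
                 q_self = unname(q_self), bias = bias, spline = sp),
            class = "bias_curve")
}

#' Evaluate a bias curve at quantile positions
#'
#' Flat extrapolation outside the fitted probability grid.
#' @param curve A [fit_bias_curve()] object.
#' @param p Probabilities.
#' @return Predicted bias (same units as the corrected variable).
#' @export
predict_bias <- function(curve, p) {
  stopifnot(inherits(curve, "bias_curve"))
  p <- pmin(pmax(p, min(curve$probs)), max(curve$probs))
  stats::predict(curve$spline, p)$y
}

#' Apply a bias correction to self-reported values
#'
#' Each value is placed at its quantile position on the curve's
#' self-reported distribution (linear interpolation of the stored quantile
#' grid, clamped at the edges) and the spline-predicted bias at that
#' position is added: corrected = value + bias(p(value)).
#'
#' @param values Numeric vector of self-reported values.
#' @param curve A [fit_bias_curve()] object for the matching sex/variable.
#' @return Corrected values.
#' @export
apply_bias_correction <- function(values, curve) {
  stopifnot(inherits(curve, "bias_curve"))
  p <- stats::approx(curve$q_self, curve$probs, xout = values, rule = 2,
                     ties = "ordered")$y
  values + predict_bias(curve, p)
}

#' Serialize a bias curve to JSON (grid + fitted values)
#' @param curve A `bias_curve`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_bias_curve <- function(curve, path) {
  obj <- list(sex = curve$sex, variable = curve$variable,
              probs = curve$probs, q_self = curve$q_self, bias = curve$bias,
              spar = curve$spline$spar)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Correct self-reported weight and height in a cohort
#'
#' Fits sex-specific weight and height bias curves between the cohort's
#' self-reported values and a measured reference sample, and adds the
#' predicted bias to each individual's self-report. Weight and height are
#' corrected independently (the standard, if imperfect, practice).
#'
#' @param individuals Cohort with `sex`, `self_reported_weight`,
#'   `self_reported_height` (and optionally `survey_weight`).
#' @param reference Measured reference data.frame with `sex`, `weight`,
#'   `height` (and optionally `survey_weight`).
#' @param n_quantiles,spar Passed to [fit_bias_curve()].
#' @return `individuals` with `corrected_weight`, `corrected_height` and
#'   `corrected_bmi` columns added; the fitted curves are attached as
#'   attribute `bias_curves`.
#' @export
correct_anthropometry <- function(individuals, reference,
                                  n_quantiles = 99L, spar = NULL) {
  curves <- list()
  individuals$corrected_weight <- NA_real_
  individuals$corrected_height <- NA_real_
  for (s in levels(factor(individuals$sex))) {
    i_s <- individuals$sex == s
    r_s <- reference$sex == s
    cw <- fit_bias_curve(individuals$self_reported_weight[i_s],
                         reference$weight[r_s], sex = s, variable = "weight",
                         self_weights = individuals$survey_weight[i_s],
                         measured_weights = reference$survey_weight[r_s],
                         n_quantiles = n_quantiles, spar = spar)
    ch <- fit_bias_curve(individuals$self_reported_height[i_s],
                         reference$height[r_s], sex = s, variable = "height",
                         self_weights = individuals$survey_weight[i_s],
                         measured_weights = reference$survey_weight[r_s],
                         n_quantiles = n_quantiles, spar = spar)
    individuals$corrected_weight[i_s] <-
      apply_bias_correction(individuals$self_reported_weight[i_s], cw)
    individuals$corrected_height[i_s] <-
      apply_bias_correction(individuals$self_reported_height[i_s], ch)
    curves[[s]] <- list(weight = cw, height = ch)
  }
  individuals$corrected_bmi <-
    individuals$corrected_weight / individuals$corrected_height^2
  attr(individuals, "bias_curves") <- curves
  individuals
}

#' Weighted obesity prevalence (BMI >= 30)
#'
#' @param individuals Cohort data.frame.
#' @param use_corrected Use `corrected_weight`/`corrected_height` (TRUE)
#'   or the self-reported columns (FALSE).
#' @param weight_col Survey-weight column.
#' @param n_boot Bootstrap replicates for a percentile CI (0 skips).
#' @param seed Bootstrap seed.
#' @param cutoff BMI threshold, default 30 kg/m^2.
#' @return List with `prevalence` (fraction), `ci` (length-2 or NULL),
#'   `n`.
#' @export
obesity_prevalence <- function(individuals, use_corrected = TRUE,
                               weight_col = "survey_weight",
                               n_boot = 0L, seed = 1L, cutoff = 30) {
  wt <- if (use_corrected) individuals$corrected_weight else individuals$self_reported_weight
  ht <- if (use_corrected) individuals$corrected_height else individuals$self_reported_height
  if (any(ht <= 0)) stop("non-positive height")
  w <- individuals[[weight_col]]
  if (is.null(w)) w <- rep(1, nrow(individuals))
  bmi <- wt / ht^2
  obese <- as.numeric(bmi >= cutoff)
  prev <- wmean(obese, w)
  ci <- NULL
  if (n_boot > 0L) {
    set.seed(as.integer(seed))
    reps <- vapply(seq_len(n_boot), function(r) {
      s <- sample.int(length(obese), replace = TRUE)
      wmean(obese[s], w[s])
    }, numeric(1L))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  }
  list(prevalence = prev, ci = ci, n = length(obese))
}
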