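#' Weighted quantiles
#'
#' Quantiles of a sample with positive case weights, computed by linear
#' interpolation of the weighted empirical distribution function (reduces to
#' `stats::quantile(type = 4)`-like behaviour under equal weights).
#'
#' @param x Numeric vector.
#' @param w Positive weights, recycled to `length(x)`.
#' @param probs Probabilities in \[0, 1\].
#' @param na.rm Drop missing values in `x`?
#' @return Numeric vector of quantiles, named by `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs = seq(0, 1, 0.25), na.rm = FALSE) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(w, length(x))
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  stopifnot(length(x) > 0L, all(w > 0), all(probs >= 0 & probs <= 1))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  # midpoint positions of each observation in the weighted CDF
  pk <- (cw - w / 2) / cw[length(cw)]
  out <- stats::approx(pk, x, xout = probs, rule = 2, ties = "ordered")$y
  names(out) <- sprintf("%g%%", probs * 100)
  out
}

#' Weighted mean convenience wrapper
#' @param x Numeric vector.
#' @param w Weights (NULL for equal).
#' @return Scalar weighted mean.
#' @keywords internal
wmean <- function(x, w = NULL) {
  if (is.null(w)) return(mean(x))
  sum(w * x) / sum(w)
}

#' Assign weighted income tertiles
#'
#' Splits a population into low / middle / high income groups at the
#' weighted tertiles of per-capita income, mirroring survey practice of
#' computing tertile cut points with sampling weights.
#'
#' @param income Numeric vector of per-capita incomes.
#' @param w Survey weights (NULL for equal weights).
#' @return Factor with levels `income_tertiles()`.
#' @export
assign_income_tertiles <- function(income, w = NULL) {
  cuts <- weighted_quantile(income, w, probs = c(1 / 3, 2 / 3))
  lab <- income_tertiles()
  factor(ifelse(income <= cuts[1L], lab[1L],
                ifelse(income <= cuts[2L], lab[2L], lab[3L])),
         levels = lab)
}

# stop() with a consistent configuration-error prefix naming the field
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
    config_error(field, "must contain probabilities in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    config_error(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_finite <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    config_error(field, "must be finite numeric")
  }
  invisible(x)
}
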