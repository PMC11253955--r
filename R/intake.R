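#' Convert standard servings to millilitres per day
#'
#' Linear conversion of reported servings of each beverage type to ml/day
#' via a serving-size lookup. Additive over records of the same person-day.
#'
#' @param servings Numeric vector of serving counts, named by beverage code
#'   (or accompanied by `codes`).
#' @param serving_size_table Named numeric, ml per standard serving by
#'   beverage code.
#' @param codes Optional character vector of beverage codes, one per
#'   element of `servings` (defaults to `names(servings)`).
#' @return Numeric vector of ml/day.
#' @export
servings_to_ml <- function(servings, serving_size_table = default_serving_sizes(),
                           codes = names(servings)) {
  if (is.null(codes)) stop("beverage codes required (names of 'servings' or 'codes')")
  if (any(servings < 0)) stop("servings must be >= 0")
  unknown <- setdiff(unique(codes), names(serving_size_table))
  if (length(unknown)) {
    stop("unknown beverage code(s): ", paste(unknown, collapse = ", "))
  }
  unname(servings * serving_size_table[codes])
}

#' Convert millilitres to kcal per day
#'
#' @param ml Numeric vector of ml/day.
#' @param density_table Named numeric, kcal per ml by category.
#' @param categories Category of each element (defaults to `names(ml)`).
#' @return Numeric vector of kcal/day.
#' @export
ml_to_kcal <- function(ml, density_table = default_caloric_densities(),
                       categories = names(ml)) {
  if (is.null(categories)) stop("categories required (names of 'ml' or 'categories')")
  unknown <- setdiff(unique(categories), names(density_table))
  if (length(unknown)) {
    stop("unknown categor(ies): ", paste(unknown, collapse = ", "))
  }
  unname(ml * density_table[categories])
}

#' Default serving sizes (ml per standard serving)
#'
#' Calibration defaults; the source item-level table is not public, so
#' these are round glass/can/cup conventions.
#' @return Named numeric vector.
#' @export
default_serving_sizes <- function() {
  c(soda = 350, juice_drink = 250, milk = 200, water = 250, coffee = 50,
    beer = 350, wine = 150, diet_soda = 350, fruit_juice = 250)
}

#' Default caloric densities (kcal per ml) of the beverage groups
#'
#' Calibration defaults chosen so the national mean SSB intake of 180
#' ml/day corresponds to 72 kcal/day (0.4 kcal/ml, a typical sugary-soda
#' density). Unsweetened covers milk/juice blends; light/diet beverages
#' are nearly calorie-free.
#' @return Named numeric vector over `beverage_categories()`.
#' @export
default_caloric_densities <- function() {
  c(ssb = 0.4, unsweetened = 0.35, alcoholic = 0.8, lightdiet = 0.02)
}

#' Survey-weighted stratified means with bootstrap confidence intervals
#'
#' Weighted mean of a variable within each stratum, with percentile
#' confidence intervals from a stratified nonparametric bootstrap over
#' individuals (resampling rows with their weights within stratum).
#' Empty strata are reported as missing, not zero.
#'
#' @param individuals data.frame of individuals.
#' @param value Column to average.
#' @param strata Stratifying column (factor); use `NULL` for the national
#'   mean only.
#' @param weight Weight column name.
#' @param n_boot Bootstrap replicates (0 skips CIs). Default 1000.
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level.
#' @return data.frame with `stratum`, `mean`, `ci_lower`, `ci_upper`, `n`.
#' @export
stratified_means <- function(individuals, value, strata = NULL,
                             weight = "survey_weight", n_boot = 1000L,
                             seed = 1L, conf = 0.95) {
  x <- individuals[[value]]
  w <- individuals[[weight]]
  if (any(w <= 0)) stop("weights must be positive")
  g <- if (is.null(strata)) {
    factor(rep("total", nrow(individuals)))
  } else if (is.factor(individuals[[strata]])) {
    individuals[[strata]]       # keep declared (possibly empty) levels
  } else {
    factor(individuals[[strata]])
  }
  alpha <- (1 - conf) / 2
  set.seed(as.integer(seed))
  res <- lapply(levels(g), function(lv) {
    idx <- which(g == lv)
    if (!length(idx)) {
      return(data.frame(stratum = lv, mean = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, n = 0L))
    }
    m <- wmean(x[idx], w[idx])
    lo <- hi <- NA_real_
    if (n_boot > 0L) {
      reps <- vapply(seq_len(n_boot), function(r) {
        s <- sample(idx, length(idx), replace = TRUE)
        wmean(x[s], w[s])
      }, numeric(1L))
      qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
      lo <- qs[1L]; hi <- qs[2L]
    }
    data.frame(stratum = lv, mean = m, ci_lower = lo, ci_upper = hi,
               n = length(idx))
  })
  do.call(rbind, res)
}
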