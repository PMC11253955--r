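#' Unit values (implicit prices) per household and category
#'
#' Prices are computed as unit values: total expenditure divided by total
#' quantity acquired. Households with zero quantity in a category get a
#' missing price (never 0 or Inf); those are later filled by
#' [impute_prices()].
#'
#' @param purchases Household purchase data.frame with `qty_<cat>` and
#'   `exp_<cat>` columns (as produced by [generate_households()]).
#' @param categories Categories to compute prices for.
#' @return data.frame with `household_id`, `state`, `metro_area` and one
#'   `price_<cat>` column per category (NA where quantity is zero).
#' @export
unit_values <- function(purchases, categories = all_categories()) {
  out <- purchases[, c("household_id", "state", "metro_area")]
  for (cc in categories) {
    q <- purchases[[paste0("qty_", cc)]]
    e <- purchases[[paste0("exp_", cc)]]
    if (is.null(q) || is.null(e)) {
      stop(sprintf("purchases has no qty_/exp_ columns for category '%s'", cc))
    }
    if (any(q < 0) || any(e < 0)) {
      stop(sprintf("negative quantity or expenditure in category '%s'", cc))
    }
    if (all(q == 0)) {
      stop(sprintf("category '%s' has zero purchases in every household; no price information", cc))
    }
    p <- ifelse(q > 0, e / q, NA_real_)
    out[[paste0("price_", cc)]] <- p
  }
  out
}

# median of observed values within groups that have at least k observations
.region_median <- function(p, group, k) {
  med <- tapply(p, group, stats::median, na.rm = TRUE)
  cnt <- tapply(!is.na(p), group, sum)
  ok <- !is.na(med) & cnt >= k
  med[!ok] <- NA_real_
  med[as.character(group)]
}

#' Impute missing prices from enclosing-region medians
#'
#' Each missing unit value is replaced by the median observed price of the
#' smallest enclosing region with at least `min_obs` observed prices,
#' escalating metropolitan area -> state -> national. Households with a
#' price already observed are returned unchanged.
#'
#' @param prices Output of [unit_values()] (carries `state`, `metro_area`).
#' @param min_obs Minimum observed prices a region must have before its
#'   median is used (default 5).
#' @return `prices` with all `price_<cat>` columns complete.
#' @export
impute_prices <- function(prices, min_obs = 5L) {
  pcols <- grep("^price_", names(prices), value = TRUE)
  for (col in pcols) {
    p <- prices[[col]]
    if (!anyNA(p)) next
    if (all(is.na(p))) {
      stop(sprintf("column '%s' has no observed price anywhere", col))
    }
    fill_metro <- .region_median(p, prices$metro_area, min_obs)
    fill_state <- .region_median(p, prices$state, min_obs)
    nat <- stats::median(p, na.rm = TRUE)
    miss <- is.na(p)
    p[miss] <- ifelse(!is.na(fill_metro[miss]), fill_metro[miss],
                      ifelse(!is.na(fill_state[miss]), fill_state[miss], nat))
    prices[[col]] <- p
  }
  prices
}

#' Specification of a beverage demand regression
#'
#' Describes one constant-elasticity (log-log) demand regression: the
#' dependent beverage category, the 11 price regressors, whether prices are
#' interacted with income-tertile indicators, the sociodemographic
#' controls, the survey-weight column and the cluster variable for robust
#' standard errors.
#'
#' The default cluster variable is the income tertile (socioeconomic
#' status, 3 clusters), matching published practice; with only 3 clusters
#' the cluster-robust standard errors are fragile, and a warning says so.
#' `cluster = "state"` (27 clusters) is the recommended alternative for
#' simulation work.
#'
#' @param dependent One of `beverage_categories()`.
#' @param price_categories Price regressors (default all 11 categories).
#' @param tertile_interaction Interact every log price with tertile
#'   indicators (tertile-specific elasticities)? Default TRUE.
#' @param controls Control columns (entered linearly / as factors).
#' @param cluster Cluster variable for robust SEs.
#' @param weight Survey-weight column.
#' @param income_form `"levels"` enters income and income squared as
#'   printed in the estimating equation; `"log"` enters log income and its
#'   square (the verbal description of the published model).
#' @param tertile_main_effects Include tertile intercept shifts?
#' @return List of class `elasticity_spec`.
#' @export
elasticity_spec <- function(dependent = "ssb",
                            price_categories = all_categories(),
                            tertile_interaction = TRUE,
                            controls = c("head_gender", "head_schooling_years",
                                         "head_race", "head_marital",
                                         "n_members", "n_children"),
                            cluster = "income_tertile",
                            weight = "survey_weight",
                            income_form = c("levels", "log"),
                            tertile_main_effects = TRUE) {
  if (!dependent %in% beverage_categories()) {
    stop("dependent category must be one of: ",
         paste(beverage_categories(), collapse = ", "))
  }
  income_form <- match.arg(income_form)
  structure(list(
    dependent = dependent,
    price_categories = price_categories,
    tertile_interaction = isTRUE(tertile_interaction),
    controls = controls,
    cluster = cluster,
    weight = weight,
    income_form = income_form,
    tertile_main_effects = isTRUE(tertile_main_effects)
  ), class = "elasticity_spec")
}

# attach complete log-price columns to the purchase table
.prepare_demand_data <- function(purchases, min_obs = 5L) {
  pr <- impute_prices(unit_values(purchases), min_obs = min_obs)
  for (cc in all_categories()) {
    purchases[[paste0("log_price_", cc)]] <- log(pr[[paste0("price_", cc)]])
  }
  if (is.null(purchases$income_tertile)) {
    purchases$income_tertile <- assign_income_tertiles(
      purchases$income_per_capita, purchases$survey_weight)
  }
  purchases
}

#' Fit one constant-elasticity demand regression
#'
#' Survey-weighted least squares of log quantity on the log prices of all
#' configured categories (optionally interacted with income-tertile
#' indicators), income and income squared, and sociodemographic controls,
#' with cluster-robust standard errors. Households with zero purchases of
#' the *dependent* category are excluded (their log quantity is undefined);
#' imputed prices let them still contribute as price regressors in the
#' other categories' regressions.
#'
#' @param purchases Household purchase data.frame.
#' @param spec An [elasticity_spec()].
#' @param min_obs Passed to [impute_prices()].
#' @return data.frame of class `elasticity_table` with one row per tertile
#'   (or a single row if `tertile_interaction = FALSE`): `category`,
#'   `tertile`, `estimate` (elasticity w.r.t. SSB price), `se`, `p_value`,
#'   `n_obs`. The full `lm` fit and covariance are attached as attributes
#'   `fit` and `vcov`.
#' @export
fit_demand <- function(purchases, spec = elasticity_spec(), min_obs = 5L) {
  stopifnot(inherits(spec, "elasticity_spec"))
  dat <- .prepare_demand_data(purchases, min_obs = min_obs)
  q <- dat[[paste0("qty_", spec$dependent)]]
  keep <- q > 0
  dat <- dat[keep, , drop = FALSE]
  dat$.logq <- log(q[keep])

  pterms <- paste0("log_price_", spec$price_categories)
  rhs <- if (spec$tertile_interaction) {
    paste(sprintf("%s:income_tertile", pterms), collapse = " + ")
  } else {
    paste(pterms, collapse = " + ")
  }
  if (spec$tertile_main_effects && spec$tertile_interaction) {
    rhs <- paste(rhs, "+ income_tertile")
  }
  inc_terms <- if (spec$income_form == "levels") {
    "income_per_capita + I(income_per_capita^2)"
  } else {
    "log(income_per_capita) + I(log(income_per_capita)^2)"
  }
  rhs <- paste(rhs, "+", inc_terms)
  if (length(spec$controls)) {
    rhs <- paste(rhs, "+", paste(spec$controls, collapse = " + "))
  }
  fml <- stats::as.formula(paste(".logq ~", rhs))

  X <- stats::model.matrix(fml, dat)
  if (nrow(X) <= ncol(X)) {
    stop(sprintf("estimation sample (n = %d) smaller than parameter count (%d)",
                 nrow(X), ncol(X)))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear regressors: ", paste(bad, collapse = ", "))
  }

  wcol <- dat[[spec$weight]]
  if (any(wcol <= 0)) stop("survey weights must be positive")
  dat$.w <- wcol
  fit <- stats::lm(fml, data = dat, weights = .w)

  cl <- dat[[spec$cluster]]
  ncl <- length(unique(cl))
  if (ncl <= 5L) {
    warning(sprintf(paste("cluster variable '%s' has only %d clusters;",
                          "cluster-robust standard errors are fragile"),
                    spec$cluster, ncl), call. = FALSE)
  }
  V <- sandwich::vcovCL(fit, cluster = cl)

  cf <- stats::coef(fit)
  if (spec$tertile_interaction) {
    nm <- paste0("log_price_ssb:income_tertile", income_tertiles())
    tlab <- income_tertiles()
  } else {
    nm <- "log_price_ssb"
    tlab <- "all"
  }
  if (!all(nm %in% names(cf))) {
    stop("SSB price coefficient(s) not found in fit: ",
         paste(setdiff(nm, names(cf)), collapse = ", "))
  }
  est <- cf[nm]
  se <- sqrt(diag(V)[nm])
  z <- est / se
  out <- data.frame(
    category = spec$dependent,
    tertile = factor(tlab, levels = unique(c(income_tertiles(), "all"))),
    estimate = unname(est),
    se = unname(se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    n_obs = nrow(dat),
    stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  attr(out, "vcov") <- V
  class(out) <- c("elasticity_table", "data.frame")
  out
}

#' Elasticity matrix over all beverage categories
#'
#' Runs [fit_demand()] for each of the four beverage categories and stacks
#' the tertile-specific elasticities of each category's quantity with
#' respect to SSB price, recording the per-category estimation sample size
#' (the positive-quantity households).
#'
#' @param purchases Household purchase data.frame.
#' @param spec Template [elasticity_spec()]; its `dependent` field is
#'   replaced per category.
#' @param categories Beverage categories to fit.
#' @return `elasticity_table` data.frame (categories x tertiles rows).
#' @export
elasticity_matrix <- function(purchases, spec = elasticity_spec(),
                              categories = beverage_categories()) {
  rows <- lapply(categories, function(cc) {
    s <- spec
    s$dependent <- cc
    out <- fit_demand(purchases, s)
    attr(out, "fit") <- NULL
    attr(out, "vcov") <- NULL
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("elasticity_table", "data.frame")
  out
}

#' Reshape an elasticity table to a category x tertile matrix
#' @param table An `elasticity_table` (or compatible data.frame).
#' @return Numeric matrix, rows = categories, columns = tertiles.
#' @export
elasticity_table_to_matrix <- function(table) {
  cats <- unique(table$category)
  terts <- income_tertiles()
  m <- matrix(NA_real_, length(cats), length(terts),
              dimnames = list(cats, terts))
  for (i in seq_len(nrow(table))) {
    m[table$category[i], as.character(table$tertile[i])] <- table$estimate[i]
  }
  m
}
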