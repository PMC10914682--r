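#' Validation thresholds
#'
#' MAPE levels below which a projection is judged adequate: 12% for
#' national and provincial series, 23% for district series (a companion
#' report quotes 13% provincially; the thresholds are configurable).
#'
#' @param mape_national,mape_province,mape_district Thresholds in %.
#' @return A list with class `validation_thresholds`.
#' @export
validation_thresholds <- function(mape_national = 12, mape_province = 12,
                                  mape_district = 23) {
  vals <- c(mape_national, mape_province, mape_district)
  if (any(vals <= 0)) stop("all MAPE thresholds must be > 0")
  structure(list(mape_national = mape_national,
                 mape_province = mape_province,
                 mape_district = mape_district),
            class = "validation_thresholds")
}

#' Mean absolute percentage error
#'
#' `mean(|observed - predicted| / |observed|) * 100`. Undefined when any
#' observed value is zero.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return MAPE in percent.
#' @examples
#' mape(c(10, 10), c(9, 11))  # 10
#' @export
mape <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    stop("observed and predicted must be equal-length, non-empty")
  }
  if (any(observed == 0)) {
    stop("MAPE is undefined when an observed value is 0")
  }
  mean(abs(observed - predicted) / abs(observed)) * 100
}

#' End-to-end parameter-recovery experiment
#'
#' For each replicate: generate a synthetic panel from a known truth
#' equation, refit the equation on the panel's cross-section at the last
#' survey year, and compare recovered to true coefficients. Predictive
#' accuracy is measured as the MAPE of refit predictions against observed
#' diagnosed prevalence on a held-out 20% of districts (the fit uses the
#' remaining 80%).
#'
#' @param config A [generator_config()]; its `seed` seeds replicate `r` as
#'   `seed + r - 1`.
#' @param n_replicates Number of replicates.
#' @param holdout_fraction Fraction of districts held out for the MAPE
#'   check (default 0.2).
#' @return List with `per_replicate` (tibble: replicate, coefficient RMSE,
#'   mean absolute relative error over coefficients with `|beta| >= 0.1`,
#'   holdout MAPE), `coefficients` (tibble of per-coefficient bias and
#'   RMSE across replicates), and `summary` (averages across replicates).
#' @export
recovery_experiment <- function(config, n_replicates = 1L,
                                holdout_fraction = 0.2) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  truth <- c("(Intercept)" = config$truth$intercept, config$truth$coefficients)
  vars <- names(config$truth$coefficients)
  big <- abs(config$truth$coefficients) >= 0.1

  errs <- matrix(NA_real_, nrow = n_replicates, ncol = length(truth),
                 dimnames = list(NULL, names(truth)))
  per <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    panel <- generate_panel(cfg)
    cross <- panel[panel$year == max(cfg$survey_years), ]

    set.seed(child_seed(cfg$seed, 0L, salt = 3L))
    n <- nrow(cross)
    hold <- sample(n, size = max(1L, round(holdout_fraction * n)))
    train <- if (holdout_fraction > 0) cross[-hold, ] else cross
    test <- cross[hold, ]

    fitted <- fit_ols(train, "diagnosed_prevalence", vars)
    est <- c("(Intercept)" = fitted$intercept, fitted$coefficients)
    errs[r, ] <- est[names(truth)] - truth

    rel <- abs(errs[r, vars][big]) / abs(config$truth$coefficients[big])
    obs <- test$diagnosed_prevalence
    pr <- predict(fitted, test)
    per[[r]] <- tibble::tibble(
      replicate = r,
      coef_rmse = sqrt(mean(errs[r, vars]^2)),
      mean_abs_rel_error = mean(rel),
      holdout_mape = if (all(obs != 0)) mape(obs, pr) else NA_real_)
  }
  per <- dplyr::bind_rows(per)
  coefs <- tibble::tibble(
    coefficient = names(truth),
    truth = unname(truth),
    bias = colMeans(errs),
    rmse = sqrt(colMeans(errs^2)))
  list(per_replicate = per, coefficients = coefs,
       summary = tibble::tibble(
         n_replicates = n_replicates,
         mean_coef_rmse = mean(per$coef_rmse),
         mean_abs_rel_error = mean(per$mean_abs_rel_error),
         mean_holdout_mape = mean(per$holdout_mape, na.rm = TRUE)))
}
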