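#' Burden accounting assumptions
#'
#' Case-fatality and complication proportions applied to projected cases.
#' Defaults come from 2016-2020 national health-insurance claims and the
#' clinical literature: an annual diabetes case fatality rate of 2.32%;
#' stroke, ischaemic heart disease and chronic kidney disease accounting for
#' 12.08%, 8.15% and 6.7% of diabetes deaths; neuropathy in 53.64% and
#' retinopathy in 30.7% of cases; diabetic ketoacidosis in 3.07% of cases
#' with 28.57% 72-hour mortality.
#'
#' @param cfr Annual case fatality rate of diabetes (fraction of cases).
#' @param p_stroke,p_ihd,p_ckd Fractions of diabetes deaths attributed to
#'   stroke, IHD and CKD.
#' @param p_neuropathy,p_retinopathy Fractions of cases with the
#'   complication.
#' @param p_dka Fraction of cases with diabetic ketoacidosis.
#' @param dka_mortality_72h 72-hour mortality among DKA cases.
#' @return A list with class `burden_assumptions`.
#' @export
burden_assumptions <- function(cfr = 0.0232, p_stroke = 0.1208,
                               p_ihd = 0.0815, p_ckd = 0.067,
                               p_neuropathy = 0.5364, p_retinopathy = 0.307,
                               p_dka = 0.0307, dka_mortality_72h = 0.2857) {
  vals <- c(cfr = cfr, p_stroke = p_stroke, p_ihd = p_ihd, p_ckd = p_ckd,
            p_neuropathy = p_neuropathy, p_retinopathy = p_retinopathy,
            p_dka = p_dka, dka_mortality_72h = dka_mortality_72h)
  if (any(vals < 0 | vals > 1)) {
    stop("every burden assumption must lie in [0, 1]: ",
         paste(names(vals)[vals < 0 | vals > 1], collapse = ", "))
  }
  if (p_stroke + p_ihd + p_ckd > 1) {
    stop("p_stroke + p_ihd + p_ckd must not exceed 1")
  }
  structure(as.list(vals), class = "burden_assumptions")
}

#' Calibration of diagnosed to measured prevalence
#'
#' The regression predicts doctor-diagnosed prevalence, which understates
#' prevalence measured by blood glucose. A single multiplicative factor is
#' chosen so the population-weighted national diagnosed prevalence at the
#' reference year equals the measured national prevalence (8.5% in 2018 by
#' default).
#'
#' @param measured_national_prevalence Measured national prevalence (%).
#' @param reference_year Year the measurement refers to.
#' @return A list with class `calibration_spec` (factor filled by
#'   [calibration_factor()]).
#' @export
calibration_spec <- function(measured_national_prevalence = 8.5,
                             reference_year = 2018L) {
  structure(list(measured_national_prevalence = measured_national_prevalence,
                 reference_year = as.integer(reference_year),
                 factor = NA_real_),
            class = "calibration_spec")
}

#' @rdname calibration_spec
#' @param panel District-year panel with `diagnosed_prevalence` and
#'   `pop15plus`.
#' @param spec A [calibration_spec()].
#' @return The spec with `factor` filled (measured over modelled national
#'   prevalence at the reference year).
#' @export
calibration_factor <- function(panel, spec = calibration_spec()) {
  ref <- panel[panel$year == spec$reference_year, ]
  if (!nrow(ref)) stop("panel has no rows for reference year ", spec$reference_year)
  national <- sum(ref$diagnosed_prevalence / 100 * ref$pop15plus) /
    sum(ref$pop15plus) * 100
  if (national <= 0) stop("national diagnosed prevalence at reference year is not positive")
  spec$factor <- spec$measured_national_prevalence / national
  spec
}

#' Project prevalence for one district and a set of years
#'
#' Evaluates every model predictor through its (possibly
#' scenario-overridden) trend, applies the prevalence equation, multiplies
#' by the calibration factor and clamps into `[0, 100]`.
#'
#' @param model A [dm_model].
#' @param trends Named list of [trend_model()]s covering every model
#'   predictor.
#' @param years Years to project.
#' @param factor Calibration factor (default 1).
#' @inheritParams value_at
#' @return Numeric vector of prevalences (%), one per year.
#' @export
project_prevalence <- function(model, trends, years, factor = 1,
                               mode = "deterministic", rng = NULL) {
  vars <- names(model$coefficients)
  missing <- setdiff(vars, names(trends))
  if (length(missing)) {
    stop("no trend for predictor(s): ", paste(missing, collapse = ", "))
  }
  pm <- vapply(vars, function(v) value_at(trends[[v]], years, mode, rng),
               numeric(length(years)))
  if (length(years) == 1L) pm <- matrix(pm, nrow = 1, dimnames = list(NULL, vars))
  pred <- predict(model, tibble::as_tibble(as.data.frame(pm)))
  clamp(pred * factor)
}

#' Convert prevalence to case counts
#'
#' @param prevalence Prevalence (%).
#' @param pop15plus Population aged 15+.
#' @return Cases as a real number (rounded only at report-writing time).
#' @export
cases_from_prevalence <- function(prevalence, pop15plus) {
  if (any(pop15plus <= 0)) stop("pop15plus must be positive")
  prevalence / 100 * pop15plus
}

#' Burden accounting
#'
#' Deaths and complication counts from case counts: `deaths_dm = cfr *
#' cases`; the stroke/IHD/CKD proportions apply to diabetes deaths;
#' neuropathy and retinopathy proportions apply to cases; DKA deaths are
#' `cases * p_dka * dka_mortality_72h`. All outputs are real numbers;
#' rounding is deferred to report writing.
#'
#' @param cases Case counts (vectorised).
#' @param assumptions A [burden_assumptions()].
#' @return Tibble with columns `cases`, `deaths_dm`, `deaths_stroke`,
#'   `deaths_ihd`, `deaths_ckd`, `deaths_dka`, `cases_neuropathy`,
#'   `cases_retinopathy`.
#' @export
burden <- function(cases, assumptions = burden_assumptions()) {
  if (any(cases < 0)) stop("cases must be >= 0")
  a <- assumptions
  deaths_dm <- a$cfr * cases
  tibble::tibble(
    cases = cases,
    deaths_dm = deaths_dm,
    deaths_stroke = a$p_stroke * deaths_dm,
    deaths_ihd = a$p_ihd * deaths_dm,
    deaths_ckd = a$p_ckd * deaths_dm,
    deaths_dka = a$p_dka * cases * a$dka_mortality_72h,
    cases_neuropathy = a$p_neuropathy * cases,
    cases_retinopathy = a$p_retinopathy * cases
  )
}

burden_count_cols <- function() {
  c("cases", "deaths_dm", "deaths_stroke", "deaths_ihd", "deaths_ckd",
    "deaths_dka", "cases_neuropathy", "cases_retinopathy")
}

#' Aggregate district projections to province and national level
#'
#' Counts sum; aggregated prevalence is total cases over total population.
#'
#' @param district_results Tidy district-level results from
#'   [run_projection()] (level `"district"`).
#' @param level `"province"` or `"national"`.
#' @param province_map Optional tibble `(district_id, province_id)`; by
#'   default taken from the `province_id` column of `district_results`.
#' @return Tibble of aggregated rows with the same columns.
#' @export
aggregate_results <- function(district_results,
                              level = c("province", "national"),
                              province_map = NULL) {
  level <- match.arg(level)
  res <- district_results
  if (!is.null(province_map)) {
    res$province_id <- NULL
    res <- dplyr::left_join(res, province_map,
                            by = c("unit_id" = "district_id"))
  }
  if (anyNA(res$province_id)) {
    orphans <- unique(res$unit_id[is.na(res$province_id)])
    stop("district(s) without a province: ", paste(orphans, collapse = ", "))
  }
  keys <- if (level == "province") c("scenario", "province_id", "year") else
    c("scenario", "year")
  out <- res |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(burden_count_cols(), "pop15plus")), sum),
      .groups = "drop") |>
    dplyr::mutate(prevalence = .data$cases / .data$pop15plus * 100,
                  level = level)
  out$unit_id <- if (level == "province") out$province_id else "IDN"
  out
}

#' Run the full multi-scenario projection
#'
#' For every scenario, district and year: evaluate the dynamized predictors,
#' apply the calibrated prevalence equation, convert prevalence to cases
#' with the population projection, apply burden accounting, then aggregate
#' to province and national level. Deterministic by default; in stochastic
#' mode the random-normal predictors are redrawn per replicate (seeded) and
#' the replicate-mean prevalence is used.
#'
#' @param panel Baseline district-year panel (used for the district/province
#'   mapping and calibration).
#' @param model A [dm_model].
#' @param trends Per-district trend sets from [fit_panel_trends()].
#' @param population Tibble `(district_id, year, pop15plus)` covering the
#'   projection years.
#' @param assumptions A [burden_assumptions()].
#' @param calibration A `calibration_spec` with its factor filled (see
#'   [calibration_factor()]), or a bare numeric factor.
#' @param scenarios Scenario ids to run (default 1:3).
#' @param years Projection years (default 2020:2045).
#' @param mode `"deterministic"` (single trajectory, random-normal variables
#'   at their means) or `"stochastic"`.
#' @param n_replicates Replicates in stochastic mode (their mean is
#'   reported).
#' @param seed Seed for stochastic mode.
#' @return Tidy tibble with district, province and national rows:
#'   `scenario`, `level`, `unit_id`, `province_id`, `year`, `prevalence`,
#'   `pop15plus` and the burden count columns.
#' @export
run_projection <- function(panel, model, trends, population,
                           assumptions = burden_assumptions(),
                           calibration = 1,
                           scenarios = 1:3, years = 2020:2045,
                           mode = c("deterministic", "stochastic"),
                           n_replicates = 1L, seed = 1L) {
  mode <- match.arg(mode)
  factor <- if (inherits(calibration, "calibration_spec")) {
    if (is.na(calibration$factor)) {
      stop("calibration factor not derived; call calibration_factor() first")
    }
    calibration$factor
  } else as.numeric(calibration)
  if (factor <= 0) stop("calibration factor must be > 0")

  dmap <- unique(panel[c("district_id", "province_id")])
  districts <- dmap$district_id
  missing_tr <- setdiff(districts, names(trends))
  if (length(missing_tr)) {
    stop("no trends for district(s): ", paste(missing_tr, collapse = ", "))
  }

  pop <- population[population$year %in% years, ]
  rows <- list()
  for (sid in scenarios) {
    sc <- scenario_spec(sid, start_year = min(years))
    for (i in seq_along(districts)) {
      d <- districts[i]
      tr <- apply_scenario(trends[[d]], sc)
      prev <- if (mode == "deterministic") {
        project_prevalence(model, tr, years, factor)
      } else {
        reps <- vapply(seq_len(n_replicates), function(r) {
          set.seed(child_seed(seed, i, salt = 100L * sid + r))
          project_prevalence(model, tr, years, factor,
                             mode = "stochastic", rng = stats::rnorm)
        }, numeric(length(years)))
        rowMeans(matrix(reps, nrow = length(years)))
      }
      dp <- pop[pop$district_id == d, ]
      dp <- dp[match(years, dp$year), ]
      if (anyNA(dp$pop15plus)) {
        stop("population projection missing for district ", d,
             " in some projection years")
      }
      b <- burden(cases_from_prevalence(prev, dp$pop15plus), assumptions)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = sid, level = "district", unit_id = d,
        province_id = dmap$province_id[i], year = years,
        prevalence = prev, pop15plus = dp$pop15plus, !!!b)
    }
  }
  district_res <- dplyr::bind_rows(rows)
  prov <- aggregate_results(district_res, "province")
  nat <- aggregate_results(district_res, "national")
  dplyr::bind_rows(
    district_res,
    dplyr::mutate(prov, province_id = .data$unit_id),
    dplyr::mutate(nat, province_id = NA_character_)
  )
}

#' Round a results table for reporting
#'
#' Counts are rounded half-up to whole persons; prevalence to 2 decimals.
#' Kept separate from the arithmetic so conservation holds exactly
#' internally.
#'
#' @param results Tidy results from [run_projection()].
#' @return The rounded tibble.
#' @export
round_for_report <- function(results) {
  for (v in burden_count_cols()) results[[v]] <- round_half_up(results[[v]])
  results$prevalence <- round(results$prevalence, 2)
  results
}

#' Wide per-measure export mirroring the published table shapes
#'
#' One row per unit with 5-yearly columns (2020, 2025, ..., 2045) for a
#' chosen measure.
#'
#' @param results Tidy results from [run_projection()].
#' @param measure One of the count columns or `"prevalence"`.
#' @param level `"province"` or `"national"` (or `"district"`).
#' @param scenario Scenario id.
#' @param years Column years (default `seq(2020, 2045, by = 5)`).
#' @return A wide tibble, units as rows and years as columns.
#' @export
wide_table <- function(results, measure = "prevalence", level = "province",
                       scenario = 1, years = seq(2020, 2045, by = 5)) {
  res <- results[results$level == level & results$scenario == scenario &
                   results$year %in% years, ]
  res <- round_for_report(res)
  out <- res |>
    dplyr::select(dplyr::all_of(c("unit_id", "year", measure))) |>
    tidyr_pivot_wider()
  out
}

# minimal pivot (unit_id x year) without importing tidyr
tidyr_pivot_wider <- function(long) {
  measure <- setdiff(names(long), c("unit_id", "year"))
  years <- sort(unique(long$year))
  units <- unique(long$unit_id)
  m <- matrix(NA_real_, nrow = length(units), ncol = length(years),
              dimnames = list(units, years))
  m[cbind(match(long$unit_id, units), match(long$year, years))] <-
    long[[measure]]
  tibble::tibble(unit_id = units, tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
}
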