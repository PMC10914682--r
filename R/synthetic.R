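#' Configuration for the synthetic district panel generator
#'
#' Builds the configuration object consumed by [generate_panel()] and
#' [generate_population()]. The generator emulates a district-level NCD
#' surveillance panel: 10 risk-factor prevalences observed at household
#' survey years, 8 programme coverages observed at programme-reporting
#' years, and a diagnosed diabetes prevalence produced by a known linear
#' "truth" equation plus Gaussian noise. All quantities are percentages of
#' the 15+ population of each district.
#'
#' District heterogeneity is generated from per-district baseline levels
#' (Gaussian around a national mean) and per-district linear time slopes
#' (Gaussian around a national slope, risk-factor slopes floored at zero so
#' secular risk trends are non-decreasing). The two minimum-service-standard
#' (SPM) coverages additionally get independent year-to-year jitter, since
#' downstream they are modelled as random-normal rather than linear-trend
#' variables.
#'
#' @param n_districts Number of districts (default 205).
#' @param n_provinces Number of provinces the districts are spread over
#'   (default 34).
#' @param survey_years Years at which risk factors are observed
#'   (default 2007, 2013, 2018).
#' @param program_years Years at which programme coverages are observed
#'   (default 2016:2020).
#' @param spm_years Years over which the two SPM coverages are summarised
#'   for their random-normal trend (default 2019:2021).
#' @param truth A [dm_model] used as the generating equation for diagnosed
#'   prevalence (default [default_model()]).
#' @param noise_sd SD (percentage points) of the Gaussian noise added to the
#'   diagnosed prevalence. The default 2.0 is derived from the generator's
#'   own between-district signal variance (about 5.4 squared percentage
#'   points under the default levels and SDs) so the cross-sectional
#'   R-squared matches the 0.571 of the shipped equation.
#' @param population_base Baseline 15+ population per district: a scalar, a
#'   vector of length `n_districts`, or `NULL` to draw log-normal sizes
#'   (median about 6e5) from the seeded stream.
#' @param population_growth Annual population growth fraction (default 0.011).
#' @param missing_fraction Fraction of predictor cells blanked and then
#'   refilled by province-mean imputation (default 0).
#' @param overshoot_cap Upper cap for raw programme coverages. At the
#'   default 100 no reporting artifact is produced; values above 100 let the
#'   raw panel contain the >100% coverage artifact that [clean_panel()]
#'   truncates.
#' @param means,sds,slopes,slope_sd Named national baseline means, SDs of the
#'   between-district level distribution, national annual slopes, and the SD
#'   of district slopes around the national slope. Defaults cover all 18
#'   predictors with values typical of the Indonesian 2018 cross-section.
#' @param spm_jitter_sd Year-to-year SD of the SPM coverages (default 3).
#' @param seed Integer root seed; identical seed and configuration give a
#'   bit-identical panel.
#'
#' @return A list with class `generator_config`.
#' @export
generator_config <- function(n_districts = 205L,
                             n_provinces = 34L,
                             survey_years = c(2007L, 2013L, 2018L),
                             program_years = 2016:2020,
                             spm_years = 2019:2021,
                             truth = default_model(),
                             noise_sd = 2.0,
                             population_base = NULL,
                             population_growth = 0.011,
                             missing_fraction = 0,
                             overshoot_cap = 100,
                             means = NULL, sds = NULL,
                             slopes = NULL, slope_sd = NULL,
                             spm_jitter_sd = 3,
                             seed = 1L) {
  defaults <- default_variable_params()
  means  <- utils::modifyList(defaults$means,  as.list(means  %||% list()))
  sds    <- utils::modifyList(defaults$sds,    as.list(sds    %||% list()))
  slopes <- utils::modifyList(defaults$slopes, as.list(slopes %||% list()))
  slope_sd <- utils::modifyList(defaults$slope_sd, as.list(slope_sd %||% list()))

  cfg <- structure(
    list(n_districts = as.integer(n_districts),
         n_provinces = as.integer(n_provinces),
         survey_years = as.integer(survey_years),
         program_years = as.integer(program_years),
         spm_years = as.integer(spm_years),
         truth = truth, noise_sd = noise_sd,
         population_base = population_base,
         population_growth = population_growth,
         missing_fraction = missing_fraction,
         overshoot_cap = overshoot_cap,
         means = means, sds = sds, slopes = slopes, slope_sd = slope_sd,
         spm_jitter_sd = spm_jitter_sd,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# National baselines: levels anchored at the 2018 cross-section, secular
# slopes per year. Risk factors in % prevalence, programmes in % coverage.
default_variable_params <- function() {
  means <- list(
    overweight = 13.6, obesity = 21.8, central_obesity = 31.0,
    sweet_food = 40.1, sugary_beverage = 61.3, fatty_food = 41.0,
    low_fruit_veg = 95.5, low_physical_activity = 33.5,
    smoking = 28.8, hypertension = 34.1,
    posbindu = 40, village_posbindu = 50, posbindu_examination = 30,
    pandu = 40, prolanis = 5, routine_blood_glucose = 3,
    spm_dm_service = 70, spm_screening = 50
  )
  sds <- list(
    overweight = 4, obesity = 5, central_obesity = 5,
    sweet_food = 10, sugary_beverage = 12, fatty_food = 10,
    low_fruit_veg = 3, low_physical_activity = 8,
    smoking = 5, hypertension = 6,
    posbindu = 15, village_posbindu = 20, posbindu_examination = 12,
    pandu = 20, prolanis = 2.5, routine_blood_glucose = 1.5,
    spm_dm_service = 15, spm_screening = 15
  )
  slopes <- list(
    overweight = 0.25, obesity = 0.5, central_obesity = 0.6,
    sweet_food = 0.1, sugary_beverage = 0.1, fatty_food = 0.3,
    low_fruit_veg = 0.05, low_physical_activity = 0.5,
    smoking = 0.05, hypertension = 0.5,
    posbindu = 2, village_posbindu = 3, posbindu_examination = 1.5,
    pandu = 3, prolanis = 0.3, routine_blood_glucose = 0.1,
    spm_dm_service = 0, spm_screening = 0
  )
  slope_sd <- as.list(stats::setNames(
    rep(0.1, length(predictor_names())), predictor_names()))
  list(means = means, sds = sds, slopes = slopes, slope_sd = slope_sd)
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid generator config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  n_pred <- length(predictor_names())
  if (cfg$n_districts < n_pred + 2L) {
    fail("n_districts", sprintf("must be >= %d for the regression to be estimable",
                                n_pred + 2L))
  }
  if (cfg$n_provinces < 1L || cfg$n_provinces > cfg$n_districts) {
    fail("n_provinces", "must be in [1, n_districts]")
  }
  if (cfg$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction > 1) {
    fail("missing_fraction", "must lie in [0, 1]")
  }
  if (cfg$population_growth <= -1) {
    fail("population_growth", "must be > -100%")
  }
  if (cfg$overshoot_cap < 100) fail("overshoot_cap", "must be >= 100")
  if (!inherits(cfg$truth, "dm_model")) fail("truth", "must be a dm_model")
  invisible(cfg)
}

# Deterministic per-district child seed so adding districts never perturbs
# the streams of existing ones. `salt` separates independent uses.
child_seed <- function(seed, i, salt = 0) {
  as.integer((as.numeric(seed) * 48271 + i * 9973 + salt * 65537) %% 2147483629 + 1)
}

district_ids <- function(n) sprintf("D%03d", seq_len(n))
province_ids <- function(n) sprintf("P%02d", seq_len(n))

# Districts dealt round-robin over provinces so every province is non-empty.
province_of <- function(n_districts, n_provinces) {
  province_ids(n_provinces)[((seq_len(n_districts) - 1L) %% n_provinces) + 1L]
}

#' Generate a synthetic district-year panel
#'
#' For every district and every year in the union of the configured survey,
#' programme and SPM years, draws the 18 predictors from the district's
#' seeded level-plus-trend process, computes diagnosed prevalence from the
#' truth equation plus Gaussian noise truncated to `[0, 100]`, optionally
#' blanks a fraction of predictor cells and refills them with
#' [impute_province_means()], and attaches the 15+ population.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per district-year: `district_id`,
#'   `province_id`, `year`, the 18 predictors, `diagnosed_prevalence`,
#'   `pop15plus`.
#' @export
generate_panel <- function(config) {
  validate_config(config)
  years <- sort(unique(c(config$survey_years, config$program_years,
                         config$spm_years)))
  n <- config$n_districts
  vars <- predictor_names()
  rf <- risk_factor_names()
  spm_vars <- c("spm_dm_service", "spm_screening")

  # reference year per variable: anchor levels at the last year of the
  # window the variable is observed in
  ref_year <- stats::setNames(
    ifelse(vars %in% rf, max(config$survey_years), max(config$program_years)),
    vars)
  ref_year[spm_vars] <- max(config$spm_years)

  prov <- province_of(n, config$n_provinces)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seed(config$seed, i))
    level <- vapply(vars, function(v)
      stats::rnorm(1, config$means[[v]], config$sds[[v]]), numeric(1))
    level_hi <- ifelse(vars %in% rf, 99.5, config$overshoot_cap - 0.5)
    level <- clamp(level, 0.5, level_hi)
    slope <- vapply(vars, function(v)
      stats::rnorm(1, config$slopes[[v]], config$slope_sd[[v]]), numeric(1))
    slope[rf] <- pmax(slope[rf], 0)  # secular risk trends are non-decreasing

    m <- vapply(vars, function(v)
      level[[v]] + slope[[v]] * (years - ref_year[[v]]),
      numeric(length(years)))
    if (length(years) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, vars))
    if (config$spm_jitter_sd > 0) {
      m[, spm_vars] <- m[, spm_vars] +
        matrix(stats::rnorm(length(years) * 2, 0, config$spm_jitter_sd),
               ncol = 2)
    }
    # risk factors stay in [0,100]; coverages may overshoot up to the cap
    m[, rf] <- clamp(m[, rf])
    pg <- setdiff(vars, rf)
    m[, pg] <- clamp(m[, pg], 0, config$overshoot_cap)

    eps <- if (config$noise_sd > 0) {
      stats::rnorm(length(years), 0, config$noise_sd)
    } else rep(0, length(years))
    df <- tibble::as_tibble(as.data.frame(m))
    dp <- clamp(predict(config$truth, df) + eps)

    rows[[i]] <- tibble::tibble(
      district_id = district_ids(n)[i], province_id = prov[i], year = years,
      !!!df, diagnosed_prevalence = dp)
  }
  panel <- dplyr::bind_rows(rows)

  if (config$missing_fraction > 0) {
    set.seed(child_seed(config$seed, 0L, salt = 1L))
    cells <- expand.grid(row = seq_len(nrow(panel)), var = vars,
                         stringsAsFactors = FALSE)
    blank <- cells[stats::runif(nrow(cells)) < config$missing_fraction, ]
    for (v in unique(blank$var)) {
      panel[[v]][blank$row[blank$var == v]] <- NA_real_
    }
    panel <- impute_province_means(panel)
  }

  pop <- generate_population(config, years)
  dplyr::left_join(panel, pop, by = c("district_id", "year"))
}

#' Generate district 15+ population projections
#'
#' Compound-growth populations: `pop15plus(d, y) = base(d) *
#' (1 + growth)^(y - min(years))`.
#'
#' @param config A [generator_config()].
#' @param years Year range to cover.
#' @return Tibble `(district_id, year, pop15plus)`.
#' @export
generate_population <- function(config, years) {
  if (!length(years)) stop("years must be non-empty")
  if (config$population_growth <= -1) {
    stop("invalid generator config: field 'population_growth' must be > -100%")
  }
  n <- config$n_districts
  base <- config$population_base
  if (is.null(base)) {
    set.seed(child_seed(config$seed, 0L, salt = 2L))
    base <- stats::rlnorm(n, meanlog = log(6e5), sdlog = 0.7)
  } else if (length(base) == 1L) {
    base <- rep(base, n)
  } else if (length(base) != n) {
    stop("population_base must be a scalar or length n_districts")
  }
  years <- sort(unique(as.integer(years)))
  tibble::tibble(
    district_id = rep(district_ids(n), each = length(years)),
    year = rep(years, times = n),
    pop15plus = rep(base, each = length(years)) *
      (1 + config$population_growth)^(rep(years, times = n) - min(years))
  )
}

#' Clean a raw panel
#'
#' Applies the reporting-artifact rule: every prevalence/coverage value and
#' the diagnosed prevalence is truncated into `[0, 100]` (programme coverage
#' reported above 100% is fulfilled to a maximum of 100%). Idempotent.
#'
#' @param panel A panel tibble as produced by [generate_panel()] or
#'   [read_panel()].
#' @return The cleaned panel.
#' @export
clean_panel <- function(panel) {
  for (v in c(predictor_names(), "diagnosed_prevalence")) {
    if (v %in% names(panel)) panel[[v]] <- clamp(panel[[v]])
  }
  panel
}

#' Fill missing predictor cells with province means
#'
#' A blank cell is replaced by the mean of the non-missing values of the
#' same variable and year among districts of the same province; if the whole
#' province is missing for that variable-year, the national mean for that
#' variable-year is used.
#'
#' @param panel A panel tibble with possible `NA` predictor cells.
#' @return The imputed panel.
#' @export
impute_province_means <- function(panel) {
  vars <- intersect(predictor_names(), names(panel))
  for (v in vars) {
    if (!anyNA(panel[[v]])) next
    sym <- rlang::sym(v)
    panel <- panel |>
      dplyr::group_by(.data$year) |>
      dplyr::mutate(.nat = mean(!!sym, na.rm = TRUE)) |>
      dplyr::group_by(.data$province_id, .data$year) |>
      dplyr::mutate(
        .prov = mean(!!sym, na.rm = TRUE),
        !!sym := dplyr::coalesce(!!sym,
                                 ifelse(is.nan(.data$.prov), .data$.nat,
                                        .data$.prov))) |>
      dplyr::ungroup() |>
      dplyr::select(-".prov", -".nat")
  }
  panel
}
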