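#' Trend models for predictor dynamization
#'
#' A `trend_model` is the per-variable rule that turns history into future
#' values: `linear` (least-squares slope extrapolated from an anchor year),
#' `frozen` (held at the anchor value), `fixed` (a constant, used by
#' scenario overrides), or `random_normal` (Normal around an observed mean,
#' used for the two SPM coverages whose short reporting series do not
#' support a trend).
#'
#' @param variable Variable name.
#' @param kind One of `"linear"`, `"frozen"`, `"fixed"`, `"random_normal"`.
#' @param slope Slope in percentage points per year (linear).
#' @param anchor_year,anchor_value Latest observed year and its value
#'   (linear, frozen).
#' @param mean,sd Mean and sample SD in percent (random_normal).
#' @param fixed_value Constant value in percent (fixed).
#' @return An object of class `trend_model`.
#' @export
trend_model <- function(variable, kind = c("linear", "frozen", "fixed",
                                           "random_normal"),
                        slope = NA_real_, anchor_year = NA_integer_,
                        anchor_value = NA_real_, mean = NA_real_,
                        sd = NA_real_, fixed_value = NA_real_) {
  kind <- match.arg(kind)
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0")
  structure(list(variable = variable, kind = kind, slope = slope,
                 anchor_year = as.integer(anchor_year),
                 anchor_value = anchor_value, mean = mean, sd = sd,
                 fixed_value = fixed_value,
                 override_start = NULL, original = NULL),
            class = "trend_model")
}

#' Fit a linear trend to a short historical series
#'
#' Least-squares slope over the observed years; the anchor is the latest
#' observed year and its observed value, so extrapolation continues from
#' the last measurement.
#'
#' @param years Observation years.
#' @param values Observed values (%).
#' @param variable Variable name carried into the result.
#' @return A `linear` [trend_model()].
#' @export
fit_trend <- function(years, values, variable = NA_character_) {
  ok <- stats::complete.cases(years, values)
  years <- years[ok]; values <- values[ok]
  if (length(unique(years)) < 2) {
    stop("need >= 2 distinct years to fit a linear trend; ",
         "use a frozen or random_normal trend instead")
  }
  slope <- unname(stats::coef(stats::lm(values ~ years))[["years"]])
  i <- which.max(years)
  trend_model(variable, "linear", slope = slope,
              anchor_year = years[i], anchor_value = values[i])
}

#' Fit a random-normal rule to a short series
#'
#' Mean and sample standard deviation (n - 1 denominator) of the observed
#' values, for variables projected as draws around their recent average.
#'
#' @inheritParams fit_trend
#' @return A `random_normal` [trend_model()].
#' @export
fit_random_normal <- function(values, variable = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 values")
  trend_model(variable, "random_normal",
              mean = mean(values),
              sd = stats::sd(values))
}

#' Evaluate a trend at one or more future years
#'
#' Linear trends extrapolate from the anchor; frozen/fixed trends are
#' constant; random-normal trends return their mean in deterministic mode
#' (the default) or one draw per year in stochastic mode. Every result is
#' truncated into `[0, 100]`. If the trend carries a scenario override, the
#' original rule is used for years before the override's start year.
#'
#' @param trend A [trend_model()].
#' @param year Integer vector of years.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param rng In stochastic mode, a function `(n, mean, sd)` returning `n`
#'   draws (e.g. [stats::rnorm]); required there, ignored otherwise.
#' @return Numeric vector of values in `[0, 100]`, one per year.
#' @export
value_at <- function(trend, year, mode = c("deterministic", "stochastic"),
                     rng = NULL) {
  mode <- match.arg(mode)
  if (!is.null(trend$override_start) && !is.null(trend$original)) {
    pre <- year < trend$override_start
    out <- numeric(length(year))
    if (any(pre)) {
      out[pre] <- value_at(trend$original, year[pre], mode, rng)
    }
    if (any(!pre)) {
      bare <- trend; bare$override_start <- NULL; bare$original <- NULL
      out[!pre] <- value_at(bare, year[!pre], mode, rng)
    }
    return(out)
  }
  raw <- switch(
    trend$kind,
    linear = trend$anchor_value + trend$slope * (year - trend$anchor_year),
    frozen = rep(trend$anchor_value, length(year)),
    fixed = rep(trend$fixed_value, length(year)),
    random_normal = {
      if (mode == "stochastic") {
        if (is.null(rng)) {
          stop("random_normal trend in stochastic mode requires an rng")
        }
        rng(length(year), trend$mean, trend$sd)
      } else {
        rep(trend$mean, length(year))
      }
    })
  clamp(raw)
}

#' Intervention scenarios
#'
#' Scenario 1 is the no-intervention baseline. Scenario 2 forces the
#' coverage of villages with an active Posbindu and of the SPM diabetes
#' service to 100%. Scenario 3 additionally freezes the four positive-slope
#' risk factors (overweight, obesity, central obesity, fatty-food
#' consumption) at their last observed (anchor) values.
#'
#' @param id Scenario id: 1, 2 or 3.
#' @param start_year First projection year the overrides apply from
#'   (default 2020).
#' @return A list with class `scenario_spec`: `id`, `label`, `overrides`
#'   (named list; `"fixed_100"` or `"frozen"`), `start_year`.
#' @export
scenario_spec <- function(id, start_year = 2020L) {
  id <- as.integer(id)
  if (!id %in% 1:3) stop("scenario id must be 1, 2 or 3")
  overrides <- switch(
    id,
    `1` = list(),
    `2` = list(village_posbindu = "fixed_100", spm_dm_service = "fixed_100"),
    `3` = list(village_posbindu = "fixed_100", spm_dm_service = "fixed_100",
               overweight = "frozen", obesity = "frozen",
               central_obesity = "frozen", fatty_food = "frozen"))
  label <- c("no intervention",
             "programme intervention (village Posbindu + SPM DM service at 100%)",
             "programme intervention + risk factors frozen at anchor year")[id]
  structure(list(id = id, label = label, overrides = overrides,
                 start_year = as.integer(start_year)),
            class = "scenario_spec")
}

#' Apply a scenario's overrides to a set of trends
#'
#' Returns the trend set with overridden variables replaced from the
#' scenario's start year onward; years before the start year still follow
#' the original trend. Frozen overrides take their value from the original
#' trend's anchor.
#'
#' @param trends Named list of [trend_model()]s, one per variable.
#' @param scenario A [scenario_spec()].
#' @return Named list of trend models.
#' @export
apply_scenario <- function(trends, scenario) {
  for (v in names(scenario$overrides)) {
    if (!v %in% names(trends)) {
      stop("scenario overrides unknown variable '", v, "'")
    }
    old <- trends[[v]]
    new <- switch(
      scenario$overrides[[v]],
      fixed_100 = trend_model(v, "fixed", fixed_value = 100),
      frozen = {
        if (is.na(old$anchor_value)) {
          stop("cannot freeze '", v, "': its trend has no anchor value")
        }
        trend_model(v, "frozen", anchor_year = old$anchor_year,
                    anchor_value = old$anchor_value)
      },
      stop("unknown override kind for '", v, "'"))
    new$override_start <- scenario$start_year
    new$original <- old
    trends[[v]] <- new
  }
  trends
}

#' Fit the full trend set for every district in a panel
#'
#' Risk factors get linear trends over the survey years; programme
#' coverages get linear trends over the programme-reporting years, except
#' the two SPM coverages which get random-normal rules over the SPM years.
#'
#' @param panel District-year panel.
#' @param survey_years,program_years,spm_years Observation windows.
#' @return Named list: `trends[[district_id]][[variable]]` is a
#'   [trend_model()].
#' @export
fit_panel_trends <- function(panel,
                             survey_years = c(2007L, 2013L, 2018L),
                             program_years = 2016:2020,
                             spm_years = 2019:2021) {
  spm_vars <- c("spm_dm_service", "spm_screening")
  rf <- risk_factor_names()
  linear_programs <- setdiff(program_names(), spm_vars)
  out <- list()
  for (d in unique(panel$district_id)) {
    sub <- panel[panel$district_id == d, ]
    tr <- list()
    for (v in rf) {
      s <- sub[sub$year %in% survey_years, ]
      tr[[v]] <- fit_trend(s$year, s[[v]], v)
    }
    for (v in linear_programs) {
      s <- sub[sub$year %in% program_years, ]
      tr[[v]] <- fit_trend(s$year, s[[v]], v)
    }
    for (v in spm_vars) {
      s <- sub[sub$year %in% spm_years, ]
      tr[[v]] <- fit_random_normal(s[[v]], v)
    }
    out[[d]] <- tr
  }
  out
}

#' Serialize a trend set to a tidy tibble (and back)
#'
#' @param trends Output of [fit_panel_trends()].
#' @return A tibble with one row per district-variable.
#' @export
trends_to_table <- function(trends) {
  dplyr::bind_rows(lapply(names(trends), function(d) {
    dplyr::bind_rows(lapply(trends[[d]], function(t) tibble::tibble(
      district_id = d, variable = t$variable, kind = t$kind,
      slope = t$slope, anchor_year = t$anchor_year,
      anchor_value = t$anchor_value, mean = t$mean, sd = t$sd,
      fixed_value = t$fixed_value)))
  }))
}

#' @rdname trends_to_table
#' @param table A tibble as produced by [trends_to_table()].
#' @export
table_to_trends <- function(table) {
  out <- list()
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    out[[r$district_id]][[r$variable]] <- trend_model(
      r$variable, r$kind, slope = r$slope, anchor_year = r$anchor_year,
      anchor_value = r$anchor_value, mean = r$mean, sd = r$sd,
      fixed_value = r$fixed_value)
  }
  out
}
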