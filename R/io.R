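#' Read and write district panels
#'
#' CSV, one row per district-year, canonical columns: `district_id`,
#' `province_id`, `year`, the 18 predictors, `diagnosed_prevalence` and
#' optionally `pop15plus`. Reading validates the presence of the canonical
#' columns and basic ranges.
#'
#' @param path File path.
#' @return [read_panel()]: the panel tibble. [write_panel()]: `path`,
#'   invisibly.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(panel_id_cols(), predictor_names(), "diagnosed_prevalence")
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop("panel file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (v in c(predictor_names(), "diagnosed_prevalence")) {
    bad <- which(!is.na(panel[[v]]) & (panel[[v]] < 0 | panel[[v]] > 100))
    if (length(bad)) {
      stop("panel file '", path, "', column '", v, "': value out of [0, 100] ",
           "at row ", bad[1], " (run clean_panel() on raw exports first)")
    }
  }
  panel
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Read and write population projections
#'
#' CSV with columns `district_id`, `year`, `pop15plus`.
#'
#' @param path File path.
#' @export
read_population <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("district_id", "year", "pop15plus"), names(pop))
  if (length(missing)) {
    stop("population file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(pop$pop15plus <= 0)
  if (length(bad)) {
    stop("population file '", path, "': non-positive pop15plus at row ", bad[1])
  }
  pop
}

#' @rdname read_population
#' @param population Population tibble.
#' @export
write_population <- function(population, path) {
  readr::write_csv(population, path)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' YAML with flat keys; anything omitted falls back to the package
#' defaults. Recognised keys mirror the arguments of [generator_config()],
#' [burden_assumptions()], [calibration_spec()], [selection_thresholds()],
#' [validation_thresholds()] plus `years_start`, `years_end`, `scenarios`,
#' `mode`, `n_replicates`, `seed`.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file '", path, "' is not a key-value map")
  cfg
}

#' Run the whole pipeline
#'
#' A programmatic driver chaining the stages: `simulate` (synthetic panel +
#' population), `build` (screen, fit, eliminate, check; writes the model
#' and the elimination log), `project` (scenarios 1-3; tidy and wide
#' tables), `validate` (MAPE + recovery), or `all`. Every run writes a
#' `run_log.txt` recording the seed and settings, so a run can be
#' reproduced from its log.
#'
#' @param out_dir Output directory (created if needed).
#' @param steps Character vector of stages, or `"all"`.
#' @param config Optional named list of overrides (see [read_config()]).
#' @param seed Root seed; overrides `config$seed`.
#' @return Invisibly, a list with the in-memory artifacts of the stages run.
#' @export
run_pipeline <- function(out_dir, steps = "all", config = list(), seed = NULL) {
  if ("all" %in% steps) steps <- c("simulate", "build", "project", "validate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)

  gen_keys <- intersect(names(config), names(formals(generator_config)))
  gcfg <- do.call(generator_config, c(config[gen_keys], list(seed = seed)))
  years <- seq(config$years_start %||% 2020L, config$years_end %||% 2045L)
  scenarios <- config$scenarios %||% 1:3
  mode <- config$mode %||% "deterministic"

  log_lines <- c(
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("dmproj version:", as.character(utils::packageVersion("dmproj"))),
    paste("R version:", R.version.string),
    paste("seed:", seed),
    paste("steps:", paste(steps, collapse = ", ")),
    paste("mode:", mode),
    paste("years:", min(years), "-", max(years)),
    paste("scenarios:", paste(scenarios, collapse = ", ")),
    "config:",
    paste0("  ", names(config), " = ",
           vapply(config, function(x) paste(format(x), collapse = " "),
                  character(1))))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  art <- list(config = gcfg, seed = seed)

  panel_path <- file.path(out_dir, "panel.csv")
  pop_path <- file.path(out_dir, "population.csv")
  if ("simulate" %in% steps) {
    art$panel <- generate_panel(gcfg)
    art$population <- generate_population(gcfg, years)
    write_panel(art$panel, panel_path)
    write_population(art$population, pop_path)
  } else {
    if (!file.exists(panel_path)) {
      stop("panel file missing: ", panel_path, " (run the simulate step first)")
    }
    art$panel <- read_panel(panel_path)
    art$population <- read_population(pop_path)
  }

  model_path <- file.path(out_dir, "model.txt")
  if ("build" %in% steps) {
    cross <- art$panel[art$panel$year == max(gcfg$survey_years), ]
    art$build <- build_model(cross)
    write_model(art$build$model, model_path)
    readr::write_csv(art$build$log, file.path(out_dir, "elimination_log.csv"))
    readr::write_csv(art$build$assumptions,
                     file.path(out_dir, "assumption_report.csv"))
  }

  if ("project" %in% steps) {
    if (!is.null(art$build)) {
      model <- art$build$model
    } else if (file.exists(model_path)) {
      model <- read_model(model_path)
    } else {
      stop("model missing: ", model_path, " (run the build step first)")
    }
    trends <- fit_panel_trends(art$panel, gcfg$survey_years,
                               gcfg$program_years, gcfg$spm_years)
    calib <- calibration_factor(art$panel,
                                calibration_spec(
                                  config$measured_national_prevalence %||% 8.5,
                                  config$reference_year %||% 2018L))
    art$results <- run_projection(
      art$panel, model, trends, art$population,
      assumptions = burden_assumptions(), calibration = calib,
      scenarios = scenarios, years = years, mode = mode,
      n_replicates = config$n_replicates %||% 1L, seed = seed)
    readr::write_csv(round_for_report(
      art$results[art$results$level != "district", ]),
      file.path(out_dir, "projection_summary.csv"))
    readr::write_csv(round_for_report(art$results),
                     file.path(out_dir, "projection_tidy.csv"))
    readr::write_csv(wide_table(art$results, "prevalence", "province", 1),
                     file.path(out_dir, "table_prevalence_by_province.csv"))
    readr::write_csv(wide_table(art$results, "cases", "province", 1),
                     file.path(out_dir, "table_cases_by_province.csv"))
    readr::write_csv(wide_table(art$results, "deaths_dm", "province", 1),
                     file.path(out_dir, "table_deaths_by_province.csv"))
  }

  if ("validate" %in% steps) {
    art$recovery <- recovery_experiment(gcfg,
                                        n_replicates = config$n_replicates %||% 5L)
    readr::write_csv(art$recovery$per_replicate,
                     file.path(out_dir, "validation_replicates.csv"))
    readr::write_csv(art$recovery$coefficients,
                     file.path(out_dir, "validation_coefficients.csv"))
    thr <- validation_thresholds()
    s <- art$recovery$summary
    writeLines(c(
      "validation summary",
      sprintf("  replicates: %d", s$n_replicates),
      sprintf("  mean coefficient RMSE: %.6f", s$mean_coef_rmse),
      sprintf("  mean abs relative error (|beta| >= 0.1): %.2f%%",
              100 * s$mean_abs_rel_error),
      sprintf("  mean held-out district MAPE: %.2f%% (threshold %.0f%%)",
              s$mean_holdout_mape, thr$mape_district)),
      file.path(out_dir, "validation_summary.txt"))
  }

  invisible(art)
}
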