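#' Canonical predictor names
#'
#' The district panel carries 18 candidate predictors of diagnosed diabetes
#' prevalence: 10 behavioural/clinical risk-factor prevalences and 8
#' NCD-programme coverages, all in percent. These vectors fix the canonical
#' column names used throughout the package.
#'
#' @return Character vector of variable names.
#' @export
risk_factor_names <- function() {
  c("overweight", "obesity", "central_obesity", "sweet_food",
    "sugary_beverage", "fatty_food", "low_fruit_veg",
    "low_physical_activity", "smoking", "hypertension")
}

#' @rdname risk_factor_names
#' @export
program_names <- function() {
  c("posbindu", "village_posbindu", "posbindu_examination", "pandu",
    "prolanis", "routine_blood_glucose", "spm_dm_service", "spm_screening")
}

#' @rdname risk_factor_names
#' @export
predictor_names <- function() {
  c(risk_factor_names(), program_names())
}

# Panel columns other than the predictors.
panel_id_cols <- function() c("district_id", "province_id", "year")

#' Default district prevalence model
#'
#' The package ships a nine-term linear equation for diagnosed diabetes
#' prevalence (%) fitted on 205 Indonesian districts: four risk factors
#' (overweight, obesity, central obesity, fatty-food consumption) and five
#' programme coverages (villages with an active Posbindu, Pandu, routine
#' blood-glucose checking, SPM diabetes services, SPM productive-age
#' screening), with R-squared 0.571. It is the default "truth" for the
#' synthetic generator and the default model for projections.
#'
#' @return A [dm_model] object.
#' @examples
#' m <- default_model()
#' predict(m, setNames(numeric(9), names(coef(m))[-1]))  # intercept only
#' @export
default_model <- function() {
  dm_model(
    intercept = -1.212,
    coefficients = c(
      overweight            =  0.216,
      obesity               =  0.017,
      central_obesity       =  0.112,
      fatty_food            =  0.019,
      village_posbindu      = -0.001,
      pandu                 =  0.003,
      routine_blood_glucose =  1.510,
      spm_dm_service        = -0.012,
      spm_screening         =  0.008
    ),
    r_squared = 0.571,
    n_obs = 205L
  )
}

# Clamp a numeric vector into [lo, hi]; NA passes through.
clamp <- function(x, lo = 0, hi = 100) pmin(pmax(x, lo), hi)

# round() half-up for report writing (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)
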