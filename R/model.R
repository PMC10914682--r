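#' Linear prevalence model
#'
#' A light container for an affine district-prevalence model: an intercept
#' plus named slopes (percentage points of diagnosed prevalence per
#' percentage point of predictor), with optional fit diagnostics.
#'
#' @param intercept Numeric scalar, percent.
#' @param coefficients Named numeric vector of slopes. Models used against
#'   district panels name their slopes from [predictor_names()]; the
#'   container itself accepts any names so the fitting machinery stays
#'   usable on arbitrary regressions.
#' @param r_squared Coefficient of determination in `[0, 1]`, or `NA`.
#' @param p_values Named numeric vector of per-coefficient p-values, or `NULL`.
#' @param n_obs Number of observations behind the fit, or `NA`.
#' @param fit The underlying [stats::lm] fit, kept for residual-based
#'   assumption checks; optional.
#'
#' @return An object of class `dm_model`.
#' @export
dm_model <- function(intercept, coefficients, r_squared = NA_real_,
                     p_values = NULL, n_obs = NA_integer_, fit = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared must lie in [0, 1], got ", r_squared)
  }
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         r_squared = r_squared, p_values = p_values,
         n_obs = as.integer(n_obs), fit = fit),
    class = "dm_model"
  )
}

#' @export
coef.dm_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.dm_model <- function(x, ...) {
  cat("<dm_model> diagnosed prevalence (%) =", format(x$intercept), "\n")
  for (nm in names(x$coefficients)) {
    b <- x$coefficients[[nm]]
    cat(sprintf("  %+0.4g * %s\n", b, nm))
  }
  cat(sprintf("R-squared: %s   n: %s\n",
              ifelse(is.na(x$r_squared), "NA", format(x$r_squared)),
              ifelse(is.na(x$n_obs), "NA", x$n_obs)))
  invisible(x)
}

#' Predict diagnosed prevalence from a prevalence model
#'
#' Evaluates the affine equation `intercept + sum(coef * value)`. The result
#' is deliberately not clamped to `[0, 100]`; clamping is applied by the
#' projection step after calibration.
#'
#' @param object A [dm_model].
#' @param newdata Named numeric vector, one-row data frame, or data frame of
#'   predictor values in percent. Every model predictor must be present.
#' @param ... Unused.
#'
#' @return Numeric vector of predicted diagnosed prevalences (%).
#' @examples
#' m <- default_model()
#' predict(m, c(overweight = 13.6, obesity = 21.8, central_obesity = 31,
#'              fatty_food = 40, village_posbindu = 50, pandu = 40,
#'              routine_blood_glucose = 3, spm_dm_service = 70,
#'              spm_screening = 50))
#' @export
predict.dm_model <- function(object, newdata, ...) {
  vars <- names(object$coefficients)
  if (is.data.frame(newdata)) {
    missing <- setdiff(vars, names(newdata))
    if (length(missing)) {
      stop("missing predictor(s): ", paste(missing, collapse = ", "))
    }
    x <- as.matrix(newdata[vars])
  } else {
    missing <- setdiff(vars, names(newdata))
    if (length(missing)) {
      stop("missing predictor(s): ", paste(missing, collapse = ", "))
    }
    x <- matrix(as.numeric(newdata[vars]), nrow = 1,
                dimnames = list(NULL, vars))
  }
  drop(object$intercept + x %*% object$coefficients[vars])
}

#' Serialize a prevalence model to a flat key-value text file
#'
#' One `key = value` pair per line: the intercept, each slope under its
#' predictor name, and the diagnostics `r_squared` / `n_obs`.
#'
#' @param model A [dm_model].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  lines <- c(
    sprintf("intercept = %.17g", model$intercept),
    sprintf("%s = %.17g", names(model$coefficients), model$coefficients),
    sprintf("r_squared = %.17g", model$r_squared),
    sprintf("n_obs = %d", model$n_obs)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- grep("=", trimws(readLines(path)), fixed = TRUE, value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  vals <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  special <- c("intercept", "r_squared", "n_obs")
  dm_model(
    intercept    = vals[["intercept"]],
    coefficients = vals[setdiff(names(vals), special)],
    r_squared    = if ("r_squared" %in% names(vals)) vals[["r_squared"]] else NA_real_,
    n_obs        = if ("n_obs" %in% names(vals)) as.integer(vals[["n_obs"]]) else NA_integer_
  )
}
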