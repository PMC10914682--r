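#' Selection thresholds for model building
#'
#' @param bivariate_alpha Screening level for the bivariate correlation test
#'   (default 0.25): candidates with correlation p below it enter the full
#'   model.
#' @param retention_alpha Level above which a full-model predictor becomes a
#'   removal candidate during backward elimination (default 0.05).
#' @param confounding_delta Relative change in any remaining coefficient or
#'   in R-squared that marks a removed variable as a confounder to be
#'   restored (default 0.10).
#' @return A list with class `selection_thresholds`.
#' @export
selection_thresholds <- function(bivariate_alpha = 0.25,
                                 retention_alpha = 0.05,
                                 confounding_delta = 0.10) {
  vals <- c(bivariate_alpha, retention_alpha, confounding_delta)
  if (any(vals <= 0 | vals >= 1)) {
    stop("all selection thresholds must lie in (0, 1)")
  }
  structure(list(bivariate_alpha = bivariate_alpha,
                 retention_alpha = retention_alpha,
                 confounding_delta = confounding_delta),
            class = "selection_thresholds")
}

#' Bivariate screening by correlation
#'
#' Tests each candidate's Pearson correlation with the outcome (two-sided t
#' test) and retains those with p below `thresholds$bivariate_alpha`. A
#' liberal screening level is used on purpose so weak predictors still reach
#' the multivariable stage. Zero-variance candidates are dropped with a
#' warning rather than an error.
#'
#' @param panel Data frame of district-year observations.
#' @param outcome Name of the outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param thresholds A [selection_thresholds()].
#' @return Character vector of retained candidates, input order preserved,
#'   with the per-candidate p-values in attribute `"p_values"`.
#' @export
bivariate_screen <- function(panel, outcome, candidates,
                             thresholds = selection_thresholds()) {
  y <- panel[[outcome]]
  keep <- character(0)
  pvals <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  for (v in candidates) {
    x <- panel[[v]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) stop("need >= 3 complete observations for ", v)
    if (stats::sd(x[ok]) == 0) {
      warning("candidate '", v, "' has zero variance; excluded from screening")
      next
    }
    pvals[[v]] <- stats::cor.test(x[ok], y[ok])$p.value
    if (pvals[[v]] < thresholds$bivariate_alpha) keep <- c(keep, v)
  }
  structure(keep, p_values = pvals)
}

#' Ordinary least squares fit of the prevalence equation
#'
#' Fits `outcome ~ predictors` by least squares and packages the result as a
#' [dm_model] (intercept, slopes, R-squared, per-coefficient p-values), with
#' the underlying [stats::lm] object kept for assumption checks.
#'
#' @inheritParams bivariate_screen
#' @param predictors Character vector of predictor columns.
#' @return A [dm_model].
#' @export
fit_ols <- function(panel, outcome, predictors) {
  dat <- panel[stats::complete.cases(panel[c(outcome, predictors)]),
               c(outcome, predictors), drop = FALSE]
  if (nrow(dat) <= length(predictors) + 1L) {
    stop("need more observations (", nrow(dat), ") than parameters (",
         length(predictors) + 1L, ")")
  }
  x <- cbind(1, as.matrix(dat[predictors]))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", outcome))
  fit <- stats::lm(fml, data = dat)
  sm <- summary(fit)
  cf <- stats::coef(fit)
  dm_model(
    intercept = cf[["(Intercept)"]],
    coefficients = cf[setdiff(names(cf), "(Intercept)")],
    r_squared = sm$r.squared,
    p_values = sm$coefficients[setdiff(names(cf), "(Intercept)"), 4],
    n_obs = nrow(dat),
    fit = fit
  )
}

#' Backward elimination with confounder retention
#'
#' Starting from the full model, repeatedly takes the still-removable
#' predictor with the largest p-value above `retention_alpha` (ties broken
#' by larger p, then alphabetically) and refits without it. If the trial
#' removal changes any remaining coefficient by at least
#' `confounding_delta` (relative) or drops R-squared by at least
#' `confounding_delta` (relative), the variable is judged a confounder and
#' restored — and not reconsidered; otherwise it stays excluded. Stops when
#' no removable predictor remains.
#'
#' @inheritParams bivariate_screen
#' @param full_predictors Predictors of the full model.
#' @return List with `model` (the final [dm_model]) and `log` (a tibble with
#'   one row per trial removal: variable, its p-value, the action taken, the
#'   R-squared before/after, and the largest relative coefficient change).
#' @export
backward_eliminate <- function(panel, outcome, full_predictors,
                               thresholds = selection_thresholds()) {
  current <- full_predictors
  locked <- character(0)  # restored confounders, never re-tried
  model <- fit_ols(panel, outcome, current)
  log <- list()

  repeat {
    pv <- model$p_values
    # NaN p-values (e.g. a saturated zero-residual fit) are not removable
    removable <- setdiff(names(pv)[!is.na(pv) & pv > thresholds$retention_alpha],
                         locked)
    if (!length(removable)) break
    # largest p first; alphabetical on exact ties
    ord <- order(-pv[removable], removable)
    victim <- removable[ord[1]]

    remaining <- setdiff(current, victim)
    if (!length(remaining)) break
    trial <- fit_ols(panel, outcome, remaining)

    shared <- intersect(names(model$coefficients), names(trial$coefficients))
    rel_b <- abs(trial$coefficients[shared] - model$coefficients[shared]) /
      pmax(abs(model$coefficients[shared]), .Machine$double.eps)
    rel_r2 <- (model$r_squared - trial$r_squared) /
      max(model$r_squared, .Machine$double.eps)
    confounded <- max(rel_b, 0) >= thresholds$confounding_delta ||
      rel_r2 >= thresholds$confounding_delta

    log[[length(log) + 1L]] <- tibble::tibble(
      variable = victim, p_value = unname(pv[victim]),
      action = if (confounded) "kept as confounder" else "removed",
      r_squared_before = model$r_squared, r_squared_after = trial$r_squared,
      max_rel_coef_change = if (length(shared)) max(rel_b) else NA_real_)

    if (confounded) {
      locked <- c(locked, victim)
    } else {
      current <- remaining
      model <- trial
    }
  }

  list(model = model,
       log = if (length(log)) dplyr::bind_rows(log) else tibble::tibble(
         variable = character(), p_value = numeric(), action = character(),
         r_squared_before = numeric(), r_squared_after = numeric(),
         max_rel_coef_change = numeric()))
}

#' Regression assumption checks
#'
#' Runs the six classical checks on a fitted prevalence model: existence
#' (outcome variance > 0), independence (Durbin-Watson statistic in
#' `[1.5, 2.5]`), linearity (Tukey-style curvature test: quadratic term of
#' residuals on fitted values not significant), homoscedasticity
#' (Breusch-Pagan p > 0.05), normality of residuals (Shapiro-Wilk
#' p > 0.05), and collinearity (all variance inflation factors < 10,
#' computed by auxiliary regressions so perfectly collinear columns yield an
#' infinite VIF and a clean failure). A check whose statistic cannot be
#' computed — e.g. Shapiro-Wilk on numerically zero residuals — is reported
#' as not evaluable.
#'
#' @param model A [dm_model] from [fit_ols()] (must carry its `lm` fit).
#' @param panel The panel the model was fitted on.
#' @return Tibble with columns `test`, `statistic`, `p_value`, `criterion`,
#'   `pass` (logical; `NA` = not evaluable).
#' @export
check_assumptions <- function(model, panel) {
  if (is.null(model$fit)) stop("model carries no lm fit; refit with fit_ols()")
  fit <- model$fit
  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  preds <- names(model$coefficients)
  outcome <- all.vars(stats::formula(fit))[1]
  degenerate <- stats::sd(res) < 1e-10

  rows <- list()
  add <- function(test, statistic, p_value, criterion, pass) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      test = test, statistic = statistic, p_value = p_value,
      criterion = criterion, pass = pass)
  }

  v <- stats::var(panel[[outcome]], na.rm = TRUE)
  add("existence", v, NA_real_, "outcome variance > 0", v > 0)

  dw <- tryCatch(lmtest::dwtest(fit), error = function(e) NULL)
  if (is.null(dw) || degenerate) {
    add("independence", NA_real_, NA_real_, "Durbin-Watson in [1.5, 2.5]", NA)
  } else {
    add("independence", unname(dw$statistic), dw$p.value,
        "Durbin-Watson in [1.5, 2.5]",
        dw$statistic >= 1.5 && dw$statistic <= 2.5)
  }

  if (degenerate || stats::sd(fitted) < 1e-10) {
    add("linearity", NA_real_, NA_real_, "no curvature (quadratic p > 0.05)", NA)
  } else {
    curv <- stats::lm(res ~ fitted + I(fitted^2))
    p <- stats::coef(summary(curv))["I(fitted^2)", 4]
    add("linearity", stats::coef(curv)[["I(fitted^2)"]], p,
        "no curvature (quadratic p > 0.05)", p > 0.05)
  }

  bp <- tryCatch(lmtest::bptest(fit), error = function(e) NULL)
  if (is.null(bp) || degenerate) {
    add("homoscedasticity", NA_real_, NA_real_, "Breusch-Pagan p > 0.05", NA)
  } else {
    add("homoscedasticity", unname(bp$statistic), bp$p.value,
        "Breusch-Pagan p > 0.05", bp$p.value > 0.05)
  }

  sw <- if (degenerate || length(res) < 3 || length(res) > 5000) NULL else
    tryCatch(stats::shapiro.test(res), error = function(e) NULL)
  if (is.null(sw)) {
    add("normality", NA_real_, NA_real_, "Shapiro-Wilk p > 0.05", NA)
  } else {
    add("normality", unname(sw$statistic), sw$p.value,
        "Shapiro-Wilk p > 0.05", sw$p.value > 0.05)
  }

  vifs <- vif_values(panel, preds)
  add("collinearity", max(vifs), NA_real_, "all VIF < 10",
      all(is.finite(vifs)) && max(vifs) < 10)

  out <- dplyr::bind_rows(rows)
  attr(out, "vif") <- vifs
  out
}

# VIF_j = 1 / (1 - R^2 of predictor j on the other predictors), computed by
# auxiliary regressions; an aliased column gives R^2 = 1 and VIF = Inf.
vif_values <- function(panel, predictors) {
  if (length(predictors) < 2) {
    return(stats::setNames(rep(1, length(predictors)), predictors))
  }
  dat <- panel[stats::complete.cases(panel[predictors]), predictors,
               drop = FALSE]
  vapply(predictors, function(v) {
    others <- setdiff(predictors, v)
    aux <- stats::lm(
      stats::reformulate(sprintf("`%s`", others), response = sprintf("`%s`", v)),
      data = dat)
    # an aliased column makes this fit exact; the perfect-fit warning is
    # the expected signal, not a problem to surface
    r2 <- suppressWarnings(summary(aux)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Full model-building procedure
#'
#' Convenience wrapper chaining [bivariate_screen()], the full-model
#' [fit_ols()], [backward_eliminate()] and [check_assumptions()].
#'
#' @inheritParams bivariate_screen
#' @return List with `screened`, `full_model`, `model`, `log`, `assumptions`.
#' @export
build_model <- function(panel, outcome = "diagnosed_prevalence",
                        candidates = predictor_names(),
                        thresholds = selection_thresholds()) {
  screened <- bivariate_screen(panel, outcome, candidates, thresholds)
  full <- fit_ols(panel, outcome, as.character(screened))
  elim <- backward_eliminate(panel, outcome, as.character(screened), thresholds)
  list(screened = screened, full_model = full, model = elim$model,
       log = elim$log,
       assumptions = check_assumptions(elim$model, panel))
}
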