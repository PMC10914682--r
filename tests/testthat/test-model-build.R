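test_that("bivariate screening retains correlated and drops null candidates", {
  set.seed(1)
  panel <- tibble::tibble(
    y = rnorm(100, 10, 2),
    dup = NA_real_, flat = 5)
  panel$dup <- panel$y                     # identical to the outcome
  panel$indep <- rnorm(100)

  expect_warning(
    keep <- bivariate_screen(panel, "y", c("dup", "flat", "indep")),
    "zero variance")
  expect_true("dup" %in% keep)             # p ~ 0 for a perfect correlate
  expect_false("flat" %in% keep)           # constant: excluded, not an error
  pv <- attr(keep, "p_values")
  expect_lt(pv[["dup"]], 1e-10)
})

test_that("screening at alpha 0.25 retains an independent candidate in ~25% of replicates", {
  set.seed(99)
  hits <- vapply(seq_len(1000), function(i) {
    panel <- tibble::tibble(y = rnorm(50), x = rnorm(50))
    "x" %in% bivariate_screen(panel, "y", "x")
  }, logical(1))
  expect_equal(mean(hits), 0.25, tolerance = 0.2)  # +-0.05 absolute
})

test_that("fit_ols reproduces exact generating equations", {
  x <- seq(0, 10, length.out = 25)
  panel <- tibble::tibble(x = x, y = 2 + 3 * x)
  m <- suppressWarnings(fit_ols(panel, "y", "x"))
  expect_equal(m$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(m$coefficients[["x"]]), 3, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("fit_ols r_squared equals 1 - SSE/SST computed by brute force", {
  dat <- sim_regression(80, c(a = 1.5, b = -0.7), noise_sd = 2, seed = 7)
  names(dat) <- c("y", "a", "b")
  m <- fit_ols(dat, "y", c("a", "b"))
  pred <- m$intercept + as.matrix(dat[c("a", "b")]) %*% m$coefficients
  sse <- sum((dat$y - pred)^2)
  sst <- sum((dat$y - mean(dat$y))^2)
  expect_equal(m$r_squared, 1 - sse / sst, tolerance = 1e-12)
})

test_that("fit_ols errors on rank-deficient designs naming the columns", {
  dat <- sim_regression(50, c(a = 1, b = 2), seed = 3)
  names(dat) <- c("y", "a", "b")
  dat$c <- dat$a
  expect_error(fit_ols(dat, "y", c("a", "b", "c")), "collinear.*c")
})

test_that("zero-noise synthetic panel round-trips the default equation", {
  cfg <- small_config(noise_sd = 0)
  panel <- generate_panel(cfg)
  cross <- panel[panel$year == 2018, ]
  m <- suppressWarnings(fit_ols(cross, "diagnosed_prevalence",
                                default_predictors()))
  expect_equal(coef(m), coef(default_model()), tolerance = 1e-8)
})

test_that("backward elimination removes a pure-noise predictor almost always", {
  betas <- c(x1 = 2, x2 = -1.5, x3 = 0.8, x4 = 1.2, noise = 0)
  removed <- vapply(seq_len(50), function(s) {
    dat <- sim_regression(205, betas, noise_sd = 1, seed = 1000 + s)
    names(dat) <- c("y", names(betas))
    out <- backward_eliminate(dat, "y", names(betas))
    !"noise" %in% names(out$model$coefficients)
  }, logical(1))
  expect_gte(mean(removed), 0.9)
})

test_that("elimination respects the retention level and model nesting", {
  dat <- sim_regression(205, c(x1 = 2, x2 = -1.5, x3 = 0, x4 = 0, x5 = 0.02),
                        noise_sd = 1, seed = 15)
  names(dat) <- c("y", paste0("x", 1:5))
  full <- fit_ols(dat, "y", paste0("x", 1:5))
  out <- backward_eliminate(dat, "y", paste0("x", 1:5))

  # never removes a predictor significant at the retention level
  expect_true(all(out$log$p_value[out$log$action == "removed"] > 0.05))
  # nesting: the reduced model cannot out-fit the full model
  expect_lte(out$model$r_squared, full$r_squared + 1e-12)
  # every step is logged with before/after fit quality
  expect_true(all(c("variable", "p_value", "action", "r_squared_before",
                    "r_squared_after") %in% names(out$log)))
})

test_that("a model with all predictors significant is returned unchanged", {
  dat <- sim_regression(150, c(x1 = 3, x2 = -2), noise_sd = 0.5, seed = 8)
  names(dat) <- c("y", "x1", "x2")
  out <- backward_eliminate(dat, "y", c("x1", "x2"))
  expect_equal(nrow(out$log), 0L)
  expect_setequal(names(out$model$coefficients), c("x1", "x2"))
})

test_that("a confounder is restored when its removal shifts other coefficients", {
  # z causes both x and y: dropping z moves the coefficient of x by far
  # more than 10%, so the rule must keep z even though its p-value is
  # pushed above the retention level by a small sample + collinearity
  set.seed(1)
  n <- 60
  z <- rnorm(n)
  x <- 0.9 * z + rnorm(n, 0, 0.5)
  y <- 1 + 0.5 * x + 0.6 * z + rnorm(n, 0, 2.5)
  dat <- tibble::tibble(y = y, x = x, z = z)
  out <- backward_eliminate(dat, "y", c("x", "z"))
  kept <- out$log$action == "kept as confounder"
  expect_true(any(kept))
  expect_true(all(out$log$variable[kept] %in% names(out$model$coefficients)))
  expect_gte(max(out$log$max_rel_coef_change[kept],
                 (out$log$r_squared_before[kept] - out$log$r_squared_after[kept]) /
                   out$log$r_squared_before[kept]), 0.10)
})

test_that("assumption checks handle degenerate and collinear panels", {
  cfg <- small_config(noise_sd = 0)
  panel <- generate_panel(cfg)
  cross <- panel[panel$year == 2018, ]
  m <- suppressWarnings(fit_ols(cross, "diagnosed_prevalence",
                                default_predictors()))
  rep0 <- check_assumptions(m, cross)
  expect_setequal(rep0$test, c("existence", "independence", "linearity",
                               "homoscedasticity", "normality", "collinearity"))
  expect_equal(sum(rep0$test == "normality"), 1L)
  # zero residuals: normality is not evaluable rather than rejected
  expect_true(is.na(rep0$pass[rep0$test == "normality"]))
  expect_true(all(is.finite(attr(rep0, "vif"))))

  # duplicated predictor column: collinearity must fail, not error
  dup <- cross
  dup$obesity <- dup$overweight
  m2 <- suppressWarnings(fit_ols(dup, "diagnosed_prevalence",
                                 setdiff(default_predictors(), "obesity")))
  rep2 <- check_assumptions(
    dm_model(m2$intercept,
             c(m2$coefficients, obesity = 0)[c(default_predictors())],
             fit = m2$fit),
    dup)
  expect_false(isTRUE(rep2$pass[rep2$test == "collinearity"]))
})

test_that("the homoscedasticity check detects proportional noise", {
  rejects <- vapply(seq_len(40), function(s) {
    set.seed(3000 + s)
    x <- runif(205, 1, 10)
    mu <- 2 + 3 * x
    y <- mu + rnorm(205, 0, 0.2 * mu)   # noise SD proportional to the mean
    dat <- tibble::tibble(y = y, x = x)
    m <- fit_ols(dat, "y", "x")
    rep <- check_assumptions(m, dat)
    isFALSE(rep$pass[rep$test == "homoscedasticity"])
  }, logical(1))
  expect_gte(mean(rejects), 0.8)
})

test_that("prediction evaluates the affine equation and is strict about inputs", {
  m <- default_model()
  zeros <- setNames(numeric(9), default_predictors())
  expect_equal(predict(m, zeros), -1.212)

  vals <- c(overweight = 13.6, obesity = 21.8, central_obesity = 31.0,
            fatty_food = 40, village_posbindu = 50, pandu = 40,
            routine_blood_glucose = 3, spm_dm_service = 70,
            spm_screening = 50)
  expect_equal(predict(m, vals), 10.4882, tolerance = 1e-12)

  bump <- vals; bump[["overweight"]] <- bump[["overweight"]] + 1
  expect_equal(predict(m, bump) - predict(m, vals), 0.216, tolerance = 1e-12)

  expect_error(predict(m, vals[-1]), "overweight")

  # affinity: f(a) + f(b) - f(0) = f(a + b)
  set.seed(4)
  a <- setNames(runif(9, 0, 60), default_predictors())
  b <- setNames(runif(9, 0, 60), default_predictors())
  expect_equal(predict(m, a) + predict(m, b) - predict(m, zeros),
               predict(m, a + b), tolerance = 1e-10)
})

test_that("model serialization round-trips through the key-value format", {
  m <- default_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(coef(m2), coef(m))
  expect_equal(m2$r_squared, m$r_squared)
  expect_equal(m2$n_obs, m$n_obs)
})
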