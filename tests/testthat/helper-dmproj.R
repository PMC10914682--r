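# Small, fast generator configuration used across tests where the full
# 205-district panel is not the point.
small_config <- function(...) {
  generator_config(n_districts = 30L, n_provinces = 6L, seed = 42L, ...)
}

# Nine predictors of the shipped default equation.
default_predictors <- function() names(default_model()$coefficients)

# A quick synthetic regression data set with independent predictors.
sim_regression <- function(n, betas, intercept = 1, noise_sd = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * length(betas)), nrow = n,
              dimnames = list(NULL, names(betas)))
  y <- intercept + drop(x %*% betas) + rnorm(n, 0, noise_sd)
  tibble::tibble(y = y, tibble::as_tibble(as.data.frame(x)))
}
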