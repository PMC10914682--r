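test_that("burden accounting reproduces its defining identities", {
  a <- burden_assumptions()
  b <- burden(c(0, 1e6), a)
  expect_equal(unlist(b[1, -1]), setNames(rep(0, 7), names(b)[-1]))
  # proportions hold bit-exactly pre-rounding
  expect_equal(b$deaths_stroke[2] / b$deaths_dm[2], a$p_stroke)
  expect_equal(b$deaths_ihd[2] / b$deaths_dm[2], a$p_ihd)
  expect_equal(b$deaths_ckd[2] / b$deaths_dm[2], a$p_ckd)
  expect_equal(b$deaths_dka[2], 1e6 * a$p_dka * a$dka_mortality_72h)
  expect_equal(b$cases_neuropathy[2] / 1e6, a$p_neuropathy)

  expect_error(burden(-5), ">= 0")
  expect_error(burden_assumptions(cfr = 1.5), "cfr")
  expect_error(burden_assumptions(p_stroke = 0.5, p_ihd = 0.4, p_ckd = 0.2),
               "exceed 1")
})

test_that("cases follow prevalence times population", {
  expect_equal(cases_from_prevalence(0, 1e6), 0)
  expect_equal(cases_from_prevalence(9.19, 1e6), 91900)
  expect_error(cases_from_prevalence(5, 0), "positive")
})

test_that("projected prevalence is calibrated, clamped and trend-driven", {
  m <- default_model()
  flat <- lapply(setNames(nm = default_predictors()), function(v)
    trend_model(v, "frozen", anchor_year = 2018, anchor_value = 30))
  # flat trends with factor 1: constant across years
  prev <- project_prevalence(m, flat, 2020:2045, factor = 1)
  expect_equal(length(unique(round(prev, 12))), 1L)

  # a negative equation output is clamped to zero
  low <- lapply(flat, function(t) { t$anchor_value <- 0; t })
  low$spm_dm_service$anchor_value <- 100  # -0.012 * 100 pushes below -1.212
  expect_equal(project_prevalence(m, low, 2030, factor = 1), 0)

  expect_error(project_prevalence(m, flat[-1], 2030), "overweight")
})

test_that("aggregation conserves counts and weights prevalence by population", {
  res <- tibble::tibble(
    scenario = 1, level = "district", unit_id = c("D001", "D002"),
    province_id = c("P01", "P01"), year = 2020,
    prevalence = c(10, 20), pop15plus = c(1000, 1000),
    cases = c(100, 200), deaths_dm = c(2.32, 4.64),
    deaths_stroke = 0, deaths_ihd = 0, deaths_ckd = 0, deaths_dka = 0,
    cases_neuropathy = 0, cases_retinopathy = 0)
  nat <- aggregate_results(res, "national")
  expect_equal(nat$cases, 300)
  expect_equal(nat$prevalence, 15)
  prov <- aggregate_results(res, "province")
  expect_equal(prov$cases, nat$cases)

  # single-district province: the province row equals the district row
  solo <- res[1, ]
  psolo <- aggregate_results(solo, "province")
  expect_equal(psolo$cases, solo$cases)
  expect_equal(psolo$prevalence, solo$prevalence)

  orphan <- res
  orphan$province_id <- NA_character_
  expect_error(aggregate_results(orphan, "province"), "without a province")
})

test_that("a full projection run conserves, orders scenarios and scales", {
  cfg <- small_config()
  panel <- generate_panel(cfg)
  trends <- fit_panel_trends(panel)
  pop <- generate_population(cfg, 2020:2045)
  calib <- calibration_factor(panel)
  res <- run_projection(panel, default_model(), trends, pop,
                        calibration = calib)

  # conservation: national = sum of provinces = sum of districts, per
  # scenario-year, before any rounding
  for (lv in c("province", "district")) {
    sums <- res[res$level == lv, ] |>
      dplyr::group_by(scenario, year) |>
      dplyr::summarise(cases = sum(cases), deaths = sum(deaths_dm),
                       .groups = "drop")
    nat <- res[res$level == "national", ]
    nat <- nat[order(nat$scenario, nat$year), ]
    sums <- sums[order(sums$scenario, sums$year), ]
    expect_equal(sums$cases, nat$cases)
    expect_equal(sums$deaths, nat$deaths_dm)
  }

  # scenario ordering for every unit-year (generator risk slopes are >= 0)
  wide <- res |>
    dplyr::select(scenario, level, unit_id, year, prevalence, deaths_dm) |>
    tidyr::pivot_wider(names_from = scenario,
                       values_from = c(prevalence, deaths_dm))
  expect_true(all(wide$prevalence_3 <= wide$prevalence_2 + 1e-12))
  expect_true(all(wide$prevalence_2 <= wide$prevalence_1 + 1e-12))
  expect_true(all(wide$deaths_dm_3 <= wide$deaths_dm_2 + 1e-12))
  expect_true(all(wide$deaths_dm_2 <= wide$deaths_dm_1 + 1e-12))

  # burden identity holds on every row with cases > 0
  pos <- res[res$cases > 0, ]
  expect_equal(pos$deaths_stroke / pos$deaths_dm,
               rep(burden_assumptions()$p_stroke, nrow(pos)))

  # homogeneity: doubling the population doubles counts, leaves prevalence
  pop2 <- pop; pop2$pop15plus <- 2 * pop2$pop15plus
  panel2 <- panel; panel2$pop15plus <- 2 * panel2$pop15plus
  res2 <- run_projection(panel2, default_model(), trends, pop2,
                         calibration = calib)
  expect_equal(res2$cases, 2 * res$cases, tolerance = 1e-12)
  expect_equal(res2$prevalence, res$prevalence, tolerance = 1e-12)

  # determinism: identical inputs give identical outputs
  expect_identical(res, run_projection(panel, default_model(), trends, pop,
                                       calibration = calib))
})

test_that("one flat district with zero growth repeats the same row yearly", {
  m <- default_model()
  trends <- list(D001 = lapply(setNames(nm = default_predictors()), function(v)
    trend_model(v, "frozen", anchor_year = 2018, anchor_value = 40)))
  panel <- tibble::tibble(district_id = "D001", province_id = "P01",
                          year = 2018L, diagnosed_prevalence = 9,
                          pop15plus = 1e5)
  pop <- tibble::tibble(district_id = "D001", year = 2020:2025,
                        pop15plus = 1e5)
  res <- run_projection(panel, m, trends, pop, calibration = 1,
                        scenarios = 1, years = 2020:2025)
  d <- res[res$level == "district", ]
  expect_equal(length(unique(d$cases)), 1L)
  expect_equal(length(unique(d$prevalence)), 1L)
})

test_that("stochastic mode reports the replicate mean and is seeded", {
  cfg <- small_config()
  panel <- generate_panel(cfg)
  trends <- fit_panel_trends(panel)
  pop <- generate_population(cfg, 2020:2023)
  r1 <- run_projection(panel, default_model(), trends, pop, calibration = 1,
                       scenarios = 1, years = 2020:2023,
                       mode = "stochastic", n_replicates = 3, seed = 9)
  r2 <- run_projection(panel, default_model(), trends, pop, calibration = 1,
                       scenarios = 1, years = 2020:2023,
                       mode = "stochastic", n_replicates = 3, seed = 9)
  expect_identical(r1, r2)
  r3 <- run_projection(panel, default_model(), trends, pop, calibration = 1,
                       scenarios = 1, years = 2020:2023,
                       mode = "stochastic", n_replicates = 3, seed = 10)
  expect_false(identical(r1$prevalence, r3$prevalence))
})

test_that("calibration anchors the national prevalence at the reference year", {
  cfg <- small_config()
  panel <- generate_panel(cfg)
  spec <- calibration_factor(panel, calibration_spec(8.5, 2018L))
  ref <- panel[panel$year == 2018, ]
  national <- sum(ref$diagnosed_prevalence / 100 * ref$pop15plus) /
    sum(ref$pop15plus) * 100
  expect_equal(national * spec$factor, 8.5, tolerance = 1e-12)
  expect_gt(spec$factor, 0)
  expect_error(calibration_factor(panel, calibration_spec(8.5, 1999L)),
               "reference year")
})

test_that("report rounding is half-up and wide tables mirror 5-year columns", {
  res <- tibble::tibble(
    scenario = 1, level = "province", unit_id = "P01", province_id = "P01",
    year = c(2020, 2025), prevalence = c(9.194, 9.196),
    pop15plus = 1e6, cases = c(100.5, 99.49), deaths_dm = c(2.5, 3.5),
    deaths_stroke = 0, deaths_ihd = 0, deaths_ckd = 0, deaths_dka = 0,
    cases_neuropathy = 0, cases_retinopathy = 0)
  r <- round_for_report(res)
  expect_equal(r$cases, c(101, 99))
  expect_equal(r$deaths_dm, c(3, 4))  # half-up, not banker's
  expect_equal(r$prevalence, c(9.19, 9.20))

  w <- wide_table(res, "cases", "province", 1, years = c(2020, 2025))
  expect_equal(names(w), c("unit_id", "2020", "2025"))
  expect_equal(w$`2020`, 101)
})
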