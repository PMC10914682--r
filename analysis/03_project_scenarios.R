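#!/usr/bin/env Rscript
# Stage 3: dynamize every predictor and project prevalence, cases, deaths
# and complications 2020-2045 under the three intervention scenarios:
#   1 - no intervention;
#   2 - village-Posbindu and SPM diabetes-service coverage forced to 100%;
#   3 - scenario 2 plus overweight, obesity, central obesity and fatty-food
#       consumption frozen at their 2018 levels.

library(dmproj)

out <- "results/analysis"
panel <- read_panel(file.path(out, "panel.csv"))
population <- read_population(file.path(out, "population.csv"))
model <- read_model(file.path(out, "model_default.txt"))

trends <- fit_panel_trends(panel)
calib <- calibration_factor(panel)
cat(sprintf("calibration: diagnosed -> measured factor %.4f (8.5%% anchor, 2018)\n",
            calib$factor))

results <- run_projection(panel, model, trends, population,
                          calibration = calib)

readr::write_csv(round_for_report(results), file.path(out, "projection_tidy.csv"))
for (meas in c("prevalence", "cases", "deaths_dm")) {
  readr::write_csv(wide_table(results, meas, "province", 1),
                   file.path(out, sprintf("table_%s_by_province.csv", meas)))
}

nat <- results[results$level == "national", ]
pick <- function(s, y, col) nat[[col]][nat$scenario == s & nat$year == y]
cat(sprintf("national prevalence 2020 -> 2045 (scenario 1): %.2f%% -> %.2f%% (+%.1f%%)\n",
            pick(1, 2020, "prevalence"), pick(1, 2045, "prevalence"),
            (pick(1, 2045, "prevalence") / pick(1, 2020, "prevalence") - 1) * 100))
cat(sprintf("cases 2045: s1 %.1fM, s2 %.1fM, s3 %.1fM\n",
            pick(1, 2045, "cases") / 1e6, pick(2, 2045, "cases") / 1e6,
            pick(3, 2045, "cases") / 1e6))
cat(sprintf("deaths 2045: s1 %s, s2 %s (-%.2f%%), s3 %s (-%.2f%%)\n",
            format(round(pick(1, 2045, "deaths_dm"))),
            format(round(pick(2, 2045, "deaths_dm"))),
            (1 - pick(2, 2045, "deaths_dm") / pick(1, 2045, "deaths_dm")) * 100,
            format(round(pick(3, 2045, "deaths_dm"))),
            (1 - pick(3, 2045, "deaths_dm") / pick(1, 2045, "deaths_dm")) * 100))
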