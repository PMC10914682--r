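#!/usr/bin/env Rscript
# Stage 1: generate the synthetic district panel and population projection.
#
# The panel emulates the structure of the Indonesian district-level NCD
# data: 205 districts in 34 provinces, 10 risk-factor prevalences observed
# at the 2007/2013/2018 survey years, 8 programme coverages observed
# 2016-2020 (the two SPM coverages summarised over 2019-2021), and a
# diagnosed diabetes prevalence produced by the shipped nine-term equation
# plus noise calibrated to its R-squared of 0.571.

library(dmproj)

seed <- 20260923L
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = seed)
panel <- generate_panel(cfg)
population <- generate_population(cfg, 2020:2045)

write_panel(panel, file.path(out, "panel.csv"))
write_population(population, file.path(out, "population.csv"))

cross <- panel[panel$year == 2018, ]
cat(sprintf("panel: %d districts x %d years (%d rows)\n",
            dplyr::n_distinct(panel$district_id),
            dplyr::n_distinct(panel$year), nrow(panel)))
cat(sprintf("2018 diagnosed prevalence: mean %.2f%%, SD %.2f%%\n",
            mean(cross$diagnosed_prevalence),
            sd(cross$diagnosed_prevalence)))
cat(sprintf("2020 population 15+: %.1f million across all districts\n",
            sum(population$pop15plus[population$year == 2020]) / 1e6))
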