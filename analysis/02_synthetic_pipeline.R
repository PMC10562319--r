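#!/usr/bin/env Rscript
# End-to-end check of the accounting pipeline on a synthetic landscape with
# known ground truth: generate grids, registries and a "true" coefficient
# table, run every flux engine, and compare against the generator's
# direct-multiplication oracle. Then calibrate the landscape to the
# published national areas and show the linear response of the fluxes.

library(ghgscape)

cfg <- synthetic_config(seed = 20)
ls_ <- generate_landscape(cfg)
pipe <- run_pipeline(ls_)

m <- merge(ls_$truth$components, pipe$components, by = c("component", "gas"),
           suffixes = c("_truth", "_pipeline"))
m$abs_diff_Gg <- abs(m$value_Gg_truth - m$value_Gg_pipeline)
cat(sprintf("Synthetic landscape: %d x %d cells, %d regions, %d lakes\n",
            cfg$nrow, cfg$ncol, cfg$n_regions, cfg$n_lakes))
cat(sprintf("Pipeline total %.4f vs ground truth %.4f TgCO2eq/yr (max abs component diff %.3g Gg)\n",
            pipe$total_co2eq_Tg, ls_$truth$total_co2eq_Tg,
            max(m$abs_diff_Gg)))
tot_in <- sum(ifelse(ls_$sector_totals$biogenic, 0, ls_$sector_totals$total))
cat(sprintf("Proxy allocation conserves sector totals: %.6g in, %.6g gridded\n",
            tot_in, sum(pipe$allocation)))

# calibrate the landscape so its accounting matches the published areas
cur <- pipe$areas
scale_to <- function(subs, target_total) {
  a <- cur[cur$subcategory %in% subs, ]
  data.frame(subcategory = a$subcategory,
             area_km2 = target_total * a$area_km2 / sum(a$area_km2))
}
target <- rbind(
  data.frame(subcategory = c("organic_annual", "organic_perennial",
                             "mineral_all_crops", "livestock_production",
                             "mineral_soil", "drained_peatland", "river",
                             "peat_production"),
             area_km2 = c(958, 1212, 18265, 1986, 174405, 36725, 1388, 1026)),
  scale_to(paste0("lake_class_", 1:5), 32510),
  scale_to(paste0("mire_class_", 1:4), 30508),
  scale_to(subcategory_scheme()$subcategories$artificial, 7973))
ls_cal <- calibrate_to_areas(ls_, target)
cal_areas <- area_accounting(ls_cal$grid, ls_cal$lakes, ls_cal$rivers)
cat(sprintf("Calibrated accounted area: %.0f km2 (target %.0f)\n",
            sum(cal_areas$area_km2), sum(target$area_km2)))
pipe_cal <- run_pipeline(ls_cal)
cat(sprintf("Calibrated pipeline total: %.2f TgCO2eq/yr\n",
            pipe_cal$total_co2eq_Tg))

dir.create("results", showWarnings = FALSE)
write_reports(list(synthetic_components = m,
                   synthetic_calibrated_areas = as.data.frame(cal_areas)),
              "results", seed = cfg$seed)
cat("wrote results/synthetic_components.csv, synthetic_calibrated_areas.csv\n")
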