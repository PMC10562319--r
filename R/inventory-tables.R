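#' Load the packaged national-inventory tables
#'
#' Reads the packaged transcriptions of the published national accounting:
#' the land-cover area table, the national flux table (Tg CO2eq/yr with
#' uncertainty half-widths), the regional aggregates, the reconstructed
#' per-region populations and the derived coefficient table. Numbers are
#' stored exactly as printed (thousands separators stripped, '.' decimal).
#'
#' @param dir Directory with the CSV fixtures; defaults to the package's
#'   `extdata`.
#' @return List: `areas`, `fluxes`, `regions`, `populations` (with attribute
#'   `national_population`), `coefficients`.
#' @export
inventory_data <- function(dir = system.file("extdata", package = "ghgscape")) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  pops <- rd("region_populations_synthetic.csv")
  attr(pops, "national_population") <- 5503664
  list(areas = rd("land_cover_areas.csv"),
       fluxes = rd("national_flux_table.csv"),
       regions = rd("regional_table.csv"),
       populations = pops,
       coefficients = read_coefficient_table(
         file.path(dir, "coefficients_inventory_derived.csv")))
}

# land-cover area (km2) under each flux-table row, for intensity = flux/area;
# artificial sources are all allocated to the whole artificial area
.row_area_map <- function(areas) {
  a <- function(cat, sub) areas$area_km2[areas$category == cat &
                                         areas$subcategory == sub]
  art <- a("artificial", "total")
  c(setNames(rep(art, 12),
             paste0("artificial.", c("industrial_processes",
               "energy_waste_solids", "energy_peat", "energy_gaseous",
               "energy_liquid", "energy_biomass", "energy_total",
               "road_traffic", "machinery", "waste_management",
               "residential_combustion", "total_emission"))),
    "arable.livestock_production" = a("arable", "livestock_production"),
    "arable.field_cultivation"    = a("arable", "field_cultivation_total"),
    "arable.organic_annual"       = a("arable", "organic_annual"),
    "arable.organic_perennial"    = a("arable", "organic_perennial"),
    "arable.mineral_all_crops"    = a("arable", "mineral_all_crops"),
    "arable.total_emission"       = a("arable", "total"),
    "forest.timber_mineral"       = a("forest", "mineral_soil"),
    "forest.timber_drained_peat"  = a("forest", "drained_peatland"),
    "forest.energywood_mineral"   = a("forest", "mineral_soil"),
    "forest.energywood_drained_peat" = a("forest", "drained_peatland"),
    "forest.timber_total"         = a("forest", "total"),
    "forest.energywood_total"     = a("forest", "total"),
    "forest.harvest_total"        = a("forest", "total"),
    "forest.drained_peat_soil"    = a("forest", "drained_peatland"),
    "forest.total_emission"       = a("forest", "total"),
    "forest.ecosystems_mineral_soil" = a("forest", "total"),
    "forest.ecosystems_drained_peat" = a("forest", "total"),
    "forest.total_sink"           = a("forest", "total"),
    "forest.net_emission"         = a("forest", "total"),
    "waterbody.rivers"            = a("waterbody", "river"),
    "waterbody.lakes"             = a("waterbody", "lakes"),
    "waterbody.total_emission"    = a("waterbody", "total"),
    "wetland.peat_production"     = a("wetland", "peat_production"),
    "wetland.mire_soil"           = a("wetland", "undrained_mires"),
    "wetland.total_emission"      = a("wetland", "total"),
    "wetland.net_emission"        = a("wetland", "total"),
    "total.total_emission"        = a("total", "total"),
    "total.net_emission"          = a("total", "total"))
}

#' Rebuild the national flux table from its printed components
#'
#' Recomputes, from the component rows only: per-category per-gas sums and
#' totals, quadrature SDs of the category totals, the national emission and
#' net rollup, and intensities (flux over the land-cover area under each
#' row). Printed values are kept alongside for comparison.
#'
#' @param data As from [inventory_data()].
#' @return List: `rows` (flux table with `total_calc`, `intensity_calc`
#'   columns), `rollup` (see [national_rollup()]), `categories` (per-category
#'   emission/sink frame used for the rollup).
#' @export
inventory_flux_report <- function(data) {
  fx <- data$fluxes
  key <- paste(fx$category, fx$source, sep = ".")
  amap <- .row_area_map(data$areas)
  fx$total_calc <- rowSums(cbind(fx$ch4, fx$co2, fx$n2o), na.rm = TRUE)
  fx$area_km2 <- unname(amap[key])
  fx$intensity_calc <- intensity(fx$total, fx$area_km2)

  cats <- c("artificial", "arable", "forest", "waterbody", "wetland")
  comp <- fx[fx$level == "component", ]
  emis <- fx[fx$level == "category_emission", ]
  sink <- fx[fx$level == "category_sink", ]
  per_cat <- do.call(rbind, lapply(cats, function(cc) {
    le <- comp[comp$category == cc, ]
    pe <- emis[emis$category == cc, ]
    ps <- sink[sink$category == cc, ]
    data.frame(
      category = cc,
      ch4 = sum(le$ch4), co2 = sum(le$co2), n2o = sum(le$n2o),
      emission_Tg = pe$total, emission_sd = pe$sd,
      sink_Tg = if (nrow(ps) > 0) ps$total else 0,
      sink_sd = if (nrow(ps) > 0) ps$sd else 0,
      sink_co2 = if (nrow(ps) > 0) ps$co2 else 0,
      emission_calc = sum(le$total))
  }))
  # the published national net SD combines the emission SD with the
  # Monte-Carlo forest sink SD; the (small) mire sink SD is not part of it
  forest_sink_sd <- sink$sd[sink$category == "forest"]
  rollup <- national_rollup(per_cat, sink_sd_override = forest_sink_sd)
  list(rows = fx, rollup = rollup, categories = per_cat)
}

#' Rebuild the regional table from printed emission and sink columns
#'
#' Net, intensity and per-capita values are recomputed per region from the
#' printed emission, sink, area and (reconstructed) population; the national
#' per-capita uses the published total population.
#'
#' @param data As from [inventory_data()].
#' @return A [regional_aggregate()] result plus printed columns
#'   (`net_printed`, `intensity_printed`, `per_capita_printed`).
#' @export
inventory_region_report <- function(data) {
  reg <- data$regions[data$regions$code != 0, ]
  flux <- data.frame(region = reg$code, emission_Tg = reg$emission_Tg,
                     sink_Tg = reg$sink_Tg)
  areas <- data.frame(region = reg$code, area_km2 = reg$area_km2)
  pops <- data.frame(region = data$populations$code,
                     population = data$populations$population)
  attr(pops, "national_population") <-
    attr(data$populations, "national_population")
  out <- regional_aggregate(flux, areas, pops)
  out$name <- reg$region[match(out$region, reg$code)]
  out$net_printed <- reg$net_Tg[match(out$region, reg$code)]
  out$intensity_printed <- reg$intensity[match(out$region, reg$code)]
  out$per_capita_printed <- reg$per_capita[match(out$region, reg$code)]
  out
}

#' Reproduce national flux rows through the coefficient engines
#'
#' Runs each area-based flux engine with the packaged derived coefficient
#' table on the printed areas, returning CO2eq totals (Tg/yr) per engine:
#' cropland soils, rivers, lakes, undrained mires (emissions and ecosystem
#' sink), drained-peat forest soils, peat production and harvest (harvested
#' carbon back-computed from the printed harvest CO2 components).
#'
#' @param data As from [inventory_data()].
#' @return Named list of numbers (Tg CO2eq / yr).
#' @export
inventory_engine_checks <- function(data) {
  ar <- data$areas
  a <- function(cat, sub) ar$area_km2[ar$category == cat & ar$subcategory == sub]
  tab <- data$coefficients
  tg <- function(f) to_co2eq(f)$value / 1000  # Gg gas flux -> Tg CO2eq

  organic_annual <- tg(coefficient_flux(a("arable", "organic_annual"),
                                        "organic_annual", "CO2", tab))
  organic_perennial <- tg(coefficient_flux(a("arable", "organic_perennial"),
                                           "organic_perennial", "CO2", tab))
  mineral <- tg(coefficient_flux(a("arable", "mineral_all_crops"),
                                 "mineral_all_crops", "CO2", tab))
  rivers <- tg(river_emissions(a("waterbody", "river"), tab))
  # per-class lake areas are not published: the aggregate rates make the
  # split immaterial, so the registry spreads the lake area evenly by class
  lakes_reg <- data.frame(area_km2 = rep(a("waterbody", "lakes") / 5, 5),
                          size_class = 1:5)
  lk <- lake_emissions(lakes_reg, tab)
  lakes <- tg(lk$CO2) + tg(lk$CH4)
  mire_area <- a("wetland", "undrained_mires")
  mr <- mire_fluxes(setNames(rep(mire_area / 4, 4),
                             paste0("mire_class_", 1:4)), tab)
  mires_emission <- tg(mr$CH4) + tg(mr$N2O)
  mires_sink <- tg(mr$CO2)
  dp <- drained_peat_soil_fluxes(a("forest", "drained_peatland"), tab)
  drained_peat <- tg(dp$CH4) + tg(dp$CO2) + tg(dp$N2O)
  pp <- peat_production_emissions(a("wetland", "peat_production"), tab)
  peat_production <- tg(pp$CH4) + tg(pp$CO2) + tg(pp$N2O)
  # harvested C from the printed harvest CO2 fluxes (Tg CO2 x 12/44, in Gg)
  fx <- data$fluxes
  hv <- fx[fx$source %in% c("timber_mineral", "timber_drained_peat",
                            "energywood_mineral", "energywood_drained_peat"), ]
  harvest_in <- data.frame(
    assortment = sub("_(mineral|drained_peat)$", "", hv$source),
    soil = ifelse(grepl("mineral", hv$source), "mineral_soil",
                  "drained_peatland"),
    carbon_Gg = hv$co2 * 1000 * 12 / 44,
    sd = hv$sd * 1000 * 12 / 44)
  harvest <- harvest_emissions(harvest_in)$total$value / 1000

  list(organic_annual = organic_annual,
       organic_perennial = organic_perennial,
       mineral_all_crops = mineral,
       rivers = rivers, lakes = lakes,
       mires_emission = mires_emission, mires_sink = mires_sink,
       drained_peat_soil = drained_peat,
       peat_production = peat_production,
       harvest_total = harvest)
}

#' Write the report tables to disk
#'
#' Deterministic CSV output (same inputs, byte-identical files) with a short
#' provenance comment header.
#'
#' @param reports Named list of data frames.
#' @param dir Output directory (created if needed).
#' @param seed Optional seed recorded in the header.
#' @return Invisibly, the written paths.
#' @export
write_reports <- function(reports, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  ver <- as.character(utils::packageVersion("ghgscape"))
  for (nm in names(reports)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# ghgscape %s seed=%s", ver, seed), con)
    utils::write.csv(as.data.frame(reports[[nm]]), con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
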