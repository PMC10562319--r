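dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)

## Table 1: land-cover areas (printed values; spaces in thousands stripped)
t1 <- read.csv(text = '
category,subcategory,level,area_km2,frac_of_category,frac_of_total
artificial,total,category_total,7973,NA,3
arable,livestock_production,subcategory,1986,9,NA
arable,organic_annual,subcategory,958,4,NA
arable,organic_perennial,subcategory,1212,5,NA
arable,mineral_all_crops,subcategory,18265,81,NA
arable,field_cultivation_total,subtotal,20435,91,NA
arable,total,category_total,22537,100,7
forest,mineral_soil,subcategory,174405,83,NA
forest,drained_peatland,subcategory,36725,17,NA
forest,total,category_total,211130,100,69
waterbody,river,subcategory,1388,4,NA
waterbody,lakes,subcategory,32510,96,NA
waterbody,total,category_total,33896,100,11
wetland,peat_production,subcategory,1026,3,NA
wetland,undrained_mires,subcategory,30508,97,NA
wetland,total,category_total,31534,100,10
total,total,grand_total,306954,NA,100
', stringsAsFactors = FALSE)
write.csv(t1, "inst/extdata/land_cover_areas.csv", row.names = FALSE, quote = FALSE)

## Table 2: printed national fluxes (TgCO2eq/yr), SD = printed +- half-width
t2 <- read.csv(text = '
category,source,level,ch4,co2,n2o,total,sd,intensity
artificial,industrial_processes,component,0,8.51,0,8.51,0.30,1.07
artificial,energy_waste_solids,component,0,6.49,0,6.49,0.13,0.81
artificial,energy_peat,component,0,5.76,0.04,5.80,0.20,0.73
artificial,energy_gaseous,component,0,5.72,0,5.72,1.59,0.72
artificial,energy_liquid,component,0,1.67,0,1.67,0.07,0.21
artificial,energy_biomass,component,0.01,0,0.09,0.10,0.05,0.01
artificial,energy_total,subtotal,0.01,19.63,0.13,19.77,0.59,2.48
artificial,road_traffic,component,0,10.37,0,10.37,0.31,1.30
artificial,machinery,component,0,3.16,0,3.16,0.19,0.40
artificial,waste_management,component,1.88,0,0.10,1.98,0.70,0.25
artificial,residential_combustion,component,0.19,1.66,0.03,1.88,0.44,0.24
artificial,total_emission,category_emission,2.08,43.34,0.26,45.68,1.97,5.73
arable,livestock_production,component,2.80,0,0.24,3.04,2.28,1.53
arable,field_cultivation,component,0,0.20,3.22,3.43,2.57,0.17
arable,organic_annual,component,0,2.78,0,2.78,0.48,2.90
arable,organic_perennial,component,0,2.53,0,2.53,0.67,2.09
arable,mineral_all_crops,component,0,0.47,0,0.47,0.25,0.03
arable,total_emission,category_emission,2.80,5.98,3.47,12.24,3.54,0.55
forest,timber_mineral,component,0,44.75,0,44.75,3.12,0.26
forest,timber_drained_peat,component,0,8.84,0,8.84,0.49,0.24
forest,timber_total,subtotal,0,53.60,0,53.60,3.16,0.25
forest,energywood_mineral,component,0,5.23,0,5.23,0.89,0.03
forest,energywood_drained_peat,component,0,0.99,0,0.99,0.14,0.03
forest,energywood_total,subtotal,0,6.22,0,6.22,0.90,0.03
forest,harvest_total,subtotal,0,59.82,0,59.82,3.29,0.28
forest,drained_peat_soil,component,0.35,0,1.44,1.79,3.52,0.05
forest,total_emission,category_emission,0.35,59.82,1.44,61.61,4.81,0.29
forest,ecosystems_mineral_soil,sink_component,NA,-79.87,NA,-79.87,12.20,-0.38
forest,ecosystems_drained_peat,sink_component,NA,-9.41,NA,-9.41,6.10,-0.04
forest,total_sink,category_sink,NA,-89.28,NA,-89.28,13.70,-0.42
forest,net_emission,category_net,0.35,-29.47,1.44,-27.68,10.30,-0.13
waterbody,rivers,component,0,7.33,0,7.33,1.20,5.28
waterbody,lakes,component,0.86,5.16,0,6.02,1.50,0.19
waterbody,total_emission,category_emission,0.86,12.49,0,13.35,1.92,0.39
wetland,peat_production,component,0.06,1.80,0.09,1.95,0.39,1.90
wetland,mire_soil,component,11.48,0,0.84,12.32,1.79,0.40
wetland,total_emission,category_emission,11.54,1.80,0.93,14.27,1.84,0.45
wetland,mire_ecosystems,sink_component,NA,-3.91,NA,-3.91,0.40,0.00
wetland,total_sink,category_sink,NA,-3.91,NA,-3.91,0.40,0.00
wetland,net_emission,category_net,11.54,-2.11,0.93,10.36,4.40,0.34
total,total_emission,grand_emission,17.63,123.43,6.10,147.16,6.83,0.48
total,net_emission,grand_net,17.63,30.23,6.10,53.90,15.30,0.18
', stringsAsFactors = FALSE)
write.csv(t2, "inst/extdata/national_flux_table.csv", row.names = FALSE, quote = FALSE)

## Table 3: printed regional aggregates
t3 <- read.csv(text = '
code,region,area_km2,emission_Tg,sink_Tg,net_Tg,intensity,per_capita
1,Uusimaa,9569,16.973,-3.614,13.360,1.40,7.8
2,Southwest Finland,10914,6.989,-4.069,2.920,0.27,6.0
4,Satakunta,8269,5.787,-2.897,2.890,0.35,13.5
5,Kanta-Hame,5708,3.973,-1.740,2.232,0.39,13.1
6,Pirkanmaa,15550,8.827,-5.386,3.441,0.22,6.5
7,Paijat-Hame,6942,4.005,-2.231,1.774,0.26,8.6
8,Kymenlaakso,4948,3.633,-1.393,2.240,0.45,13.9
9,South Karelia,6872,4.531,-1.694,2.837,0.41,22.5
10,South Savo,17099,8.072,-4.102,3.969,0.23,30.1
11,North Savo,21078,9.542,-6.283,3.259,0.15,13.1
12,North Karelia,22903,7.902,-6.728,1.174,0.05,7.2
13,Central Finland,19012,8.732,-6.564,2.168,0.11,8.0
14,South Ostrobothnia,14356,7.247,-4.878,2.368,0.16,12.3
15,Ostrobothnia,7580,4.824,-2.939,1.885,0.25,10.7
16,Central Ostrobothnia,5224,2.550,-1.585,0.965,0.18,14.2
17,North Ostrobothnia,39194,18.660,-10.333,8.328,0.21,20.0
18,Kainuu,22688,5.537,-7.292,-1.754,-0.08,-24.6
19,Lapland,98982,19.372,-19.498,-0.126,-0.001,-0.7
0,total,336887,147.157,-93.226,53.931,0.16,9.8
', stringsAsFactors = FALSE)
write.csv(t3, "inst/extdata/regional_table.csv", row.names = FALSE, quote = FALSE)

## Region populations: SYNTHETIC reconstruction (population = net*1e6/per_capita)
reg <- t3[t3$code != 0, ]
pop <- data.frame(code = reg$code, region = reg$region,
                  population = round(reg$net_Tg * 1e6 / reg$per_capita))
con <- file("inst/extdata/region_populations_synthetic.csv", "w")
writeLines(c(
 "# SYNTHETIC stand-in for the per-region population register:",
 "# reconstructed as (regional net emission x 1e6 / printed per-capita net),",
 "# so per-capita recomputation checks arithmetic conventions only.",
 "# The national total population used for country-level per-capita is the",
 "# published 5503664 (31.12.2020), not the sum of this column."), con)
write.csv(pop, con, row.names = FALSE, quote = FALSE)
close(con)

## Emission coefficients DERIVED from printed national totals
## (per-class splits are not published; every class carries the aggregate rate)
fmt <- function(x) formatC(x, digits = 12, format = "g")
rows <- list()
add <- function(category, subcategory, gas, coef, sd, term = "total",
                zone = "national", element = "", source = "derived") {
  rows[[length(rows) + 1]] <<- data.frame(category, subcategory, gas, zone,
                                          term, coefficient = coef, sd,
                                          element, source)
}
# arable soil CO2 (Tg -> Gg: x1000), per printed subcategory area
add("arable", "organic_annual",    "CO2", 2780/958,   480/958)
add("arable", "organic_perennial", "CO2", 2530/1212,  670/1212)
add("arable", "mineral_all_crops", "CO2", 470/18265,  250/18265)
# rivers
add("waterbody", "river", "CO2", 7330/1388, 1200/1388)
# lakes: aggregate CO2 evasion rate and CH4 split diffusion/ebullition;
# printed lake SD assigned to the CO2 evasion term
lake_a <- 32510
for (k in 1:5) {
  add("waterbody", paste0("lake_class_", k), "CO2", 5160/lake_a, 1500/lake_a,
      term = "evasion")
  # CH4 in CO2eq 0.86 Tg -> gas mass 860/28 Gg
  ch4 <- (860/28)/lake_a
  add("waterbody", paste0("lake_class_", k), "CH4", 0.6*ch4, 0, term = "diffusion")
  add("waterbody", paste0("lake_class_", k), "CH4", 0.4*ch4, 0, term = "ebullition")
}
add("waterbody", "macrophyte_phragmites", "CH4", (860/28)/lake_a, 0)
add("waterbody", "macrophyte_equisetum",  "CH4", (860/28)/lake_a, 0)
# mires: CH4 11.48 Tg CO2eq -> 11480/28 Gg gas; N2O 0.84 -> 840/265;
# ecosystem CO2 sink -3.91 Tg
mire_a <- 30508
for (k in 1:4) {
  add("wetland", paste0("mire_class_", k), "CH4", (11480/28)/mire_a, (1790/28)/mire_a)
  add("wetland", paste0("mire_class_", k), "N2O", (840/265)/mire_a, 0)
  add("wetland", paste0("mire_class_", k), "CO2", -3910/mire_a, (400)/mire_a)
}
# drained peatland forest soils: CH4 0.35 TgCO2eq, N2O 1.44 TgCO2eq, CO2 0
peat_f <- 36725
add("forest", "drained_peatland", "CH4", (350/28)/peat_f, 0)
add("forest", "drained_peatland", "CO2", 0, 0)
add("forest", "drained_peatland", "N2O", (1440/265)/peat_f, (3520/265)/peat_f)
# peat production national factors over 1026 km2
pp <- 1026
add("wetland", "peat_production", "CH4", (60/28)/pp, 0)
add("wetland", "peat_production", "CO2", 1800/pp, (390)/pp)
add("wetland", "peat_production", "N2O", (90/265)/pp, 0)
coefs <- do.call(rbind, rows)
coefs$coefficient <- fmt(coefs$coefficient)
coefs$sd <- fmt(coefs$sd)
con <- file("inst/extdata/coefficients_inventory_derived.csv", "w")
writeLines(c(
 "# Area-based emission coefficients, Gg gas km-2 yr-1 (gas mass, not CO2eq),",
 "# DERIVED from the printed national flux totals divided by printed areas.",
 "# The published per-size-class and per-mire-class coefficient tables are in",
 "# a supplement not shipped here, so every class carries the national",
 "# aggregate rate; class-resolved behaviour is exercised with synthetic",
 "# coefficient tables instead."), con)
write.csv(coefs, con, row.names = FALSE, quote = FALSE)
close(con)

## Mire classification rules: SYNTHETIC full-coverage rule table
g <- expand.grid(productivity = c("productive", "poorly_productive", "unproductive"),
                 main_class = c("spruce_mire", "pine_mire", "open_bog"),
                 fertility = c("herb_rich", "mesotrophic", "oligotrophic", "ombrotrophic"),
                 stringsAsFactors = FALSE)
cls <- function(p, m, f) {
  if (p == "productive" && m %in% c("spruce_mire", "pine_mire")) return(1L)
  if (f == "ombrotrophic") return(4L)
  if (m == "open_bog" && f %in% c("herb_rich", "mesotrophic")) return(2L)
  3L
}
g$mire_class <- mapply(cls, g$productivity, g$main_class, g$fertility)
con <- file("inst/extdata/mire_rules_synthetic.csv", "w")
writeLines(c(
 "# SYNTHETIC mire classification rule table (full coverage of the attribute",
 "# domain). Classes: 1 productive forested mires, 2 sedge fens, 3 other open",
 "# and sparsely treed fens, 4 ombrotrophic bogs."), con)
write.csv(g, con, row.names = FALSE, quote = FALSE)
close(con)
cat("fixtures written\n")
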