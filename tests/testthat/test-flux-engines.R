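coef_df <- function(...) coefficient_table(rbind(...))
row_of <- function(category, subcategory, gas, coefficient, sd = 0,
                   zone = "national", term = "total", element = "")
  data.frame(category, subcategory, gas, zone, term, coefficient, sd, element)

test_that("coefficient fluxes are area times rate, with zone fallback", {
  tab <- coef_df(
    row_of("arable", "organic_annual", "CO2", 2.9, 0.5, zone = "southern"),
    row_of("arable", "organic_annual", "CO2", 2.0, 0.4, zone = "national"),
    row_of("forest", "drained_peatland", "N2O", 0.04, 0.01))
  f <- coefficient_flux(100, "organic_annual", "CO2", tab, zone = "southern")
  expect_equal(f$value, 290)
  expect_equal(f$sd, 50)
  # zonal row missing -> national fallback
  f2 <- coefficient_flux(100, "organic_annual", "CO2", tab, zone = "northern")
  expect_equal(f2$value, 200)
  expect_equal(coefficient_flux(0, "organic_annual", "CO2", tab)$value, 0)
  # linearity in area
  expect_equal(coefficient_flux(84, "drained_peatland", "N2O", tab)$value,
               84 * 0.04)
  expect_error(coefficient_flux(1, "nosuch", "CO2", tab), "no coefficient")
})

test_that("element-flagged coefficient rows convert through molar masses", {
  tab <- coef_df(row_of("wetland", "mire_class_1", "CO2", -0.12, 0.01,
                        element = "C"))
  f <- coefficient_flux(10, "mire_class_1", "CO2", tab)
  expect_equal(f$value, 10 * -0.12 * 44 / 12)
  expect_equal(f$sd, 10 * 0.01 * 44 / 12)
})

test_that("coefficient tables validate schema, keys and SDs", {
  expect_error(coefficient_table(data.frame(category = "x")), "columns")
  expect_error(coef_df(row_of("a", "s", "CO2", 1, -1)), "non-negative")
  expect_error(coef_df(row_of("a", "s", "SF6", 1)), "gas")
  expect_error(coef_df(row_of("a", "s", "CO2", 1), row_of("a", "s", "CO2", 2)),
               "duplicate")
})

test_that("lake emissions follow the per-lake arithmetic", {
  tab <- coef_df(
    row_of("waterbody", "lake_class_2", "CO2", 0.2, 0.05, term = "evasion"),
    row_of("waterbody", "lake_class_2", "CH4", 0.01, 0.001, term = "diffusion"),
    row_of("waterbody", "lake_class_2", "CH4", 0.004, 0.001, term = "ebullition"),
    row_of("waterbody", "lake_class_3", "CO2", 0.1, 0, term = "evasion"),
    row_of("waterbody", "lake_class_3", "CH4", 0.02, 0, term = "diffusion"),
    row_of("waterbody", "lake_class_3", "CH4", 0.006, 0, term = "ebullition"),
    row_of("waterbody", "macrophyte_phragmites", "CH4", 0.05, 0),
    row_of("waterbody", "macrophyte_equisetum", "CH4", 0.03, 0))
  # zero cover: CH4 is exactly area x (diffusion + ebullition)
  one <- data.frame(area_km2 = 0.5)
  got <- lake_emissions(one, tab)
  expect_equal(got$CH4$value, 0.5 * (0.01 + 0.004))
  expect_equal(got$CO2$value, 0.5 * 0.2)
  # substitution: covered area switches to the species coefficient
  cov <- data.frame(area_km2 = 2, size_class = 3,
                    cover_phragmites = 0.25, cover_equisetum = 0.1)
  got2 <- lake_emissions(cov, tab)
  expect_equal(got2$CH4$value,
               2 * 0.65 * (0.02 + 0.006) + 2 * 0.25 * 0.05 + 2 * 0.1 * 0.03)
  # additive mode keeps the full open-water terms
  got3 <- lake_emissions(cov, tab, macrophyte = "additive")
  expect_equal(got3$CH4$value,
               2 * (0.02 + 0.006) + 2 * 0.25 * 0.05 + 2 * 0.1 * 0.03)
  # registry totals match a hand-summed per-lake oracle
  set.seed(9)
  reg <- data.frame(area_km2 = runif(20, 0.2, 5),
                    size_class = sample(2:3, 20, replace = TRUE),
                    cover_phragmites = runif(20, 0, 0.3),
                    cover_equisetum = runif(20, 0, 0.3))
  got4 <- lake_emissions(reg, tab)
  ev <- ifelse(reg$size_class == 2, 0.2, 0.1)
  ow <- ifelse(reg$size_class == 2, 0.014, 0.026)
  hand_co2 <- sum(reg$area_km2 * ev)
  hand_ch4 <- sum(reg$area_km2 * (1 - reg$cover_phragmites -
                                  reg$cover_equisetum) * ow +
                  reg$area_km2 * reg$cover_phragmites * 0.05 +
                  reg$area_km2 * reg$cover_equisetum * 0.03)
  expect_equal(got4$CO2$value, hand_co2)
  expect_equal(got4$CH4$value, hand_ch4)
  # an unclassifiable registry (sub-minimum lakes only) yields zero flux
  expect_equal(lake_emissions(data.frame(area_km2 = 0.001), tab)$CO2$value, 0)
  expect_error(lake_emissions(data.frame(area_km2 = 1, size_class = 2,
                                         cover_phragmites = 0.7,
                                         cover_equisetum = 0.6), tab),
               "exceed")
})

test_that("river area applies the 3.5 m width rule to line rivers", {
  expect_equal(river_area(data.frame(kind = "line", length_km = 1,
                                     area_km2 = NA)), 0.0035)
  pol <- data.frame(kind = c("polygon", "polygon"), area_km2 = c(1.2, 3.4),
                    length_km = NA)
  expect_equal(river_area(pol), 4.6)
  mix <- data.frame(kind = c("polygon", "line"), area_km2 = c(10, NA),
                    length_km = c(NA, 200))
  expect_equal(river_area(mix), 10 + 0.7)
  # river emissions are linear in area
  tab <- coef_df(row_of("waterbody", "river", "CO2", 5.28, 0.9))
  expect_equal(river_emissions(2776, tab)$value,
               2 * river_emissions(1388, tab)$value)
  expect_equal(river_emissions(0, tab)$value, 0)
})

test_that("mire fluxes sum class areas times coefficients, sink negative", {
  tab <- coef_df(
    row_of("wetland", "mire_class_1", "CH4", 0.3, 0.1),
    row_of("wetland", "mire_class_1", "N2O", 0.002, 0),
    row_of("wetland", "mire_class_1", "CO2", -0.1, 0.02),
    row_of("wetland", "mire_class_2", "CH4", 0.5, 0.1),
    row_of("wetland", "mire_class_2", "N2O", 0.004, 0),
    row_of("wetland", "mire_class_2", "CO2", -0.2, 0.02))
  got <- mire_fluxes(c(mire_class_1 = 10, mire_class_2 = 20), tab)
  expect_equal(got$CH4$value, 10 * 0.3 + 20 * 0.5)
  expect_equal(got$N2O$value, 10 * 0.002 + 20 * 0.004)
  expect_equal(got$CO2$value, -(10 * 0.1 + 20 * 0.2))
  expect_equal(got$CH4$sd, sqrt(1 + 4))
  z <- mire_fluxes(c(mire_class_1 = 0, mire_class_2 = 0), tab)
  expect_equal(z$CH4$value, 0)
  expect_error(mire_fluxes(c(mire_class_3 = 5), tab), "no coefficient")
})

test_that("mire CO2 coefficient derivation closes the carbon balance", {
  expect_equal(as.numeric(derive_mire_co2_coefficient(0, 0, 0)), 0)
  # accumulation alone: a CO2-C sink of the same magnitude
  k <- derive_mire_co2_coefficient(20, 0, 0)
  expect_equal(attr(k, "co2_c_gC_m2"), -20)
  expect_equal(as.numeric(k), -20 * 1e-3 * 44 / 12)
  # mass balance identity under the full convention:
  # accumulation = -CO2C - CH4C - leachC
  for (a in c(5, 20)) for (m in c(0, 3)) for (l in c(0, 8)) {
    co2c <- attr(derive_mire_co2_coefficient(a, m, l), "co2_c_gC_m2")
    expect_equal(a, -co2c - m - l)
  }
  # convention switches drop terms
  k2 <- derive_mire_co2_coefficient(10, 5, 7, include_ch4 = FALSE)
  expect_equal(attr(k2, "co2_c_gC_m2"), -17)
  expect_error(derive_mire_co2_coefficient(-1), ">= 0")
})

test_that("harvested carbon is an immediate CO2 emission", {
  h <- data.frame(assortment = "timber", soil = "mineral_soil",
                  carbon_Gg = 12000, sd = 0)
  expect_equal(harvest_emissions(h)$total$value, 44000)  # 12 Tg C -> 44 Tg
  # four components combine with quadrature SD
  h4 <- data.frame(
    assortment = c("timber", "timber", "energywood", "energywood"),
    soil = rep(c("mineral_soil", "drained_peatland"), 2),
    carbon_Gg = c(120, 24, 15, 3), sd = c(9, 3, 3, 1.5))
  got <- harvest_emissions(h4)
  expect_equal(got$total$value, sum(c(120, 24, 15, 3)) * 44 / 12)
  expect_equal(got$total$sd, sqrt(sum((c(9, 3, 3, 1.5) * 44 / 12)^2)))
  expect_equal(nrow(got$components), 4)
  expect_error(harvest_emissions(data.frame(assortment = "timber",
                                            soil = "mineral_soil",
                                            carbon_Gg = -1)), "non-negative")
})

test_that("peat production factors scale linearly with area", {
  tab <- coef_df(row_of("wetland", "peat_production", "CH4", 0.06, 0),
                 row_of("wetland", "peat_production", "CO2", 1.75, 0.3),
                 row_of("wetland", "peat_production", "N2O", 0.009, 0))
  got <- peat_production_emissions(1026, tab)
  expect_equal(got$CO2$value, 1026 * 1.75)
  expect_equal(peat_production_emissions(0, tab)$CO2$value, 0)
  expect_equal(peat_production_emissions(2052, tab)$CH4$value,
               2 * got$CH4$value)
})

test_that("proxy allocation conserves municipal totals exactly", {
  muni <- matrix(c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L, NA), 3)
  # uniform proxy: total / n per cell
  tot <- data.frame(municipality = c(1, 2), total = c(8, 6))
  got <- allocate_by_proxy(tot, matrix(1, 3, 3), muni)
  expect_equal(got[muni == 1 & !is.na(muni)], rep(2, 4))
  expect_equal(got[muni == 2 & !is.na(muni)], rep(1.5, 4))
  # two municipalities, crafted weights: hand-normalized oracle
  w <- matrix(c(1, 3, 2, 0, 0, 4, 5, 1, 9), 3)
  got2 <- allocate_by_proxy(tot, w, muni)
  m1 <- muni == 1 & !is.na(muni)
  expect_equal(got2[m1], 8 * w[m1] / sum(w[m1]))
  expect_equal(sum(got2), 14)
  # property: conservation under random weights and totals
  set.seed(21)
  for (i in 1:10) {
    w <- matrix(runif(9), 3)
    t2 <- data.frame(municipality = c(1, 2), total = runif(2, 0, 100))
    expect_equal(sum(allocate_by_proxy(t2, w, muni)), sum(t2$total))
  }
  # biogenic CO2 rows allocate as zero
  tb <- data.frame(municipality = c(1, 2), total = c(8, 6),
                   biogenic = c(TRUE, FALSE))
  expect_equal(sum(allocate_by_proxy(tb, matrix(1, 3, 3), muni)), 6)
  # all-zero mask: uniform fallback or rejection
  wz <- matrix(0, 3, 3)
  expect_equal(allocate_by_proxy(tot, wz, muni)[muni == 1 & !is.na(muni)],
               rep(2, 4))
  expect_error(allocate_by_proxy(tot, wz, muni, fallback = FALSE), "proxy")
  # municipality absent from the grid is rejected
  t3 <- data.frame(municipality = 9, total = 1)
  expect_error(allocate_by_proxy(t3, matrix(1, 3, 3), muni), "no cells")
})

test_that("engines double their output when all areas double", {
  tab <- coef_df(
    row_of("wetland", "mire_class_1", "CH4", 0.3, 0.1),
    row_of("wetland", "mire_class_1", "N2O", 0.002, 0.001),
    row_of("wetland", "mire_class_1", "CO2", -0.1, 0.02))
  a <- mire_fluxes(c(mire_class_1 = 7), tab)
  b <- mire_fluxes(c(mire_class_1 = 14), tab)
  for (g in c("CH4", "N2O", "CO2")) {
    expect_equal(b[[g]]$value, 2 * a[[g]]$value)
    expect_equal(b[[g]]$sd, 2 * a[[g]]$sd)
  }
})
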