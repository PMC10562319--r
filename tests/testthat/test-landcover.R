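test_that("lake size classes follow the half-open interval convention", {
  expect_equal(classify_lake_size(0.5), 2L)
  expect_equal(classify_lake_size(100), 5L)   # boundary goes up
  expect_equal(classify_lake_size(0.1), 2L)
  expect_equal(classify_lake_size(0.01), 1L)
  expect_true(is.na(classify_lake_size(0.005)))  # below 1 ha: excluded
  expect_error(classify_lake_size(-1), "positive")
  # monotone: a larger lake never gets a smaller class
  set.seed(11)
  a <- sort(exp(runif(200, log(0.01), log(500))))
  expect_true(all(diff(classify_lake_size(a)) >= 0))
})

test_that("cropland classification splits organic soils by crop type", {
  expect_equal(classify_cropland("Fibric Histosol", "annual"),
               "organic_annual")
  expect_equal(classify_cropland("Gleyic Podzol", "perennial"),
               "organic_perennial")
  expect_equal(classify_cropland("Haplic Podzol", "annual"),
               "mineral_all_crops")
  # an unknown legend unit is rejected in strict mode, defaulted in lenient
  expect_error(classify_cropland("Basalt", "annual",
                                 mineral_soils = "Haplic Podzol"), "unknown")
  expect_warning(
    out <- classify_cropland("Basalt", "annual",
                             mineral_soils = "Haplic Podzol",
                             unknown = "mineral"),
    "mineral")
  expect_equal(out, "mineral_all_crops")
})

test_that("mire classification is a lookup that partitions the input", {
  rules <- read_mire_rules()
  # every rule row maps to its own class
  got <- classify_mire(rules[c("productivity", "main_class", "fertility")],
                       rules)
  expect_equal(as.integer(got), rules$mire_class)
  expect_equal(attr(got, "n_unclassified"), 0)
  # a full synthetic mire attribute raster partitions: class areas sum to
  # the total mire area
  set.seed(3)
  n <- 500
  attrs <- rules[sample(nrow(rules), n, replace = TRUE),
                 c("productivity", "main_class", "fertility")]
  cls <- classify_mire(attrs, rules)
  cell <- 0.0625
  expect_equal(sum(table(cls)) * cell, n * cell)
  # a gap in the rule table yields a counted unclassified signal
  gap <- rules[rules$mire_class != 4, ]
  expect_warning(cls2 <- classify_mire(attrs, gap), "unclassified")
  expect_equal(attr(cls2, "n_unclassified"), sum(is.na(cls2)))
  expect_gt(attr(cls2, "n_unclassified"), 0)
})

test_that("region-to-zone mapping is configurable and validated", {
  expect_equal(zone_of_region(17), "northern")
  expect_equal(zone_of_region(1), "southern")
  expect_equal(zone_of_region(c(16, 19)), c("southern", "northern"))
  expect_error(zone_of_region(25), "unknown region")
  expect_equal(zone_of_region(3, northern = 3, valid = 1:4), "northern")
})

test_that("fractional resampling conserves area against the geometric oracle", {
  # 16 m -> 250 m is not an integer ratio; use a 10x10 toy at 16 m
  set.seed(5)
  mask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  got <- resample_fractions(mask, 16, 250)
  want <- brute_force_resample(mask, 16, 250)
  expect_equal(unclass(got), want, ignore_attr = TRUE)
  expect_equal(attr(got, "area_ratio"), 1)
  expect_true(all(got >= 0 & got <= 1))
  # identity and empty masks
  ones <- resample_fractions(matrix(1, 50, 50), 25, 250)
  expect_equal(max(abs(ones - 1)), 0)
  expect_equal(sum(resample_fractions(matrix(0, 10, 10), 16, 250)), 0)
  # conservation on a half-covered mask
  half <- matrix(0, 12, 12); half[, 1:6] <- 1
  got2 <- resample_fractions(half, 16, 250)
  expect_equal(sum(got2) * 250^2, sum(half) * 16^2)
})

test_that("area accounting partitions the grid and uses registries for water", {
  g <- tiny_grid()
  at <- area_accounting(g)
  expect_s3_class(at, "area_table")
  expect_equal(sum(at$area_km2), 4 * 0.0625)
  expect_equal(at$area_km2[at$subcategory == "mineral_soil"], 0.0625)
  # waterbody areas come from registries, not cell counts
  lakes <- data.frame(area_km2 = c(0.5, 12, 0.004))  # last one excluded
  rivers <- data.frame(kind = c("polygon", "line"),
                       area_km2 = c(2, NA), length_km = c(NA, 100))
  at2 <- area_accounting(g, lakes, rivers)
  expect_equal(at2$area_km2[at2$subcategory == "lake_class_2"], 0.5)
  expect_equal(at2$area_km2[at2$subcategory == "lake_class_4"], 12)
  expect_equal(at2$area_km2[at2$subcategory == "river"], 2 + 0.35)
  expect_false("lake_class_1" %in% at2$subcategory)
  # fractions per category sum to 100
  for (cc in unique(at2$category))
    expect_equal(sum(at2$frac_of_category[at2$category == cc]), 100)
  expect_equal(sum(at2$frac_of_total), 100)
  # excluded cells reduce accounted area
  gx <- landscape_grid(matrix(c("forest", "excluded"), 1),
                       matrix(c("mineral_soil", NA), 1),
                       matrix(c(1L, NA), 1))
  expect_equal(sum(area_accounting(gx)$area_km2), 0.0625)
})

test_that("landscape grids validate co-registration and region coverage", {
  expect_error(landscape_grid(matrix("forest", 2, 2),
                              matrix("mineral_soil", 2, 3),
                              matrix(1L, 2, 2)), "dimensions")
  expect_error(landscape_grid(matrix("woodland", 1), matrix("x", 1),
                              matrix(1L, 1)), "unknown category")
  expect_error(landscape_grid(matrix("forest", 1), matrix("mineral_soil", 1),
                              matrix(NA_integer_, 1)), "region")
})
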