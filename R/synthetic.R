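#' Configuration for the synthetic landscape generator
#'
#' Defaults emulate the national study conditions: the five land-cover
#' categories at their published area fractions (artificial 3 %, arable 7 %,
#' forest 69 %, waterbody 11 %, wetland 10 %), the published subcategory
#' mixtures (e.g. forest 83 % mineral / 17 % drained peat; organic soils
#' about 9 % of arable land), lake areas log-uniform across all five size
#' classes including sub-minimum lakes that must be excluded, and a
#' southern/northern zone split. One seed fixes all randomness.
#'
#' @param seed Integer seed controlling every random draw.
#' @param nrow,ncol Grid dimensions (default 80 x 80 cells).
#' @param cell_size Cell edge (m, default 250).
#' @param n_regions Number of contiguous regions (Voronoi blocks).
#' @param northern_regions Region ids treated as the northern zone (default:
#'   the last region).
#' @param category_fractions Named target fractions for the five categories;
#'   must sum to <= 1, the remainder becomes `excluded` cells.
#' @param subcategory_weights Named list of per-category mixture weights.
#' @param n_lakes Number of lakes in the registry.
#' @param lake_area_range Log-uniform lake area range (km2); the default
#'   lower bound sits below the 0.01 km2 accounting minimum so exclusion is
#'   exercised.
#' @param block Patch size (cells) of the random category field.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1, nrow = 80, ncol = 80, cell_size = 250,
                             n_regions = 4, northern_regions = n_regions,
                             category_fractions = c(artificial = 0.03,
                                                    arable = 0.07,
                                                    forest = 0.69,
                                                    waterbody = 0.11,
                                                    wetland = 0.10),
                             subcategory_weights = NULL,
                             n_lakes = 60,
                             lake_area_range = c(0.005, 300),
                             block = 5) {
  if (any(category_fractions < 0) || sum(category_fractions) > 1 + 1e-9)
    stop("category fractions must be non-negative and sum to <= 1",
         call. = FALSE)
  if (is.null(subcategory_weights))
    subcategory_weights <- list(
      artificial = setNames(rep(1 / 6, 6),
                            subcategory_scheme()$subcategories$artificial),
      arable = c(livestock_production = 0.09, organic_annual = 0.04,
                 organic_perennial = 0.05, mineral_all_crops = 0.82),
      forest = c(mineral_soil = 0.83, drained_peatland = 0.17),
      waterbody = c(river = 1),
      wetland = c(peat_production = 0.03, mire_class_1 = 0.34,
                  mire_class_2 = 0.21, mire_class_3 = 0.21,
                  mire_class_4 = 0.21))
  structure(list(seed = seed, nrow = nrow, ncol = ncol,
                 cell_size = cell_size, n_regions = n_regions,
                 northern_regions = northern_regions,
                 category_fractions = category_fractions,
                 subcategory_weights = subcategory_weights,
                 n_lakes = n_lakes, lake_area_range = lake_area_range,
                 block = block),
            class = "synthetic_config")
}

# run code with a private RNG stream, restoring any prior global state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# patchy random field: coarse iid blocks upscaled + fine noise tie-break
.random_field <- function(nr, nc, block) {
  cb <- matrix(stats::rnorm(ceiling(nr / block) * ceiling(nc / block)),
               ceiling(nr / block))
  up <- kronecker(cb, matrix(1, block, block))[1:nr, 1:nc, drop = FALSE]
  up + matrix(stats::rnorm(nr * nc, sd = 0.01), nr, nc)
}

#' Generate a synthetic landscape with known ground truth
#'
#' Builds a full input bundle — co-registered grids (category, subcategory,
#' region, municipality), lake/river registries, sector activity totals, a
#' "true" coefficient table, a harvest input table, per-region populations
#' and a proxy weight layer — plus a ground-truth flux table computed by
#' direct per-cell / per-feature multiplication, independent of the flux
#' engines. Deterministic for a given seed; category cell counts hit the
#' target fractions exactly (rounded to whole cells).
#'
#' @param config A [synthetic_config()].
#' @return List: `grid` ([landscape_grid()]), `municipality` (matrix),
#'   `lakes`, `rivers`, `sector_totals`, `coefficients`, `harvest`,
#'   `populations`, `proxy` and `truth` (list with `components` per
#'   (component, gas) in Gg gas/yr and `total_co2eq_Tg`).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  .with_seed(config$seed, {
    nr <- config$nrow; nc <- config$ncol
    n <- nr * nc
    cell_km2 <- (config$cell_size / 1000)^2

    # regions: Voronoi over random seed points
    px <- stats::runif(config$n_regions, 1, nr)
    py <- stats::runif(config$n_regions, 1, nc)
    rows <- matrix(rep(seq_len(nr), nc), nr)
    cols <- matrix(rep(seq_len(nc), each = nr), nr)
    d2 <- vapply(seq_len(config$n_regions),
                 function(k) (rows - px[k])^2 + (cols - py[k])^2,
                 matrix(0, nr, nc))
    region <- matrix(apply(matrix(d2, n), 1, which.min), nr, nc)
    # two municipalities per region, split by the row coordinate
    municipality <- region * 10L + ifelse(rows <= stats::median(rows), 1L, 2L)

    # categories: rank ranges over a patchy field hit the target counts
    field <- .random_field(nr, nc, config$block)
    fr <- config$category_fractions
    counts <- round(fr * n)
    category <- matrix("excluded", nr, nc)
    ord <- order(field)
    pos <- 0
    for (k in seq_along(counts)) {
      take <- ord[seq_len(counts[k]) + pos]
      category[take] <- names(counts)[k]
      pos <- pos + counts[k]
    }

    # subcategories: per-category multinomial mixture
    subcategory <- matrix(NA_character_, nr, nc)
    for (cc in names(config$subcategory_weights)) {
      idx <- which(category == cc)
      w <- config$subcategory_weights[[cc]]
      if (length(idx) > 0)
        subcategory[idx] <- sample(names(w), length(idx), replace = TRUE,
                                   prob = w)
    }
    region[category == "excluded"] <- NA_integer_
    grid <- landscape_grid(category, subcategory, region, config$cell_size)

    # lake registry: log-uniform areas exercise all classes + exclusion
    la <- exp(stats::runif(config$n_lakes, log(config$lake_area_range[1]),
                           log(config$lake_area_range[2])))
    lakes <- data.frame(
      id = seq_len(config$n_lakes), area_km2 = la,
      size_class = suppressWarnings(classify_lake_size(la)),
      region = sample(config$n_regions, config$n_lakes, replace = TRUE),
      cover_phragmites = stats::runif(config$n_lakes, 0, 0.25),
      cover_equisetum = stats::runif(config$n_lakes, 0, 0.25))

    rivers <- data.frame(
      id = 1:7,
      kind = c(rep("polygon", 3), rep("line", 4)),
      area_km2 = c(stats::runif(3, 5, 50), rep(NA, 4)),
      length_km = c(rep(NA, 3), stats::runif(4, 10, 200)),
      region = sample(config$n_regions, 7, replace = TRUE))

    # sector activity totals (external-model style inputs), per municipality
    munis <- sort(unique(as.integer(municipality)))
    sectors <- subcategory_scheme()$subcategories$artificial
    sector_totals <- expand.grid(municipality = munis, sector = sectors,
                                 stringsAsFactors = FALSE)
    sector_totals$total <- stats::runif(nrow(sector_totals), 0, 20)
    sector_totals$biogenic <- FALSE
    sector_totals$biogenic[1] <- TRUE   # one excluded biogenic-CO2 row

    proxy <- matrix(stats::runif(n), nr, nc)

    # "true" coefficient table (Gg gas km-2 yr-1), zone-resolved for cropland
    rowslist <- list()
    addc <- function(category, subcategory, gas, zone, term, coefficient, sd)
      rowslist[[length(rowslist) + 1]] <<- data.frame(
        category = category, subcategory = subcategory, gas = gas,
        zone = zone, term = term, coefficient = coefficient, sd = sd,
        element = "", source = "synthetic-truth")
    for (sub in c("organic_annual", "organic_perennial", "mineral_all_crops"))
      for (z in c("southern", "northern"))
        addc("arable", sub, "CO2", z, "total", stats::runif(1, 0.5, 3), 0.1)
    for (k in 1:5) {
      sub <- paste0("lake_class_", k)
      addc("waterbody", sub, "CO2", "national", "evasion",
           stats::runif(1, 0.05, 0.3), 0.02)
      addc("waterbody", sub, "CH4", "national", "diffusion",
           stats::runif(1, 0.002, 0.02), 0.002)
      addc("waterbody", sub, "CH4", "national", "ebullition",
           stats::runif(1, 0.002, 0.02), 0.002)
    }
    addc("waterbody", "macrophyte_phragmites", "CH4", "national", "total",
         stats::runif(1, 0.01, 0.05), 0.005)
    addc("waterbody", "macrophyte_equisetum", "CH4", "national", "total",
         stats::runif(1, 0.01, 0.05), 0.005)
    addc("waterbody", "river", "CO2", "national", "total",
         stats::runif(1, 2, 8), 0.5)
    for (k in 1:4) {
      sub <- paste0("mire_class_", k)
      addc("wetland", sub, "CH4", "national", "total",
           stats::runif(1, 0.1, 0.6), 0.05)
      addc("wetland", sub, "N2O", "national", "total",
           stats::runif(1, 0.001, 0.01), 0.001)
      addc("wetland", sub, "CO2", "national", "total",
           -stats::runif(1, 0.05, 0.25), 0.02)  # ecosystem sink
    }
    addc("forest", "drained_peatland", "CH4", "national", "total",
         stats::runif(1, 0.005, 0.02), 0.002)
    addc("forest", "drained_peatland", "CO2", "national", "total", 0, 0)
    addc("forest", "drained_peatland", "N2O", "national", "total",
         stats::runif(1, 0.01, 0.05), 0.005)
    addc("wetland", "peat_production", "CH4", "national", "total",
         stats::runif(1, 0.01, 0.1), 0.01)
    addc("wetland", "peat_production", "CO2", "national", "total",
         stats::runif(1, 1, 2.5), 0.2)
    addc("wetland", "peat_production", "N2O", "national", "total",
         stats::runif(1, 0.001, 0.01), 0.001)
    coefs <- coefficient_table(do.call(rbind, rowslist))

    harvest <- data.frame(
      assortment = c("timber", "timber", "energywood", "energywood"),
      soil = rep(c("mineral_soil", "drained_peatland"), 2),
      carbon_Gg = stats::runif(4, 100, 2000),
      sd = stats::runif(4, 10, 100))

    populations <- data.frame(region = seq_len(config$n_regions),
                              population = round(stats::runif(
                                config$n_regions, 5e4, 1e6)))

    truth <- .ground_truth(grid, lakes, rivers, sector_totals, coefs,
                           harvest, config)
    list(grid = grid, municipality = municipality, lakes = lakes,
         rivers = rivers, sector_totals = sector_totals,
         coefficients = coefs, harvest = harvest,
         populations = populations, proxy = proxy, truth = truth,
         config = config)
  })
}

# direct-multiplication oracle: plain per-cell / per-feature accumulation,
# no engine code on this path
.ground_truth <- function(grid, lakes, rivers, sector_totals, coefs, harvest,
                          config) {
  cell <- grid$cell_area_km2
  lookup <- function(sub, gas, zone = "national", term = "total") {
    i <- which(coefs$subcategory == sub & coefs$gas == gas &
               coefs$term == term &
               (coefs$zone == zone | coefs$zone == "national"))
    coefs$coefficient[i[1]]
  }
  comp <- list()
  addt <- function(component, gas, value)
    comp[[length(comp) + 1]] <<- data.frame(component = component, gas = gas,
                                            value_Gg = value)
  # cropland soils: cell loop with the cell's zone
  for (sub in c("organic_annual", "organic_perennial", "mineral_all_crops")) {
    tot <- 0
    idx <- which(grid$category == "arable" & grid$subcategory == sub)
    for (i in idx) {
      z <- if (grid$region[i] %in% config$northern_regions) "northern"
           else "southern"
      tot <- tot + cell * lookup(sub, "CO2", z)
    }
    addt(sub, "CO2", tot)
  }
  # lakes: per-lake arithmetic with macrophyte substitution
  co2 <- ch4 <- 0
  for (i in seq_len(nrow(lakes))) {
    k <- lakes$size_class[i]
    if (is.na(k)) next
    a <- lakes$area_km2[i]
    sub <- paste0("lake_class_", k)
    cov <- lakes$cover_phragmites[i] + lakes$cover_equisetum[i]
    co2 <- co2 + a * lookup(sub, "CO2", term = "evasion")
    ch4 <- ch4 + a * (1 - cov) * (lookup(sub, "CH4", term = "diffusion") +
                                  lookup(sub, "CH4", term = "ebullition")) +
      a * lakes$cover_phragmites[i] * lookup("macrophyte_phragmites", "CH4") +
      a * lakes$cover_equisetum[i] * lookup("macrophyte_equisetum", "CH4")
  }
  addt("lakes", "CO2", co2)
  addt("lakes", "CH4", ch4)
  # rivers: width rule recomputed here
  r_area <- sum(rivers$area_km2[rivers$kind == "polygon"]) +
    sum(rivers$length_km[rivers$kind == "line"]) * 0.0035
  addt("rivers", "CO2", r_area * lookup("river", "CO2"))
  # mires and drained peat and peat production: per-cell accumulation
  acc <- new.env()
  for (g in c("CH4", "CO2", "N2O")) {
    assign(paste0("mire_", g), 0, acc)
    assign(paste0("dp_", g), 0, acc)
    assign(paste0("pp_", g), 0, acc)
  }
  for (i in which(grid$category == "wetland")) {
    sub <- grid$subcategory[i]
    pre <- if (sub == "peat_production") "pp_" else "mire_"
    for (g in c("CH4", "CO2", "N2O"))
      assign(paste0(pre, g),
             get(paste0(pre, g), acc) + cell * lookup(sub, g), acc)
  }
  for (i in which(grid$category == "forest" &
                  grid$subcategory == "drained_peatland"))
    for (g in c("CH4", "CO2", "N2O"))
      assign(paste0("dp_", g),
             get(paste0("dp_", g), acc) + cell * lookup("drained_peatland", g),
             acc)
  for (g in c("CH4", "CO2", "N2O")) {
    addt("mires", g, get(paste0("mire_", g), acc))
    addt("drained_peat_soil", g, get(paste0("dp_", g), acc))
    addt("peat_production", g, get(paste0("pp_", g), acc))
  }
  # harvest: C x 44/12
  addt("harvest", "CO2", sum(harvest$carbon_Gg) * 44 / 12)
  # artificial sector totals: already CO2eq mass, biogenic rows excluded
  art <- sum(ifelse(sector_totals$biogenic, 0, sector_totals$total))
  addt("artificial", "CO2", art)
  components <- do.call(rbind, comp)
  gwp <- c(CO2 = 1, CH4 = 28, N2O = 265)
  total <- sum(components$value_Gg * gwp[components$gas]) / 1000
  list(components = components, total_co2eq_Tg = total)
}

#' Run the accounting pipeline on a (synthetic) landscape
#'
#' The engine-route counterpart of the generator's ground truth: areas from
#' [area_accounting()], cropland soils through [coefficient_flux()] with
#' zone resolution via [zone_of_region()], lakes through [lake_emissions()],
#' rivers through [river_area()] + [river_emissions()], mires through
#' [mire_fluxes()] on class areas, drained peat and peat production through
#' their engines, harvest through [harvest_emissions()] and sector totals
#' through [allocate_by_proxy()] (summed back off the grid).
#'
#' @param landscape As from [generate_landscape()].
#' @return List: `components` data frame (component, gas, value_Gg),
#'   `total_co2eq_Tg`, `areas` (the area table) and `allocation` (the
#'   gridded artificial-surface emissions).
#' @export
run_pipeline <- function(landscape) {
  grid <- landscape$grid
  coefs <- landscape$coefficients
  config <- landscape$config
  cell <- grid$cell_area_km2
  comp <- list()
  addt <- function(component, gas, value)
    comp[[length(comp) + 1]] <<- data.frame(component = component, gas = gas,
                                            value_Gg = value)
  areas <- area_accounting(grid, landscape$lakes, landscape$rivers)
  sc <- function(sub) {  # calibration scale of a grid-based subcategory
    s <- attr(grid, "area_scale")
    if (!is.null(s) && sub %in% names(s)) s[[sub]] else 1
  }
  zone <- matrix(NA_character_, nrow(grid$region), ncol(grid$region))
  live <- !is.na(grid$region)
  zone[live] <- zone_of_region(grid$region[live],
                               northern = config$northern_regions,
                               valid = seq_len(config$n_regions))
  for (sub in c("organic_annual", "organic_perennial", "mineral_all_crops")) {
    v <- 0
    for (z in c("southern", "northern")) {
      a <- sum(grid$category == "arable" & grid$subcategory == sub &
               !is.na(zone) & zone == z) * cell * sc(sub)
      v <- v + coefficient_flux(a, sub, "CO2", coefs, zone = z)$value
    }
    addt(sub, "CO2", v)
  }
  lk <- lake_emissions(landscape$lakes, coefs)
  addt("lakes", "CO2", lk$CO2$value)
  addt("lakes", "CH4", lk$CH4$value)
  addt("rivers", "CO2",
       river_emissions(river_area(landscape$rivers), coefs)$value)
  mire_areas <- vapply(paste0("mire_class_", 1:4), function(sub)
    sum(grid$category == "wetland" & grid$subcategory == sub) * cell * sc(sub),
    numeric(1))
  mr <- mire_fluxes(mire_areas, coefs)
  dp_area <- sum(grid$category == "forest" &
                 grid$subcategory == "drained_peatland") * cell *
    sc("drained_peatland")
  dp <- drained_peat_soil_fluxes(dp_area, coefs)
  pp_area <- sum(grid$category == "wetland" &
                 grid$subcategory == "peat_production") * cell *
    sc("peat_production")
  pp <- peat_production_emissions(pp_area, coefs)
  for (g in c("CH4", "CO2", "N2O")) {
    addt("mires", g, mr[[g]]$value)
    addt("drained_peat_soil", g, dp[[g]]$value)
    addt("peat_production", g, pp[[g]]$value)
  }
  addt("harvest", "CO2", harvest_emissions(landscape$harvest)$total$value)
  alloc <- allocate_by_proxy(landscape$sector_totals, landscape$proxy,
                             landscape$municipality)
  addt("artificial", "CO2", sum(alloc))
  components <- do.call(rbind, comp)
  gwp <- c(CO2 = 1, CH4 = 28, N2O = 265)
  total <- sum(components$value_Gg * gwp[components$gas]) / 1000
  list(components = components, total_co2eq_Tg = total, areas = areas,
       allocation = alloc)
}

#' Rescale a landscape so its accounting matches a target area table
#'
#' Per-subcategory multiplicative scaling: grid-based subcategory areas get
#' a scale factor applied in [area_accounting()]; lake areas are scaled
#' within their (fixed) size class and river areas/lengths by the river
#' scale, so registries stay consistent with the accounting.
#'
#' @param landscape As from [generate_landscape()].
#' @param target Data frame with `subcategory`, `area_km2` (subcategories
#'   must exist in the landscape with nonzero area).
#' @return The landscape with scaled registries and an `area_scale`
#'   attribute on the grid.
#' @export
calibrate_to_areas <- function(landscape, target) {
  stopifnot(all(c("subcategory", "area_km2") %in% names(target)))
  current <- area_accounting(landscape$grid, landscape$lakes,
                             landscape$rivers)
  cur <- setNames(current$area_km2, current$subcategory)
  missing <- setdiff(target$subcategory, names(cur))
  if (length(missing) > 0)
    stop("target subcategories absent from landscape: ",
         paste(missing, collapse = ", "), call. = FALSE)
  scale <- setNames(target$area_km2 / cur[target$subcategory],
                    target$subcategory)
  if (any(!is.finite(scale)))
    stop("zero landscape area for a nonzero target", call. = FALSE)
  lake_subs <- grep("^lake_class_", names(scale), value = TRUE)
  if (length(lake_subs) > 0) {
    cls <- paste0("lake_class_", landscape$lakes$size_class)
    idx <- match(cls, names(scale))
    f <- ifelse(is.na(idx), 1, scale[idx])
    landscape$lakes$area_km2 <- landscape$lakes$area_km2 * f
  }
  if ("river" %in% names(scale)) {
    pol <- landscape$rivers$kind == "polygon"
    landscape$rivers$area_km2[pol] <-
      landscape$rivers$area_km2[pol] * scale[["river"]]
    landscape$rivers$length_km[!pol] <-
      landscape$rivers$length_km[!pol] * scale[["river"]]
  }
  grid_scale <- scale[setdiff(names(scale), c(lake_subs, "river"))]
  attr(landscape$grid, "area_scale") <- grid_scale
  landscape
}
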