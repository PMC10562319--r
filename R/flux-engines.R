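#' Read and validate an emission-coefficient table
#'
#' Coefficient tables are pure data: one row per (subcategory, gas, term,
#' zone) with an area-based rate. Canonical coefficient unit is Gg gas per
#' km2 per year; rows flagged with `element` `"C"` or `"N"` carry the rate in
#' elemental mass instead and are converted through the molar-mass ratio
#' before use. `zone` is `"southern"`, `"northern"` or `"national"`; `term`
#' distinguishes flux pathways within one gas (e.g. lake CH4 `diffusion` vs
#' `ebullition`), defaulting to `"total"`.
#'
#' @param path CSV file; `#` lines are comments. Required columns:
#'   `category`, `subcategory`, `gas`, `coefficient`, `sd`. Optional:
#'   `zone`, `term`, `element`, `source`.
#' @return Data frame with class `"coefficient_table"`.
#' @export
read_coefficient_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  coefficient_table(df)
}

#' @rdname read_coefficient_table
#' @param df Data frame in the same schema.
#' @export
coefficient_table <- function(df) {
  need <- c("category", "subcategory", "gas", "coefficient", "sd")
  if (!all(need %in% names(df)))
    stop("coefficient table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!"zone" %in% names(df)) df$zone <- "national"
  if (!"term" %in% names(df)) df$term <- "total"
  if (!"element" %in% names(df)) df$element <- ""
  df$element[is.na(df$element)] <- ""
  if (any(is.na(df$sd)) || any(df$sd < 0))
    stop("coefficient SDs must be non-negative", call. = FALSE)
  if (!all(df$gas %in% c("CO2", "CH4", "N2O")))
    stop("gas must be CO2, CH4 or N2O", call. = FALSE)
  if (!all(df$zone %in% c("southern", "northern", "national")))
    stop("zone must be southern, northern or national", call. = FALSE)
  if (anyDuplicated(df[c("subcategory", "gas", "term", "zone")]))
    stop("duplicate coefficient rows for the same key", call. = FALSE)
  structure(df, class = c("coefficient_table", "data.frame"))
}

# resolve one coefficient row; zonal lookup falls back to the national row
.lookup_coefficient <- function(table, subcategory, gas, zone = "national",
                                term = "total") {
  hit <- table$subcategory == subcategory & table$gas == gas &
    table$term == term & table$zone == zone
  if (!any(hit) && zone != "national")
    hit <- table$subcategory == subcategory & table$gas == gas &
      table$term == term & table$zone == "national"
  if (sum(hit) != 1)
    stop(sprintf("no coefficient for (%s, %s, %s, %s)",
                 subcategory, gas, term, zone), call. = FALSE)
  row <- table[hit, ]
  if (nzchar(row$element)) {  # elemental rate: convert to gas mass
    f <- element_to_gas(row$coefficient, gas, row$element, row$sd)
    row$coefficient <- f$value
    row$sd <- f$sd
  }
  row
}

#' Area-based coefficient flux
#'
#' The elementary engine: flux = area x coefficient, SD = area x coefficient
#' SD (areas are treated as exact; only coefficient uncertainty propagates).
#'
#' @param area_km2 Area (km2), >= 0.
#' @param subcategory,gas,zone,term Lookup key; zonal rows fall back to the
#'   national row.
#' @param table A [coefficient_table()].
#' @return A `gas_flux` in Gg gas / yr.
#' @export
coefficient_flux <- function(area_km2, subcategory, gas, table,
                             zone = "national", term = "total") {
  stopifnot(is.numeric(area_km2), length(area_km2) == 1, area_km2 >= 0)
  row <- .lookup_coefficient(table, subcategory, gas, zone, term)
  gas_flux(gas, area_km2 * row$coefficient, area_km2 * row$sd)
}

#' Lake GHG emissions from a lake registry
#'
#' Per lake: CO2 = area x evasion coefficient of its size class; CH4 =
#' open-water area x (diffusion + ebullition coefficients) plus, for each
#' emergent macrophyte species group, area x cover fraction x species
#' coefficient. Open-water area is `area x (1 - sum of covers)`: covered
#' area emits through the species coefficient instead of the open-water
#' terms (substitution; `macrophyte = "additive"` keeps the full area on the
#' open-water terms as a sensitivity mode). Lake totals are summed per gas
#' with quadrature SDs over lakes.
#'
#' @param lakes Data frame with `area_km2`, optional `size_class` (computed
#'   via [classify_lake_size()] if absent; sub-minimum lakes are excluded),
#'   optional cover columns `cover_phragmites`, `cover_equisetum` in `[0,1]`,
#'   optional `region`.
#' @param table Coefficient table with rows (subcategory `lake_class_k`, gas
#'   `CO2`, term `evasion`), (`CH4`, `diffusion`), (`CH4`, `ebullition`) and
#'   species rows (subcategory `macrophyte_phragmites` /
#'   `macrophyte_equisetum`, gas `CH4`).
#' @param macrophyte `"substitute"` (default) or `"additive"`.
#' @return List of `gas_flux` totals (`CO2`, `CH4`) plus `per_lake`, a data
#'   frame of per-lake fluxes (Gg/yr).
#' @export
lake_emissions <- function(lakes, table,
                           macrophyte = c("substitute", "additive")) {
  macrophyte <- match.arg(macrophyte)
  stopifnot("area_km2" %in% names(lakes))
  cls <- if ("size_class" %in% names(lakes)) lakes$size_class
         else classify_lake_size(lakes$area_km2)
  keep <- !is.na(cls)
  lakes <- lakes[keep, , drop = FALSE]
  cls <- cls[keep]
  species <- c(phragmites = "macrophyte_phragmites",
               equisetum = "macrophyte_equisetum")
  n <- nrow(lakes)
  co2 <- ch4 <- co2_sd <- ch4_sd <- numeric(n)
  for (i in seq_len(n)) {
    sub <- paste0("lake_class_", cls[i])
    a <- lakes$area_km2[i]
    cover <- vapply(names(species), function(s) {
      col <- paste0("cover_", s)
      if (col %in% names(lakes) && !is.na(lakes[[col]][i])) lakes[[col]][i] else 0
    }, numeric(1))
    if (sum(cover) > 1)
      stop("macrophyte cover fractions exceed 1 for lake ", i, call. = FALSE)
    ev <- .lookup_coefficient(table, sub, "CO2", term = "evasion")
    di <- .lookup_coefficient(table, sub, "CH4", term = "diffusion")
    eb <- .lookup_coefficient(table, sub, "CH4", term = "ebullition")
    open <- if (macrophyte == "substitute") a * (1 - sum(cover)) else a
    co2[i] <- a * ev$coefficient
    co2_sd[i] <- a * ev$sd
    v <- open * (di$coefficient + eb$coefficient)
    s2 <- (open * di$sd)^2 + (open * eb$sd)^2
    for (s in names(species)) {
      if (cover[[s]] > 0) {
        mc <- .lookup_coefficient(table, species[[s]], "CH4")
        v <- v + a * cover[[s]] * mc$coefficient
        s2 <- s2 + (a * cover[[s]] * mc$sd)^2
      }
    }
    ch4[i] <- v
    ch4_sd[i] <- sqrt(s2)
  }
  list(
    CO2 = gas_flux("CO2", sum(co2), sqrt(sum(co2_sd^2))),
    CH4 = gas_flux("CH4", sum(ch4), sqrt(sum(ch4_sd^2))),
    per_lake = data.frame(size_class = cls, area_km2 = lakes$area_km2,
                          co2_Gg = co2, ch4_Gg = ch4)
  )
}

#' Total river surface area from a river registry
#'
#' Wide rivers are mapped as polygons and contribute their mapped area;
#' narrow rivers (under 5 m) are mapped as lines and contribute
#' length x 3.5 m assumed average width.
#'
#' @param rivers Data frame with `kind` (`"polygon"`/`"line"`) and either
#'   `area_km2` (polygons) or `length_km` (lines).
#' @param narrow_width_m Assumed width for line rivers (default 3.5).
#' @return Total river area (km2).
#' @export
river_area <- function(rivers, narrow_width_m = 3.5) {
  stopifnot("kind" %in% names(rivers),
            all(rivers$kind %in% c("polygon", "line")))
  a <- 0
  pol <- rivers$kind == "polygon"
  if (any(pol)) {
    stopifnot(all(!is.na(rivers$area_km2[pol])))
    a <- a + sum(rivers$area_km2[pol])
  }
  lin <- rivers$kind == "line"
  if (any(lin)) {
    stopifnot(all(!is.na(rivers$length_km[lin])))
    a <- a + sum(rivers$length_km[lin]) * (narrow_width_m / 1000)
  }
  a
}

#' River CO2 emissions
#'
#' @param river_area_km2 Total river surface area (km2).
#' @param table Coefficient table with a (subcategory `river`, gas `CO2`)
#'   row.
#' @return A `gas_flux` (CO2, Gg/yr).
#' @export
river_emissions <- function(river_area_km2, table) {
  coefficient_flux(river_area_km2, "river", "CO2", table)
}

#' Undrained-mire fluxes by mire class
#'
#' Soil CH4 and N2O emissions plus the ecosystem CO2 balance (a
#' sequestration flux, negative) per mire class, each area x coefficient,
#' summed over classes with quadrature SDs. CH4 uptake is not netted against
#' the ecosystem CO2 term (emission and sequestration are kept separate).
#'
#' @param class_areas_km2 Named numeric vector of areas per
#'   `mire_class_1..4` (missing classes treated as zero area).
#' @param table Coefficient table with rows per mire class for `CH4`, `N2O`
#'   and `CO2` (the CO2 coefficient is the net ecosystem balance, negative
#'   for a sink).
#' @return List of `gas_flux`: `CH4`, `N2O` (emissions) and `CO2`
#'   (ecosystem balance, negative for a sink).
#' @export
mire_fluxes <- function(class_areas_km2, table) {
  classes <- paste0("mire_class_", 1:4)
  areas <- setNames(numeric(4), classes)
  areas[names(class_areas_km2)] <- class_areas_km2
  per_gas <- lapply(c(CH4 = "CH4", N2O = "N2O", CO2 = "CO2"), function(g) {
    v <- s <- numeric(4)
    for (k in seq_along(classes)) {
      if (areas[k] == 0) next
      row <- .lookup_coefficient(table, classes[k], g)
      v[k] <- areas[k] * row$coefficient
      s[k] <- areas[k] * row$sd
    }
    gas_flux(g, sum(v), sqrt(sum(s^2)))
  })
  per_gas
}

#' Derive the net ecosystem CO2 coefficient of an undrained mire
#'
#' From the long-term apparent rate of carbon accumulation in the peat
#' column, with the CH4-C flux and a constant net leaching export closing
#' the carbon mass balance: accumulation = -CO2C - CH4C - leachC (fluxes to
#' the atmosphere/water positive, so the CO2-C term of an accumulating mire
#' is negative, a sink). Terms can be switched off to expose the convention
#' (e.g. a balance excluding CH4-C).
#'
#' @param accumulation_gC_m2 Long-term C accumulation rate (g C m-2 yr-1,
#'   >= 0 magnitude).
#' @param ch4_c_gC_m2 CH4-C emission (g C m-2 yr-1, >= 0).
#' @param leaching_gC_m2 Net C leaching export (g C m-2 yr-1, >= 0).
#' @param include_ch4,include_leaching Convention switches; both default on.
#' @return Net ecosystem CO2 coefficient in Gg CO2 km-2 yr-1 (negative =
#'   sink), with attribute `co2_c_gC_m2` (the CO2-C balance term).
#' @export
derive_mire_co2_coefficient <- function(accumulation_gC_m2, ch4_c_gC_m2 = 0,
                                        leaching_gC_m2 = 0,
                                        include_ch4 = TRUE,
                                        include_leaching = TRUE) {
  stopifnot(accumulation_gC_m2 >= 0, ch4_c_gC_m2 >= 0, leaching_gC_m2 >= 0)
  co2_c <- -(accumulation_gC_m2 +
             (if (include_ch4) ch4_c_gC_m2 else 0) +
             (if (include_leaching) leaching_gC_m2 else 0))
  # g C m-2 yr-1 == Gg C km-2 yr-1 x 1e-3? 1 g/m2 = 1e6 g/km2 = 1 Mg/km2 = 1e-3 Gg/km2
  co2_c_gg_km2 <- co2_c * 1e-3
  coef <- element_to_gas(co2_c_gg_km2, "CO2", "C")$value
  structure(coef, co2_c_gC_m2 = co2_c)
}

#' Drained-peatland forest soil fluxes
#'
#' CH4, CO2 and N2O soil emissions of forestry-drained peat, each
#' area x coefficient.
#'
#' @param area_km2 Drained-peat forest area (km2).
#' @param table Coefficient table with rows (subcategory
#'   `drained_peatland`, gas in CH4/CO2/N2O).
#' @return List of `gas_flux` per gas.
#' @export
drained_peat_soil_fluxes <- function(area_km2, table) {
  lapply(c(CH4 = "CH4", CO2 = "CO2", N2O = "N2O"), function(g)
    coefficient_flux(area_km2, "drained_peatland", g, table))
}

#' Harvest carbon emissions
#'
#' All harvested carbon is accounted as an immediate CO2 emission (no wood
#' product storage): each harvested-C mass converts C to CO2 (x 44/12) and
#' then to CO2eq (GWP 1).
#'
#' @param harvest Data frame with `assortment` (`"timber"`/`"energywood"`),
#'   `soil` (`"mineral_soil"`/`"drained_peatland"`), `carbon_Gg` (>= 0) and
#'   optional `sd` (Gg C).
#' @return List: `components` (data frame with CO2eq flux and SD per row,
#'   Gg CO2eq/yr) and `total` (a `co2eq_flux`, quadrature SD).
#' @export
harvest_emissions <- function(harvest) {
  need <- c("assortment", "soil", "carbon_Gg")
  stopifnot(all(need %in% names(harvest)))
  if (any(harvest$carbon_Gg < 0))
    stop("harvested carbon must be non-negative", call. = FALSE)
  if (!"sd" %in% names(harvest)) harvest$sd <- 0
  fl <- mapply(function(c_gg, sd) {
    f <- to_co2eq(element_to_gas(c_gg, "CO2", "C", sd))
    c(f$value, f$sd)
  }, harvest$carbon_Gg, harvest$sd)
  comp <- data.frame(assortment = harvest$assortment, soil = harvest$soil,
                     co2eq_Gg = fl[1, ], sd_Gg = fl[2, ])
  tot <- combine_uncertainty(comp$co2eq_Gg, comp$sd_Gg)
  list(components = comp, total = co2eq_flux(tot$value, tot$sd))
}

#' Peat-production-site emissions
#'
#' National emission factors (per gas) applied to the peat-extraction area;
#' spatial allocation of the national totals is done separately via
#' [allocate_by_proxy()].
#'
#' @param area_km2 Peat production area (km2).
#' @param table Coefficient table with rows (subcategory `peat_production`,
#'   gas in CH4/CO2/N2O).
#' @return List of `gas_flux` per gas.
#' @export
peat_production_emissions <- function(area_km2, table) {
  lapply(c(CH4 = "CH4", CO2 = "CO2", N2O = "N2O"), function(g)
    coefficient_flux(area_km2, "peat_production", g, table))
}

#' Allocate sector totals onto a grid by a proxy weight layer
#'
#' Each municipality's total is spread over its cells proportionally to the
#' proxy weights inside its mask: cell value = total x weight / sum of
#' weights in the municipality. Allocation conserves each municipal total
#' exactly. A municipality whose mask has no positive weight falls back to a
#' uniform spread over the mask (or errors with `fallback = FALSE`).
#' Totals flagged biogenic CO2 are allocated as zero (excluded to avoid
#' double counting).
#'
#' @param totals Data frame with `municipality`, `total` (>= 0) and optional
#'   logical `biogenic`.
#' @param proxy Non-negative numeric matrix of weights.
#' @param municipality_grid Integer matrix (same dim) of municipality ids;
#'   `NA` outside all masks.
#' @param fallback Uniform fallback on all-zero masks (default TRUE).
#' @return Matrix of allocated emissions, same dim as `proxy`.
#' @export
allocate_by_proxy <- function(totals, proxy, municipality_grid,
                              fallback = TRUE) {
  stopifnot(is.matrix(proxy), all(dim(proxy) == dim(municipality_grid)))
  if (any(is.na(proxy)) || any(proxy < 0))
    stop("proxy weights must be non-negative", call. = FALSE)
  if (any(totals$total < 0)) stop("totals must be non-negative", call. = FALSE)
  if (!"biogenic" %in% names(totals)) totals$biogenic <- FALSE
  out <- matrix(0, nrow(proxy), ncol(proxy))
  agg <- tapply(ifelse(totals$biogenic, 0, totals$total),
                totals$municipality, sum)
  for (m in names(agg)) {
    mask <- !is.na(municipality_grid) & as.character(municipality_grid) == m
    if (!any(mask)) {
      if (agg[[m]] > 0)
        stop("municipality ", m, " has no cells on the grid", call. = FALSE)
      next
    }
    w <- proxy[mask]
    if (sum(w) == 0) {
      if (!fallback)
        stop("municipality ", m, " has no positive proxy weight",
             call. = FALSE)
      w <- rep(1, length(w))
    }
    out[mask] <- out[mask] + agg[[m]] * w / sum(w)
  }
  out
}
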