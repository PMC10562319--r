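#' Emission intensity
#'
#' Net emission divided by area, on the conventional reporting scale:
#' intensity (Gg CO2eq km-2 yr-1) = 1000 x net (Tg CO2eq yr-1) / area (km2).
#' Sign follows the net; zero or missing area yields `NA` (reported as
#' missing, never as infinity).
#'
#' @param net_Tg Net emission (Tg CO2eq / yr), vectorised.
#' @param area_km2 Area (km2), vectorised.
#' @return Intensity in Gg CO2eq km-2 yr-1.
#' @examples
#' intensity(45.68, 7973)  # 5.73
#' @export
intensity <- function(net_Tg, area_km2) {
  out <- 1000 * net_Tg / area_km2
  out[is.na(area_km2) | area_km2 <= 0] <- NA_real_
  out
}

#' Per-capita net emission
#'
#' net (Tg CO2eq / yr) x 1e6 / population, in Mg CO2eq per person per year.
#' Zero or missing population yields `NA`.
#'
#' @param net_Tg Net emission (Tg CO2eq / yr), vectorised.
#' @param population Population count, vectorised.
#' @return Mg CO2eq yr-1 per person.
#' @examples
#' per_capita(53.931, 5503664)  # 9.8
#' @export
per_capita <- function(net_Tg, population) {
  out <- net_Tg * 1e6 / population
  out[is.na(population) | population <= 0] <- NA_real_
  out
}

#' Aggregate fluxes to administrative regions
#'
#' Sums a long flux table to per-region emission, sink and net, then derives
#' intensity and per-capita values. Sinks are carried as negative numbers.
#' Negative nets, intensities and per-capita values are legal (carbon-sink
#' regions) and are never clamped.
#'
#' @param flux_table Data frame with `region`, `emission_Tg` (>= 0) and
#'   `sink_Tg` (<= 0), one or more rows per region (e.g. one per category).
#' @param region_areas Data frame with `region`, `area_km2`.
#' @param populations Data frame with `region`, `population`. Optional.
#' @return Data frame (class `region_summary`): one row per region with
#'   `emission_Tg`, `sink_Tg`, `net_Tg`, `area_km2`, `intensity`,
#'   `population`, `per_capita`; attribute `total` holds the all-region
#'   rollup (national population may be supplied via attribute on
#'   `populations`, else the column sum).
#' @export
regional_aggregate <- function(flux_table, region_areas, populations = NULL) {
  stopifnot(all(c("region", "emission_Tg", "sink_Tg") %in% names(flux_table)),
            all(c("region", "area_km2") %in% names(region_areas)))
  if (!all(flux_table$region %in% region_areas$region))
    stop("flux rows for regions missing from 'region_areas': ",
         paste(setdiff(flux_table$region, region_areas$region),
               collapse = ", "), call. = FALSE)
  em <- tapply(flux_table$emission_Tg, flux_table$region, sum)
  si <- tapply(flux_table$sink_Tg, flux_table$region, sum)
  out <- data.frame(region = names(em),
                    emission_Tg = as.numeric(em),
                    sink_Tg = as.numeric(si))
  out <- merge(out, region_areas, by = "region", all.x = TRUE)
  out$net_Tg <- out$emission_Tg + out$sink_Tg
  out$intensity <- intensity(out$net_Tg, out$area_km2)
  if (!is.null(populations)) {
    out <- merge(out, populations[c("region", "population")],
                 by = "region", all.x = TRUE)
    out$per_capita <- per_capita(out$net_Tg, out$population)
  } else {
    out$population <- NA_real_
    out$per_capita <- NA_real_
  }
  # keep the caller's region order
  out <- out[match(unique(as.character(flux_table$region)),
                   as.character(out$region)), ]
  rownames(out) <- NULL
  nat_pop <- if (!is.null(populations))
    attr(populations, "national_population") %||% sum(populations$population)
  else NA_real_
  total <- data.frame(
    region = "total",
    emission_Tg = sum(out$emission_Tg),
    sink_Tg = sum(out$sink_Tg),
    area_km2 = sum(out$area_km2),
    net_Tg = sum(out$net_Tg))
  total$intensity <- intensity(total$net_Tg, total$area_km2)
  total$population <- nat_pop
  total$per_capita <- per_capita(total$net_Tg, nat_pop)
  structure(out, class = c("region_summary", "data.frame"), total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-region sums of a gridded value layer
#'
#' Zonal sum: adds the values of `value_grid` over each region of the region
#' label grid. A brute-force building block for rolling gridded emissions up
#' to regions.
#'
#' @param value_grid Numeric matrix.
#' @param region_grid Integer matrix of region labels (same dim; `NA`
#'   outside).
#' @return Named numeric vector of sums per region.
#' @export
region_totals_from_grid <- function(value_grid, region_grid) {
  stopifnot(all(dim(value_grid) == dim(region_grid)))
  keep <- !is.na(region_grid)
  tapply(value_grid[keep], region_grid[keep], sum)
}

#' National rollup of category fluxes
#'
#' Builds the national ledger from per-category emission and sink totals:
#' total emission = sum of category emissions (SD by quadrature), total sink
#' = sum of sinks (negative; SD by quadrature unless `sink_sd_override`
#' supplies an externally derived value), net = emission + sink with the two
#' SDs combined in quadrature. Per-gas CO2eq columns are preserved when
#' present.
#'
#' @param categories Data frame, one row per land-cover category:
#'   `category`, `emission_Tg`, `emission_sd`, `sink_Tg` (<= 0, 0 if none),
#'   `sink_sd`; optional per-gas columns `ch4`, `co2`, `n2o` and sink gas
#'   column `sink_co2`.
#' @param sink_sd_override Optional SD for the total sink carried through
#'   unchanged (e.g. a Monte-Carlo-derived value).
#' @param required_categories Categories that must all be present.
#' @return List with `emission`, `sink`, `net` (each a `co2eq_flux` in
#'   Tg CO2eq/yr), per-gas totals `by_gas`, and the input `categories`.
#' @export
national_rollup <- function(categories, sink_sd_override = NULL,
                            required_categories = c("artificial", "arable",
                                                    "forest", "waterbody",
                                                    "wetland")) {
  need <- c("category", "emission_Tg", "emission_sd", "sink_Tg", "sink_sd")
  stopifnot(all(need %in% names(categories)))
  missing <- setdiff(required_categories, categories$category)
  if (length(missing) > 0)
    stop("missing land-cover categories: ",
         paste(missing, collapse = ", "), call. = FALSE)
  em <- combine_uncertainty(categories$emission_Tg, categories$emission_sd)
  si <- combine_uncertainty(categories$sink_Tg, categories$sink_sd)
  if (!is.null(sink_sd_override)) si$sd <- sink_sd_override
  emission <- co2eq_flux(em$value, em$sd, "TgCO2eq/yr")
  sink <- co2eq_flux(si$value, si$sd, "TgCO2eq/yr")
  net <- net_flux(emission, sink)
  by_gas <- NULL
  if (all(c("ch4", "co2", "n2o") %in% names(categories))) {
    sink_co2 <- if ("sink_co2" %in% names(categories))
      sum(categories$sink_co2) else si$value
    by_gas <- data.frame(
      gas = c("CH4", "CO2", "N2O"),
      emission_Tg = c(sum(categories$ch4), sum(categories$co2),
                      sum(categories$n2o)),
      net_Tg = c(sum(categories$ch4), sum(categories$co2) + sink_co2,
                 sum(categories$n2o)))
  }
  list(emission = emission, sink = sink, net = net, by_gas = by_gas,
       categories = categories)
}

#' Build the atmosphere flux ledger from a national rollup
#'
#' One directed entry per (source category, gas) with positive flux from the
#' source to the atmosphere, and one per sink from the atmosphere to the
#' ecosystem. Entry values are non-negative; the atmosphere balance (inflows
#' minus outflows) equals the national net.
#'
#' @param rollup A [national_rollup()] result whose `categories` carry
#'   per-gas columns `ch4`, `co2`, `n2o` and `sink_Tg`.
#' @return Data frame (`source`, `target`, `gas`, `value_Tg`) with attribute
#'   `balance_Tg`.
#' @export
build_flux_ledger <- function(rollup) {
  cats <- rollup$categories
  stopifnot(all(c("ch4", "co2", "n2o") %in% names(cats)))
  rows <- list()
  for (i in seq_len(nrow(cats))) {
    for (g in c("ch4", "co2", "n2o")) {
      v <- cats[[g]][i]
      if (!is.na(v) && v > 0)
        rows[[length(rows) + 1]] <- data.frame(
          source = cats$category[i], target = "atmosphere",
          gas = toupper(g), value_Tg = v)
    }
    if (cats$sink_Tg[i] < 0)
      rows[[length(rows) + 1]] <- data.frame(
        source = "atmosphere", target = paste0(cats$category[i], "_sink"),
        gas = "CO2", value_Tg = -cats$sink_Tg[i])
  }
  ledger <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               gas = character(), value_Tg = numeric())
  inflow <- sum(ledger$value_Tg[ledger$target == "atmosphere"])
  outflow <- sum(ledger$value_Tg[ledger$source == "atmosphere"])
  structure(ledger, balance_Tg = inflow - outflow)
}
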