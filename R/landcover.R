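#' Land-cover categories and subcategory scheme
#'
#' The closed lists of category and subcategory codes used throughout the
#' accounting. Categories: artificial surfaces, arable land, forest,
#' waterbodies, wetland, plus an `excluded` code for cells outside the
#' accounting (NoData, grasslands, unproductive forest land and the like,
#' which contribute neither area nor flux).
#'
#' @return Named list: `categories` (character vector) and `subcategories`
#'   (named list of character vectors per category).
#' @export
subcategory_scheme <- function() {
  list(
    categories = c("artificial", "arable", "forest", "waterbody", "wetland",
                   "excluded"),
    subcategories = list(
      artificial = c("energy", "industry", "road_traffic", "machinery",
                     "residential_combustion", "waste"),
      arable     = c("livestock_production", "organic_annual",
                     "organic_perennial", "mineral_all_crops"),
      forest     = c("mineral_soil", "drained_peatland"),
      waterbody  = c("river", paste0("lake_class_", 1:5)),
      wetland    = c("peat_production", paste0("mire_class_", 1:4)),
      excluded   = character()
    )
  )
}

#' Construct a landscape accounting grid
#'
#' Co-registered integer rasters, stored as plain matrices (row-major,
#' origin at the north-west corner): land-cover category, subcategory and
#' region label per cell. Category and subcategory are coded as character
#' matrices using the [subcategory_scheme()] codes; region is an integer
#' matrix. Cells with category `"excluded"` (or `NA`) never contribute area
#' or flux and need no region.
#'
#' @param category Character matrix of category codes.
#' @param subcategory Character matrix of subcategory codes (same dim).
#' @param region Integer matrix of region identifiers (same dim); may be NA
#'   on excluded cells only.
#' @param cell_size Cell edge length in metres (default 250; cell area
#'   0.0625 km2).
#' @return A `landscape_grid` object.
#' @export
landscape_grid <- function(category, subcategory, region, cell_size = 250) {
  stopifnot(is.matrix(category), is.matrix(subcategory), is.matrix(region))
  if (!all(dim(category) == dim(subcategory)) ||
      !all(dim(category) == dim(region)))
    stop("category, subcategory and region grids must share dimensions",
         call. = FALSE)
  sch <- subcategory_scheme()
  bad <- !(category %in% sch$categories) & !is.na(category)
  if (any(bad))
    stop("unknown category codes: ",
         paste(unique(category[bad]), collapse = ", "), call. = FALSE)
  live <- !is.na(category) & category != "excluded"
  if (any(live & is.na(region)))
    stop("every non-excluded cell must carry a region", call. = FALSE)
  structure(list(category = category, subcategory = subcategory,
                 region = region, cell_size = cell_size,
                 cell_area_km2 = (cell_size / 1000)^2),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells at %g m (%g km2/cell)\n",
              nrow(x$category), ncol(x$category), x$cell_size,
              x$cell_area_km2))
  invisible(x)
}

#' Classify lakes into the five accounting size classes
#'
#' Half-open intervals (class k covers [lower, upper), the largest class is
#' closed above by infinity): 1 = [0.01, 0.1), 2 = [0.1, 1), 3 = [1, 10),
#' 4 = [10, 100), 5 = [100, Inf) km2. Lakes below the minimum (default
#' 0.01 km2 = 1 ha) are excluded from the accounting and return `NA` rather
#' than an error.
#'
#' @param area_km2 Numeric vector of lake areas (km2), all > 0.
#' @param min_area Minimum accountable lake area (km2).
#' @return Integer vector of classes 1-5, `NA` for excluded lakes.
#' @examples
#' classify_lake_size(c(0.5, 100, 0.005))  # 2, 5, NA
#' @export
classify_lake_size <- function(area_km2, min_area = 0.01) {
  stopifnot(is.numeric(area_km2))
  if (any(is.na(area_km2)) || any(area_km2 <= 0))
    stop("lake areas must be positive", call. = FALSE)
  breaks <- c(min_area, 0.1, 1, 10, 100, Inf)
  cls <- findInterval(area_km2, breaks, left.open = FALSE)
  cls[area_km2 < min_area] <- NA_integer_
  as.integer(cls)
}

# organic soil units of the national digital soil map legend
.default_organic_soils <- c("Gleyic Podzol", "Umbric Gleysol",
                            "Fibric Histosol", "Terric Histosol")

#' Classify cropland parcels into arable subcategories
#'
#' Parcels on organic soil map units split by crop type into
#' `organic_annual` / `organic_perennial`; every other (mineral) soil maps
#' to `mineral_all_crops` regardless of crop.
#'
#' @param soil_class Character vector of soil-map legend units.
#' @param crop_type `"annual"` or `"perennial"` (vector, recycled).
#' @param organic_soils Legend units treated as organic.
#' @param mineral_soils Legend units accepted as mineral; any other unit is
#'   handled per `unknown`.
#' @param unknown `"reject"` (default) errors on a legend unit in neither
#'   list; `"mineral"` maps it to `mineral_all_crops` with a warning.
#' @return Character vector of arable subcategory codes.
#' @export
classify_cropland <- function(soil_class, crop_type,
                              organic_soils = .default_organic_soils,
                              mineral_soils = NULL,
                              unknown = c("reject", "mineral")) {
  unknown <- match.arg(unknown)
  crop_type <- rep_len(crop_type, length(soil_class))
  if (!all(crop_type %in% c("annual", "perennial")))
    stop("crop_type must be 'annual' or 'perennial'", call. = FALSE)
  is_org <- soil_class %in% organic_soils
  is_min <- if (is.null(mineral_soils)) !is_org else soil_class %in% mineral_soils
  unk <- !is_org & !is_min
  if (any(unk)) {
    if (unknown == "reject")
      stop("unknown soil classes: ", paste(unique(soil_class[unk]),
           collapse = ", "), call. = FALSE)
    warning("unknown soil classes treated as mineral: ",
            paste(unique(soil_class[unk]), collapse = ", "), call. = FALSE)
  }
  out <- rep("mineral_all_crops", length(soil_class))
  out[is_org] <- ifelse(crop_type[is_org] == "annual",
                        "organic_annual", "organic_perennial")
  out
}

#' Read a mire classification rule table
#'
#' The rule table maps (forest productivity class, site main class, site
#' fertility class) to one of four undrained-mire classes: 1 productive
#' forested mires, 2 sedge fens, 3 other open and sparsely treed fens,
#' 4 ombrotrophic bogs. The table is data, not code; the packaged default
#' (`mire_rules_synthetic.csv`) is a full-coverage synthetic rule table.
#'
#' @param path CSV with columns `productivity`, `main_class`, `fertility`,
#'   `mire_class`. Default: the packaged synthetic rules.
#' @return Data frame of rules.
#' @export
read_mire_rules <- function(path = system.file("extdata",
                            "mire_rules_synthetic.csv", package = "ghgscape")) {
  rules <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("productivity", "main_class", "fertility", "mire_class")
  if (!all(need %in% names(rules)))
    stop("mire rule table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(rules[c("productivity", "main_class", "fertility")]))
    stop("duplicate rule rows", call. = FALSE)
  if (!all(rules$mire_class %in% 1:4))
    stop("mire_class must be 1-4", call. = FALSE)
  rules
}

#' Classify undrained mire sites into the four mire classes
#'
#' Deterministic lookup in the rule table. Attribute combinations absent
#' from the table yield `NA` and are counted, not silently dropped.
#'
#' @param attributes Data frame with columns `productivity`, `main_class`,
#'   `fertility`.
#' @param rules Rule table as from [read_mire_rules()].
#' @return Integer vector of mire classes (1-4, `NA` if unclassified) with
#'   attribute `n_unclassified`.
#' @export
classify_mire <- function(attributes, rules = read_mire_rules()) {
  need <- c("productivity", "main_class", "fertility")
  stopifnot(all(need %in% names(attributes)))
  key <- function(d) paste(d$productivity, d$main_class, d$fertility, sep = "|")
  idx <- match(key(attributes), key(rules))
  out <- as.integer(rules$mire_class[idx])
  n_un <- sum(is.na(out))
  if (n_un > 0)
    warning(n_un, " mire site(s) unclassified (no matching rule)",
            call. = FALSE)
  attr(out, "n_unclassified") <- n_un
  out
}

#' Zone (southern/northern) of an administrative region
#'
#' Default mapping follows the national region coding used in the packaged
#' tables: regions 1-16 are southern, 17-19 northern. Configurable for
#' synthetic landscapes.
#'
#' @param region_id Integer vector of region identifiers.
#' @param northern Region ids counted as northern.
#' @param valid All valid region ids.
#' @return Character vector `"southern"` / `"northern"`.
#' @export
zone_of_region <- function(region_id, northern = 17:19, valid = 1:19) {
  if (any(!region_id %in% valid))
    stop("unknown region id(s): ",
         paste(setdiff(region_id, valid), collapse = ", "), call. = FALSE)
  ifelse(region_id %in% northern, "northern", "southern")
}

# 1-D overlap weights between fine intervals (n cells of size `fine`) and
# coarse intervals (size `coarse`), as a (n_coarse x n_fine) matrix of
# overlap lengths.  Shared axis origin at 0.
.overlap_weights <- function(n_fine, fine, coarse) {
  n_coarse <- ceiling(n_fine * fine / coarse)
  f_lo <- (seq_len(n_fine) - 1) * fine
  f_hi <- f_lo + fine
  c_lo <- (seq_len(n_coarse) - 1) * coarse
  c_hi <- c_lo + coarse
  w <- outer(c_hi, f_hi, pmin) - outer(c_lo, f_lo, pmax)
  w[w < 0] <- 0
  w
}

#' Resample a fine binary mask to fractional cover on a coarser grid
#'
#' Exact area-weighted overlap (not nearest neighbour): the coarse cell size
#' need not be an integer multiple of the fine size (e.g. 16 m masks onto a
#' 250 m accounting grid). Each coarse cell's fraction is the covered fine
#' area inside it divided by the coarse cell area. Total covered area is
#' conserved exactly when the coarse extent covers the fine extent (the
#' coarse grid is sized by `ceiling`, so it always does).
#'
#' @param fine_mask Numeric/logical matrix (0/1 or fractions in `[0,1]`).
#' @param fine_size Fine cell edge (m).
#' @param coarse_size Coarse cell edge (m), > `fine_size`.
#' @return Matrix of fractional covers in `[0,1]`; attribute `area_ratio`
#'   gives coarse/fine covered-area ratio (1 when conserved).
#' @export
resample_fractions <- function(fine_mask, fine_size, coarse_size) {
  stopifnot(is.matrix(fine_mask), coarse_size > fine_size)
  m <- fine_mask * 1.0
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stop("fine_mask values must be in [0, 1]", call. = FALSE)
  wr <- .overlap_weights(nrow(m), fine_size, coarse_size)
  wc <- .overlap_weights(ncol(m), fine_size, coarse_size)
  covered <- wr %*% m %*% t(wc)          # covered area (m2) per coarse cell
  frac <- covered / coarse_size^2
  fine_area <- sum(m) * fine_size^2
  attr(frac, "area_ratio") <- if (fine_area > 0) sum(covered) / fine_area else 1
  frac
}

#' Area accounting table from a landscape grid and feature registries
#'
#' Tallies per-subcategory areas: land categories from full-cell assignment
#' on the grid (cells x cell area), waterbody areas from the feature
#' registries (lake areas above the 1 ha minimum; river area per
#' [river_area()], i.e. polygon areas plus the 3.5 m width rule for line
#' rivers) rather than from cell counts. Excluded cells contribute nothing.
#'
#' @param grid A [landscape_grid()].
#' @param lakes Optional lake registry (data frame with `area_km2`, and
#'   optionally `size_class`).
#' @param rivers Optional river registry (see [river_area()]).
#' @return An area table: `category`, `subcategory`, `area_km2`,
#'   `frac_of_category` and `frac_of_total` (percent).
#' @export
area_accounting <- function(grid, lakes = NULL, rivers = NULL) {
  stopifnot(inherits(grid, "landscape_grid"))
  live <- !is.na(grid$category) & grid$category != "excluded" &
    grid$category != "waterbody"
  tab <- table(category = grid$category[live],
               subcategory = grid$subcategory[live])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, , drop = FALSE]
  df$area_km2 <- df$Freq * grid$cell_area_km2
  scale <- attr(grid, "area_scale")
  if (!is.null(scale)) {
    idx <- match(df$subcategory, names(scale))
    df$area_km2 <- df$area_km2 * ifelse(is.na(idx), 1, scale[idx])
  }
  df <- df[c("category", "subcategory", "area_km2")]
  wb <- list()
  if (!is.null(lakes) && nrow(lakes) > 0) {
    cls <- if ("size_class" %in% names(lakes)) lakes$size_class
           else classify_lake_size(lakes$area_km2)
    keep <- !is.na(cls)
    if (any(keep)) {
      a <- tapply(lakes$area_km2[keep], paste0("lake_class_", cls[keep]), sum)
      wb <- c(wb, list(data.frame(category = "waterbody",
                                  subcategory = names(a),
                                  area_km2 = as.numeric(a))))
    }
  }
  if (!is.null(rivers) && nrow(rivers) > 0)
    wb <- c(wb, list(data.frame(category = "waterbody", subcategory = "river",
                                area_km2 = river_area(rivers))))
  df <- rbind(df, do.call(rbind, wb))
  area_table(df)
}

#' Build an area table from per-subcategory areas
#'
#' Adds category and total fraction columns; category totals are the sums of
#' their subcategories.
#'
#' @param df Data frame with `category`, `subcategory`, `area_km2`.
#' @return The data frame ordered by category with `frac_of_category` and
#'   `frac_of_total` percentage columns; class `"area_table"`.
#' @export
area_table <- function(df) {
  stopifnot(all(c("category", "subcategory", "area_km2") %in% names(df)))
  total <- sum(df$area_km2)
  cat_tot <- tapply(df$area_km2, df$category, sum)
  df$frac_of_category <- 100 * df$area_km2 / as.numeric(cat_tot[df$category])
  df$frac_of_total <- if (total > 0) 100 * df$area_km2 / total else 0
  df <- df[order(match(df$category, subcategory_scheme()$categories)), ]
  rownames(df) <- NULL
  structure(df, class = c("area_table", "data.frame"),
            total_area_km2 = total,
            category_totals = cat_tot)
}
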