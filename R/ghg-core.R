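#' Gas species definitions
#'
#' Builds the descriptor for one of the three inventory gases. GWP100 weights
#' follow the IPCC AR5 set (1 for CO2, 28 for CH4, 265 for N2O) and molar
#' masses default to the integer values conventional in inventory practice
#' (CO2 = 44, CH4 = 16, N2O = 44 g/mol; elements C = 12, N = 14). N2O carries
#' two nitrogen atoms per molecule, CO2 and CH4 one carbon atom each.
#'
#' @param name One of `"CO2"`, `"CH4"`, `"N2O"`.
#' @param gwp100 Optional override of the GWP100 multiplier.
#' @param molar_mass Optional override of the gas molar mass (g/mol).
#' @param element_mass Optional override of the element molar mass (g/mol);
#'   e.g. 12.011 for IUPAC carbon instead of the integer default.
#' @return A `gas_species` object (list with `name`, `gwp100`, `molar_mass`,
#'   `element`, `element_atoms`, `element_mass`).
#' @examples
#' gas_species("CH4")$gwp100  # 28
#' @export
gas_species <- function(name, gwp100 = NULL, molar_mass = NULL,
                        element_mass = NULL) {
  name <- match.arg(name, c("CO2", "CH4", "N2O"))
  defaults <- list(
    CO2 = list(gwp100 = 1,   molar_mass = 44, element = "C", atoms = 1L,
               element_mass = 12),
    CH4 = list(gwp100 = 28,  molar_mass = 16, element = "C", atoms = 1L,
               element_mass = 12),
    N2O = list(gwp100 = 265, molar_mass = 44, element = "N", atoms = 2L,
               element_mass = 14)
  )[[name]]
  out <- list(
    name          = name,
    gwp100        = if (is.null(gwp100)) defaults$gwp100 else gwp100,
    molar_mass    = if (is.null(molar_mass)) defaults$molar_mass else molar_mass,
    element       = defaults$element,
    element_atoms = defaults$atoms,
    element_mass  = if (is.null(element_mass)) defaults$element_mass else element_mass
  )
  structure(out, class = "gas_species")
}

#' Mass flux of a single gas
#'
#' Canonical internal unit is Gg gas per year; `unit` only tracks the scale
#' for I/O. Sign convention: emission to the atmosphere positive,
#' sequestration negative. `sd` is an uncertainty half-width in the same unit.
#'
#' @param species A `gas_species` or a species name.
#' @param value Mass flux (Gg gas / yr unless `unit` says otherwise).
#' @param sd Non-negative uncertainty in the same unit.
#' @param unit One of `"Gg/yr"`, `"Tg/yr"`, `"Mg/yr"`.
#' @return A `gas_flux` object.
#' @export
gas_flux <- function(species, value, sd = 0, unit = "Gg/yr") {
  if (is.character(species)) species <- gas_species(species)
  stopifnot(inherits(species, "gas_species"), is.numeric(value), length(value) == 1)
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  unit <- match.arg(unit, c("Gg/yr", "Tg/yr", "Mg/yr"))
  structure(list(species = species, value = value, sd = sd, unit = unit),
            class = "gas_flux")
}

# scale factor taking a mass in `from` units to `to` units
.mass_scale <- function(from, to) {
  gg <- c("Mg/yr" = 1e-3, "Gg/yr" = 1, "Tg/yr" = 1e3) # value in Gg per unit
  if (!from %in% names(gg) || !to %in% names(gg))
    stop("unknown mass unit", call. = FALSE)
  unname(gg[[from]] / gg[[to]])
}

#' Convert a flux between mass scales (Mg/Gg/Tg per year)
#'
#' @param flux A `gas_flux` or `co2eq_flux`.
#' @param unit Target unit.
#' @return The flux rescaled; round-trips exactly in double precision for
#'   the power-of-ten scales used.
#' @export
convert_unit <- function(flux, unit) {
  stopifnot(inherits(flux, c("gas_flux", "co2eq_flux")))
  units <- if (inherits(flux, "co2eq_flux"))
    c("GgCO2eq/yr", "TgCO2eq/yr", "MgCO2eq/yr") else c("Gg/yr", "Tg/yr", "Mg/yr")
  unit <- match.arg(unit, units)
  s <- .mass_scale(sub("CO2eq", "", flux$unit), sub("CO2eq", "", unit))
  flux$value <- flux$value * s
  flux$sd <- flux$sd * s
  flux$unit <- unit
  flux
}

#' Convert an elemental mass flux (C or N) to a gas flux
#'
#' Scales a carbon or nitrogen mass flux to the corresponding gas mass via
#' the molar-mass ratio: C to CO2 multiplies by 44/12, C to CH4 by 16/12,
#' N to N2O by 44/28 (two N atoms per molecule). The SD scales by the same
#' factor.
#'
#' @param element_mass Mass of the element, Gg / yr (may be negative for
#'   uptake).
#' @param species Target `gas_species` (or name).
#' @param element `"C"` or `"N"`; must match the species' element.
#' @param sd Uncertainty on `element_mass`, same unit.
#' @return A `gas_flux` in Gg gas / yr.
#' @examples
#' element_to_gas(12, "CO2", "C")$value  # 44
#' @export
element_to_gas <- function(element_mass, species, element, sd = 0) {
  if (is.character(species)) species <- gas_species(species)
  element <- match.arg(element, c("C", "N"))
  if (!identical(element, species$element))
    stop(sprintf("element '%s' does not match species %s (expects %s)",
                 element, species$name, species$element), call. = FALSE)
  ratio <- species$molar_mass / (species$element_atoms * species$element_mass)
  gas_flux(species, element_mass * ratio, sd * ratio)
}

#' Inverse of [element_to_gas()]: gas mass back to elemental mass
#'
#' @param flux A `gas_flux`.
#' @return Elemental mass (Gg element / yr) with attribute `sd`.
#' @export
gas_to_element <- function(flux) {
  stopifnot(inherits(flux, "gas_flux"))
  sp <- flux$species
  ratio <- (sp$element_atoms * sp$element_mass) / sp$molar_mass
  structure(flux$value * ratio, sd = flux$sd * ratio)
}

#' CO2-equivalent flux
#'
#' @param value Flux in the given CO2eq unit (emission positive).
#' @param sd Non-negative uncertainty half-width, same unit.
#' @param unit `"GgCO2eq/yr"` or `"TgCO2eq/yr"` or `"MgCO2eq/yr"`.
#' @return A `co2eq_flux` object.
#' @export
co2eq_flux <- function(value, sd = 0, unit = "GgCO2eq/yr") {
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  unit <- match.arg(unit, c("GgCO2eq/yr", "TgCO2eq/yr", "MgCO2eq/yr"))
  structure(list(value = value, sd = sd, unit = unit), class = "co2eq_flux")
}

#' Express a gas flux as CO2-equivalents
#'
#' Multiplies value and SD by the species GWP100; sign is preserved.
#'
#' @param flux A `gas_flux`.
#' @return A `co2eq_flux` on the matching mass scale.
#' @examples
#' to_co2eq(gas_flux("CH4", 1, unit = "Tg/yr"))$value  # 28
#' @export
to_co2eq <- function(flux) {
  stopifnot(inherits(flux, "gas_flux"))
  g <- flux$species$gwp100
  co2eq_flux(flux$value * g, flux$sd * g,
             unit = sub("/yr", "CO2eq/yr", flux$unit, fixed = TRUE))
}

#' Combine additive flux components and their uncertainties
#'
#' Values add; uncertainty half-widths combine in quadrature
#' (root-sum-of-squares), treating components as independent.
#'
#' @param values Numeric vector of component values.
#' @param sds Numeric vector of non-negative component SDs (recycled if
#'   length 1).
#' @return List with `value` (sum) and `sd` (quadrature).
#' @examples
#' combine_uncertainty(rep(0, 2), c(3, 4))$sd  # 5
#' @export
combine_uncertainty <- function(values, sds = 0) {
  stopifnot(is.numeric(values), is.numeric(sds))
  if (length(sds) == 1) sds <- rep(sds, length(values))
  if (length(sds) != length(values))
    stop("'values' and 'sds' lengths differ", call. = FALSE)
  if (any(is.na(sds)) || any(sds < 0))
    stop("all SDs must be non-negative", call. = FALSE)
  list(value = sum(values), sd = sqrt(sum(sds^2)))
}

#' Net emission: emission minus sequestration
#'
#' The sequestration flux may be passed either as a negative flux (the
#' internal convention) or as a positive magnitude; its absolute value is
#' subtracted. SDs combine in quadrature unless `sd_override` supplies an
#' externally derived net SD (used where a published net uncertainty comes
#' from Monte Carlo rather than quadrature).
#'
#' @param emission A `co2eq_flux` (emission, >= 0 by convention).
#' @param sequestration A `co2eq_flux`; magnitude is subtracted.
#' @param sd_override Optional net SD carried through unchanged.
#' @return A `co2eq_flux` for the net emission.
#' @export
net_flux <- function(emission, sequestration, sd_override = NULL) {
  stopifnot(inherits(emission, "co2eq_flux"), inherits(sequestration, "co2eq_flux"))
  if (!identical(emission$unit, sequestration$unit))
    stop("emission and sequestration must share a unit", call. = FALSE)
  value <- emission$value - abs(sequestration$value)
  sd <- if (is.null(sd_override))
    combine_uncertainty(c(0, 0), c(emission$sd, sequestration$sd))$sd
  else sd_override
  co2eq_flux(value, sd, unit = emission$unit)
}

#' @export
print.gas_flux <- function(x, ...) {
  cat(sprintf("<gas_flux> %s %.4g (sd %.4g) %s\n",
              x$species$name, x$value, x$sd, x$unit))
  invisible(x)
}

#' @export
print.co2eq_flux <- function(x, ...) {
  cat(sprintf("<co2eq_flux> %.4g (sd %.4g) %s\n", x$value, x$sd, x$unit))
  invisible(x)
}
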