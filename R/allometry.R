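# Damuth's law and the density <-> standing-biomass conversions used in the
# literature-comparison table.

#' Damuth's-law population density
#'
#' The empirical allometry `log10(D) = slope * log10(W) + intercept` linking
#' the population density D (individuals km-2) of a mammalian primary
#' consumer to its adult body mass W in grams. With the canonical
#' coefficients (-0.75, 4.23) the 3.9-5.2 t mammoth mass range maps to
#' about 0.16-0.19 individuals km-2.
#'
#' @param mass_g Adult body mass in grams (vectorised, positive).
#' @param slope,intercept Allometry coefficients (log10 scale).
#' @return Population density, individuals km-2.
#' @examples
#' damuth_density(4.55e6) # ~0.17 km-2 at the 4,550 kg reference mass
#' @export
damuth_density <- function(mass_g, slope = -0.75, intercept = 4.23) {
  if (any(mass_g <= 0)) stop("body mass must be positive", call. = FALSE)
  10^(slope * log10(mass_g) + intercept)
}

#' Convert population density to standing biomass
#'
#' @param density_km2 Individuals km-2 (non-negative).
#' @param mean_mass_tonnes Mean individual mass, tonnes (positive).
#' @return Standing biomass, tonnes km-2.
#' @export
density_to_biomass <- function(density_km2, mean_mass_tonnes) {
  if (any(density_km2 < 0)) stop("density must be >= 0", call. = FALSE)
  if (any(mean_mass_tonnes <= 0)) stop("mean mass must be positive", call. = FALSE)
  density_km2 * mean_mass_tonnes
}

#' Convert standing biomass to population density
#'
#' Used to express literature biomass estimates (e.g. 2.5 and 4.5 t km-2
#' Pleistocene standing stocks) as individuals km-2 at a common mean mass.
#'
#' @param biomass_t_km2 Standing biomass, tonnes km-2 (non-negative).
#' @param mean_mass_tonnes Mean individual mass, tonnes (positive).
#' @return Population density, individuals km-2.
#' @export
biomass_to_density <- function(biomass_t_km2, mean_mass_tonnes) {
  if (any(biomass_t_km2 < 0)) stop("biomass must be >= 0", call. = FALSE)
  if (any(mean_mass_tonnes <= 0)) stop("mean mass must be positive", call. = FALSE)
  biomass_t_km2 / mean_mass_tonnes
}

#' Population supported by a density over an area
#'
#' @param density_km2 Individuals km-2 (non-negative).
#' @param area_km2 Area, km2 (non-negative).
#' @return Expected count (real; round at presentation).
#' @export
damuth_population <- function(density_km2, area_km2) {
  if (any(density_km2 < 0) || any(area_km2 < 0)) {
    stop("density and area must be >= 0", call. = FALSE)
  }
  density_km2 * area_km2
}
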