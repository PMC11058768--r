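#' Downgrading-cascade configuration
#'
#' Every multiplicative factor that turns aboveground biomass carbon into
#' digestible, annually generated forage:
#'
#' * `carbon_to_biomass` (2.03): carbon density back to total dry biomass.
#' * `digestibility`: fraction of each preferred PFT a monogastric
#'   megaherbivore can digest (forb 0.8, graminoid 0.5, deciduous shrub 0.6).
#' * `shrub_preference_adj` (0.5): additional deciduous-shrub downgrade for
#'   proboscidean dietary preference, avoiding bias toward the abundant
#'   shrub biomass.
#' * `forage_rate` (0.10): fraction of digestible biomass sustainably
#'   consumable; `forage_rate_low`/`_high` (0.05/0.25) bound the
#'   sensitivity analysis.
#' * `npp_factor` (0.4): standing biomass to annually generated biomass
#'   (the herbivore only eats what grew this year).
#' * `pi_multiplier` (1.96): standard errors to a 95% prediction interval
#'   for the biomass confidence limits.
#'
#' @param carbon_to_biomass,shrub_preference_adj,forage_rate,forage_rate_low,forage_rate_high,npp_factor,pi_multiplier
#'   Scalar factors as described above.
#' @param digestibility Named numeric with exactly the three preferred PFT
#'   keys `forb`, `graminoid`, `deciduous_shrub`, values in (0, 1].
#' @param agbc_units Declared unit of the input biomass carbon raster.
#' @return An object of class `downgrade_config`.
#' @export
downgrade_config <- function(carbon_to_biomass = 2.03,
                             digestibility = c(forb = 0.8, graminoid = 0.5,
                                               deciduous_shrub = 0.6),
                             shrub_preference_adj = 0.5,
                             forage_rate = 0.10, forage_rate_low = 0.05,
                             forage_rate_high = 0.25, npp_factor = 0.4,
                             agbc_units = "Mg C ha-1", pi_multiplier = 1.96) {
  if (carbon_to_biomass <= 0) stop("`carbon_to_biomass` must be > 0", call. = FALSE)
  digestibility <- unlist(digestibility)
  if (!setequal(names(digestibility), PREFERRED_PFTS)) {
    stop(sprintf("`digestibility` must have exactly the keys: %s",
                 paste(PREFERRED_PFTS, collapse = ", ")), call. = FALSE)
  }
  digestibility <- digestibility[PREFERRED_PFTS]
  in_01 <- function(x) all(x > 0) && all(x <= 1)
  if (!in_01(digestibility)) stop("digestibility values must be in (0, 1]", call. = FALSE)
  if (!in_01(shrub_preference_adj)) stop("`shrub_preference_adj` must be in (0, 1]", call. = FALSE)
  if (!in_01(c(forage_rate, forage_rate_low, forage_rate_high))) {
    stop("forage rates must be in (0, 1]", call. = FALSE)
  }
  if (!in_01(npp_factor)) stop("`npp_factor` must be in (0, 1]", call. = FALSE)
  if (pi_multiplier <= 0) stop("`pi_multiplier` must be > 0", call. = FALSE)
  structure(
    list(carbon_to_biomass = carbon_to_biomass, digestibility = digestibility,
         shrub_preference_adj = shrub_preference_adj, forage_rate = forage_rate,
         forage_rate_low = forage_rate_low, forage_rate_high = forage_rate_high,
         npp_factor = npp_factor, agbc_units = agbc_units,
         pi_multiplier = pi_multiplier),
    class = "downgrade_config"
  )
}

#' @export
print.downgrade_config <- function(x, ...) {
  cat("<downgrade_config>\n")
  cat(sprintf("  carbon->biomass %g | digestibility: %s | shrub adj %g\n",
              x$carbon_to_biomass,
              paste(sprintf("%s %g", names(x$digestibility), x$digestibility),
                    collapse = ", "),
              x$shrub_preference_adj))
  cat(sprintf("  forage rate %g [%g, %g] | NPP factor %g | PI multiplier %g\n",
              x$forage_rate, x$forage_rate_low, x$forage_rate_high,
              x$npp_factor, x$pi_multiplier))
  invisible(x)
}

#' Convert biomass carbon to total biomass
#'
#' Element-wise multiplication by the carbon-to-biomass factor (default
#' 2.03); the unit label drops its carbon basis.
#'
#' @param agbc A non-negative [grid_layer()] of biomass carbon.
#' @param factor Positive conversion factor.
#' @return A [grid_layer()] of total biomass in the matching unit.
#' @export
carbon_to_total <- function(agbc, factor = 2.03) {
  stopifnot(inherits(agbc, "grid_layer"))
  if (length(factor) != 1 || factor <= 0) {
    stop("`factor` must be a positive scalar", call. = FALSE)
  }
  units <- gsub("\\s+", " ", trimws(sub("\\s*C\\s*", " ", agbc$units)))
  scale_layer(agbc, factor, units)
}

#' Biomass confidence limits from per-pixel standard errors
#'
#' `lcl = max(0, mean - k * se)` and `ucl = mean + k * se`, with `k` the
#' prediction-interval multiplier (1.96 for 95%). The lower limit is clipped
#' at zero: negative biomass is physically meaningless.
#'
#' @param mean,se Co-registered [grid_layer()]s; `se >= 0`.
#' @param pi_multiplier Positive multiplier applied to the SE.
#' @return List with `grid_layer` elements `lcl` and `ucl`.
#' @export
confidence_bounds <- function(mean, se, pi_multiplier = 1.96) {
  stopifnot(inherits(mean, "grid_layer"), inherits(se, "grid_layer"))
  stop_if_misaligned(mean, se, "mean/se")
  if (any(se$values < 0, na.rm = TRUE)) stop("`se` must be >= 0", call. = FALSE)
  list(
    lcl = grid_layer(pmax(mean$values - pi_multiplier * se$values, 0),
                     mean$units, mean$pixel_size_m),
    ucl = grid_layer(mean$values + pi_multiplier * se$values,
                     mean$units, mean$pixel_size_m)
  )
}

#' Combined downgrading factor at one pixel
#'
#' Sums, over the preferred PFTs, cover x digestibility (x the
#' shrub-preference adjustment for deciduous shrubs). Non-preferred PFTs
#' (evergreen shrub, other) and unknown keys contribute zero; unknown keys
#' raise a warning. The result lies in [0, max digestibility] (0.8 at
#' defaults); the ceiling would require full forb cover.
#'
#' @param cover_at_pixel Named numeric of cover fractions at one pixel.
#' @param config A [downgrade_config()].
#' @return Dimensionless factor in [0, 1].
#' @examples
#' pixel_downgrade_factor(c(forb = 0.2, graminoid = 0.3, deciduous_shrub = 0.5),
#'                        downgrade_config()) # 0.46
#' @export
pixel_downgrade_factor <- function(cover_at_pixel, config = downgrade_config()) {
  stopifnot(inherits(config, "downgrade_config"))
  cov <- unlist(cover_at_pixel)
  if (any(cov < -COVER_TOL | cov > 1 + COVER_TOL)) {
    stop("cover fractions must be in [0, 1]", call. = FALSE)
  }
  if (sum(cov) > 1 + COVER_TOL) {
    stop("cover fractions sum to more than 1", call. = FALSE)
  }
  unknown <- setdiff(names(cov), ALL_PFTS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown PFT(s): %s", paste(unknown, collapse = ", ")),
            call. = FALSE)
  }
  total <- 0
  for (pft in PREFERRED_PFTS) {
    if (!pft %in% names(cov)) next
    adj <- if (pft == "deciduous_shrub") config$shrub_preference_adj else 1
    total <- total + cov[[pft]] * config$digestibility[[pft]] * adj
  }
  total
}

# vectorized form of pixel_downgrade_factor over a stack; NA where any
# preferred cover layer is nodata
downgrade_factor_matrix <- function(stack, config) {
  missing <- setdiff(PREFERRED_PFTS, names(stack$cover))
  if (length(missing)) {
    stop(sprintf("stack is missing preferred cover layer(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  total <- 0
  for (pft in PREFERRED_PFTS) {
    adj <- if (pft == "deciduous_shrub") config$shrub_preference_adj else 1
    total <- total + stack$cover[[pft]]$values * config$digestibility[[pft]] * adj
  }
  total
}

#' Digestible annually generated biomass per pixel
#'
#' The full downgrading cascade. Per valid pixel, on the canonical
#' Mg km-2 scale:
#'
#' `agdb = agbc(variant) x carbon_to_biomass x downgrade_factor x
#'  forage_rate x npp_factor`
#'
#' where `downgrade_factor` is the cover-weighted digestibility of
#' [pixel_downgrade_factor()]. All steps are scalar multiplications, so the
#' ordering is immaterial; stages are tagged `total_biomass` (after the
#' carbon conversion), `digestible`, `foraged` and `annual` for reporting.
#' Water pixels yield 0 (a real zero-forage habitat); a nodata pixel in any
#' input layer propagates to nodata output.
#'
#' @param stack A [landscape_stack()].
#' @param config A [downgrade_config()].
#' @param biomass_variant `"mean"`, `"lcl"` or `"ucl"`: which biomass layer
#'   enters the cascade (confidence limits via [confidence_bounds()]).
#' @param forage_rate_override Optional forage rate replacing
#'   `config$forage_rate` (used by the sensitivity analysis).
#' @param keep_stages Attach the intermediate stage layers as attribute
#'   `"stages"` (used by run reports).
#' @return An `agdb_layer`: list with `layer` (a [grid_layer()],
#'   Mg km-2 yr-1), `stage = "annual"`, `biomass_variant` and `forage_rate`.
#' @examples
#' # a 1 Mg C ha-1 pixel under full forb cover:
#' # 100 Mg C km-2 x 2.03 x 0.8 x 0.10 x 0.4 = 6.496 Mg km-2 yr-1
#' @export
compute_agdb_annual <- function(stack, config = downgrade_config(),
                                biomass_variant = c("mean", "lcl", "ucl"),
                                forage_rate_override = NULL,
                                keep_stages = FALSE) {
  stopifnot(inherits(stack, "landscape_stack"),
            inherits(config, "downgrade_config"))
  biomass_variant <- match.arg(biomass_variant)
  rate <- if (is.null(forage_rate_override)) config$forage_rate else forage_rate_override
  if (rate <= 0 || rate > 1) stop("forage rate must be in (0, 1]", call. = FALSE)

  agbc <- switch(biomass_variant,
    mean = stack$agbc_mean,
    lcl = confidence_bounds(stack$agbc_mean, stack$agbc_se,
                            config$pi_multiplier)$lcl,
    ucl = confidence_bounds(stack$agbc_mean, stack$agbc_se,
                            config$pi_multiplier)$ucl
  )
  agbc <- grid_layer(agbc$values, config$agbc_units, agbc$pixel_size_m)
  agbc_km2 <- to_mg_per_km2(agbc)

  factor_mat <- downgrade_factor_matrix(stack, config)
  px <- agbc$pixel_size_m

  total_biomass <- agbc_km2$values * config$carbon_to_biomass
  digestible <- total_biomass * factor_mat
  foraged <- digestible * rate
  annual <- foraged * config$npp_factor
  annual[stack$water_mask & !is.na(annual)] <- 0

  out <- structure(
    list(layer = grid_layer(annual, "Mg km-2 yr-1", px), stage = "annual",
         biomass_variant = biomass_variant, forage_rate = rate),
    class = "agdb_layer"
  )
  if (keep_stages) {
    zero_water <- function(v) { v[stack$water_mask & !is.na(v)] <- 0; v }
    attr(out, "stages") <- list(
      total_biomass = grid_layer(zero_water(total_biomass), "Mg km-2", px),
      digestible = grid_layer(zero_water(digestible), "Mg km-2", px),
      foraged = grid_layer(zero_water(foraged), "Mg km-2", px),
      annual = out$layer
    )
    attr(out, "downgrade_factor") <- factor_mat
  }
  out
}

#' @export
print.agdb_layer <- function(x, ...) {
  cat(sprintf("<agdb_layer> stage=%s, biomass=%s, forage rate=%g\n",
              x$stage, x$biomass_variant, x$forage_rate))
  print(x$layer)
  invisible(x)
}
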