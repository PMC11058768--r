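#' Herbivore density from annual digestible forage
#'
#' Divides digestible annually generated biomass (Mg km-2 yr-1) by one
#' animal's annual need (tonnes; 1 Mg = 1 tonne) to give the density the
#' pixel's forage production can sustain.
#'
#' @param agdb An `agdb_layer` from [compute_agdb_annual()] (or a
#'   [grid_layer()] already in Mg km-2 yr-1).
#' @param annual_need_tonnes Positive annual need of one individual, tonnes
#'   dry forage (unrounded; see [annual_needs()]).
#' @param body_mass_kg Optional body mass recorded on the result for
#'   labelling.
#' @return A `density_layer`: list with `layer` ([grid_layer()],
#'   individuals km-2) and `body_mass_kg`.
#' @export
density_from_agdb <- function(agdb, annual_need_tonnes, body_mass_kg = NA_real_) {
  layer <- if (inherits(agdb, "agdb_layer")) agdb$layer else agdb
  stopifnot(inherits(layer, "grid_layer"))
  if (length(annual_need_tonnes) != 1 || annual_need_tonnes <= 0) {
    stop("`annual_need_tonnes` must be a positive scalar", call. = FALSE)
  }
  structure(
    list(layer = scale_layer(layer, 1 / annual_need_tonnes, "individuals km-2"),
         body_mass_kg = body_mass_kg),
    class = "density_layer"
  )
}

#' @export
print.density_layer <- function(x, ...) {
  cat(sprintf("<density_layer> body mass %s kg\n",
              format(x$body_mass_kg)))
  print(x$layer)
  invisible(x)
}

#' Zonal summary of forage and supportable density
#'
#' Aggregates per-pixel densities and forage by ecological-landscape zone:
#' area, mean annual digestible biomass, mean density at each body-mass
#' bound, and the supported population (sum of density x pixel area over
#' the zone's valid pixels). A final `total` row pools all valid pixels
#' (the pooled computation, not a mean of zone means). Water pixels count
#' toward area and contribute zero individuals; nodata pixels are excluded
#' everywhere. Counts stay unrounded; rounding is presentation-only.
#'
#' @param density_low,density_high `density_layer`s at the low and high
#'   body-mass bound (low mass = higher density).
#' @param agdb The `agdb_layer` the densities derive from.
#' @param zones [grid_layer()] of integer zone labels.
#' @param zone_names Optional named character vector label -> name.
#' @param pixel_area_km2 Pixel area; defaults to the grid's own
#'   ((pixel_size_m/1000)^2).
#' @return A `zonal_summary` data frame, zones sorted by label, plus the
#'   `total` row.
#' @export
zonal_summary <- function(density_low, density_high, agdb, zones,
                          zone_names = NULL, pixel_area_km2 = NULL) {
  dl <- if (inherits(density_low, "density_layer")) density_low$layer else density_low
  dh <- if (inherits(density_high, "density_layer")) density_high$layer else density_high
  ag <- if (inherits(agdb, "agdb_layer")) agdb$layer else agdb
  stop_if_misaligned(dl, dh, "density layers")
  stop_if_misaligned(dl, ag, "density/agdb")
  stop_if_misaligned(dl, zones, "density/zones")
  if (is.null(pixel_area_km2)) pixel_area_km2 <- pixel_area_km2(dl)

  valid <- !is.na(dl$values) & !is.na(dh$values) & !is.na(zones$values)
  labs <- sort(unique(as.vector(zones$values[valid])))
  if (!is.null(zone_names)) {
    empty <- setdiff(names(zone_names), as.character(labs))
    if (length(empty)) {
      message(sprintf("zone label(s) with no pixels omitted: %s",
                      paste(empty, collapse = ", ")))
    }
  }
  name_of <- function(lab) {
    if (!is.null(zone_names) && as.character(lab) %in% names(zone_names)) {
      zone_names[[as.character(lab)]]
    } else sprintf("zone_%g", lab)
  }

  one <- function(sel, lab, nm) {
    data.frame(
      zone = lab, name = nm,
      area_km2 = sum(sel) * pixel_area_km2,
      n_pixels = sum(sel),
      mean_agdb = mean(ag$values[sel]),
      mean_density_low_mass = mean(dl$values[sel]),
      mean_density_high_mass = mean(dh$values[sel]),
      supported_low_mass = sum(dl$values[sel]) * pixel_area_km2,
      supported_high_mass = sum(dh$values[sel]) * pixel_area_km2,
      stringsAsFactors = FALSE
    )
  }
  zone_mat <- zones$values
  rows <- lapply(labs, function(lab) {
    one(valid & zone_mat == lab, as.character(lab), name_of(lab))
  })
  rows <- c(rows, list(one(valid, "total", "all zones")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("zonal_summary", "data.frame"),
            pixel_area_km2 = pixel_area_km2)
}

#' @export
print.zonal_summary <- function(x, digits = 4, ...) {
  cat("Zonal carrying-capacity summary\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Total supportable population
#'
#' Extracts the all-zones totals from a [zonal_summary()]: supported count
#' at each body-mass bound and the pooled mean densities. Use
#' [format_approx_count()] to render counts to the nearest thousand.
#'
#' @param summary A [zonal_summary()].
#' @return List: `count_low_mass`, `count_high_mass`,
#'   `mean_density_low_mass`, `mean_density_high_mass`, `area_km2`.
#' @export
total_population <- function(summary) {
  stopifnot(inherits(summary, "zonal_summary"))
  tot <- summary[summary$zone == "total", ]
  if (nrow(tot) != 1) stop("summary has no total row", call. = FALSE)
  list(count_low_mass = tot$supported_low_mass,
       count_high_mass = tot$supported_high_mass,
       mean_density_low_mass = tot$mean_density_low_mass,
       mean_density_high_mass = tot$mean_density_high_mass,
       area_km2 = tot$area_km2)
}

#' Render a count rounded to the nearest thousand
#'
#' @param count Real count.
#' @param nearest Rounding grain (default 1000).
#' @return String such as `"~48,000"`.
#' @export
format_approx_count <- function(count, nearest = 1000) {
  paste0("~", formatC(round_half_up(count / nearest) * nearest,
                      format = "d", big.mark = ","))
}
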