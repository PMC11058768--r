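# Plant functional types tracked by the pipeline. Only the first three are
# preferred forage; evergreen shrubs and "other" vegetation contribute zero
# digestible biomass by construction.
PREFERRED_PFTS <- c("forb", "graminoid", "deciduous_shrub")
ALL_PFTS <- c(PREFERRED_PFTS, "evergreen_shrub", "other")

COVER_TOL <- 1e-6

#' Co-registered landscape raster stack
#'
#' Bundles the inputs of the downgrading cascade: aboveground biomass carbon
#' (mean and per-pixel standard error), fractional top cover per plant
#' functional type (PFT), integer ecological-landscape zone labels, and a
#' water mask. All layers must share shape and pixel size. Construction
#' validates the stack invariants: non-negative biomass, cover fractions in
#' [0, 1] summing to at most 1 per pixel, and zero vegetated cover on water.
#'
#' @param agbc_mean,agbc_se [grid_layer()]s of aboveground biomass carbon
#'   density (typically Mg C ha-1) and its standard error.
#' @param cover Named list of [grid_layer()]s (`units = "fraction"`), one per
#'   PFT; names drawn from `c("forb", "graminoid", "deciduous_shrub",
#'   "evergreen_shrub", "other")`.
#' @param zones [grid_layer()] of integer zone labels.
#' @param zone_names Named character vector mapping label -> landscape name.
#' @param water_mask Logical matrix, `TRUE` on water pixels.
#'
#' @return An object of class `landscape_stack`.
#' @seealso [generate_stack()] to simulate one, [write_stack()] /
#'   [read_stack()] for on-disk form.
#' @export
landscape_stack <- function(agbc_mean, agbc_se, cover, zones, zone_names,
                            water_mask) {
  stopifnot(inherits(agbc_mean, "grid_layer"), inherits(agbc_se, "grid_layer"),
            inherits(zones, "grid_layer"), is.list(cover))
  if (is.null(names(cover)) || any(!nzchar(names(cover)))) {
    stop("`cover` must be a named list of grid_layers", call. = FALSE)
  }
  unknown <- setdiff(names(cover), ALL_PFTS)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown PFT cover layer(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    cover <- cover[setdiff(names(cover), unknown)]
  }
  for (nm in names(cover)) {
    stop_if_misaligned(agbc_mean, cover[[nm]], sprintf("cover[%s]", nm))
  }
  stop_if_misaligned(agbc_mean, agbc_se, "agbc mean/se")
  stop_if_misaligned(agbc_mean, zones, "agbc/zones")
  if (!is.logical(water_mask) || !identical(dim(water_mask), dim(agbc_mean$values))) {
    stop("`water_mask` must be a logical matrix matching the stack shape",
         call. = FALSE)
  }
  labs <- unique(as.vector(zones$values[!is.na(zones$values)]))
  if (any(labs != round(labs))) stop("zone labels must be integers", call. = FALSE)
  if (is.null(names(zone_names))) {
    stop("`zone_names` must be named by zone label", call. = FALSE)
  }

  stk <- structure(
    list(agbc_mean = agbc_mean, agbc_se = agbc_se, cover = cover,
         zones = zones, zone_names = zone_names, water_mask = water_mask),
    class = "landscape_stack"
  )
  validate_stack(stk)
  stk
}

#' Validate landscape-stack invariants
#'
#' Checks non-negative biomass mean/SE, per-PFT cover in [0, 1], per-pixel
#' cover closure (sum at most 1 within tolerance), and zero vegetated cover
#' on water pixels. Called by the constructor; exported so that stacks read
#' from disk or built by hand can be re-checked.
#'
#' @param stack A [landscape_stack()].
#' @return The stack, invisibly; errors on violation.
#' @export
validate_stack <- function(stack) {
  stopifnot(inherits(stack, "landscape_stack"))
  m <- stack$agbc_mean$values
  s <- stack$agbc_se$values
  if (any(m < 0, na.rm = TRUE)) stop("agbc_mean has negative pixels", call. = FALSE)
  if (any(s < 0, na.rm = TRUE)) stop("agbc_se has negative pixels", call. = FALSE)
  total <- 0
  for (nm in names(stack$cover)) {
    v <- stack$cover[[nm]]$values
    if (any(v < -COVER_TOL | v > 1 + COVER_TOL, na.rm = TRUE)) {
      stop(sprintf("cover[%s] outside [0, 1]", nm), call. = FALSE)
    }
    total <- total + ifelse(is.na(v), 0, v)
  }
  if (any(total > 1 + COVER_TOL)) {
    stop("per-pixel cover fractions sum to more than 1", call. = FALSE)
  }
  if (any(stack$water_mask)) {
    for (nm in names(stack$cover)) {
      if (any(stack$cover[[nm]]$values[stack$water_mask] > COVER_TOL,
              na.rm = TRUE)) {
        stop(sprintf("water pixels carry non-zero %s cover", nm), call. = FALSE)
      }
    }
  }
  invisible(stack)
}

#' @export
dim.landscape_stack <- function(x) dim(x$agbc_mean$values)

#' @export
print.landscape_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<landscape_stack> %d x %d @ %g m\n", d[1], d[2],
              x$agbc_mean$pixel_size_m))
  cat(sprintf("  agbc_mean [%s]: mean %.4g | water: %d px | nodata: %d px\n",
              x$agbc_mean$units, mean(x$agbc_mean$values, na.rm = TRUE),
              sum(x$water_mask), sum(is.na(x$agbc_mean$values))))
  cat(sprintf("  cover: %s\n", paste(names(x$cover), collapse = ", ")))
  zl <- sort(unique(as.vector(x$zones$values[!is.na(x$zones$values)])))
  cat(sprintf("  zones: %s\n", paste(sprintf("%d=%s", zl,
              x$zone_names[as.character(zl)]), collapse = ", ")))
  invisible(x)
}
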