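#' Single-band raster layer
#'
#' A `grid_layer` is the common currency of every spatial stage of the
#' pipeline: a 2-D matrix of one physical quantity with a unit label and a
#' pixel size. Row 1 is the northern edge of the grid. Missing (nodata)
#' pixels are stored as `NA`; every non-`NA` value must be finite.
#'
#' @param values Numeric matrix. `NA` marks nodata pixels.
#' @param units Non-empty unit label, e.g. `"Mg C ha-1"`, `"fraction"`,
#'   `"Mg km-2 yr-1"`.
#' @param pixel_size_m Positive pixel edge length in metres (default 300,
#'   the grain of the biomass carbon maps the pipeline was designed for).
#'
#' @return An object of class `grid_layer`.
#' @examples
#' gl <- grid_layer(matrix(1:6 / 2, 2, 3), "Mg C ha-1")
#' pixel_area_km2(gl) # 0.09 for 300 m pixels
#' @export
grid_layer <- function(values, units, pixel_size_m = 300) {
  if (is.vector(values) && !is.matrix(values)) values <- matrix(values, 1)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (!is.character(units) || length(units) != 1L || !nzchar(units)) {
    stop("`units` must be a single non-empty string", call. = FALSE)
  }
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L ||
      !is.finite(pixel_size_m) || pixel_size_m <= 0) {
    stop("`pixel_size_m` must be a positive number", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (any(is.infinite(values))) {
    stop("all valid (non-NA) pixels must be finite", call. = FALSE)
  }
  structure(
    list(values = values, units = units, pixel_size_m = as.numeric(pixel_size_m)),
    class = "grid_layer"
  )
}

#' @export
dim.grid_layer <- function(x) dim(x$values)

#' Nodata mask of a layer
#'
#' @param layer A [grid_layer()].
#' @return Logical matrix, `TRUE` where the pixel carries no data.
#' @export
nodata_mask <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  is.na(layer$values)
}

#' Pixel area in square kilometres
#'
#' @param layer A [grid_layer()].
#' @return `(pixel_size_m / 1000)^2`; 0.09 km2 for the default 300 m grain.
#' @export
pixel_area_km2 <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  (layer$pixel_size_m / 1000)^2
}

#' @export
print.grid_layer <- function(x, ...) {
  d <- dim(x$values)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_layer> %d x %d @ %g m [%s]\n", d[1], d[2],
              x$pixel_size_m, x$units))
  if (length(v)) {
    cat(sprintf("  valid: %d px, min %.4g, mean %.4g, max %.4g; nodata: %d px\n",
                length(v), min(v), mean(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  no valid pixels\n")
  }
  invisible(x)
}

# element-wise scaling that preserves layer metadata
scale_layer <- function(layer, factor, units = layer$units) {
  grid_layer(layer$values * factor, units, layer$pixel_size_m)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$pixel_size_m, b$pixel_size_m))
}

stop_if_misaligned <- function(a, b, what = "layers") {
  if (!same_geometry(a, b)) {
    stop(sprintf("%s are not co-registered (shape or pixel size differ)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a biomass(-carbon) layer to the canonical Mg per km2 scale
#'
#' The pipeline's internal areal biomass unit is Mg km-2
#' (1 g m-2 = 1 Mg km-2; 1 Mg ha-1 = 100 Mg km-2). Input rasters may be
#' declared in any of the supported per-area units; conversion happens once,
#' on entry to the cascade.
#'
#' @param layer A [grid_layer()] whose `units` is one of
#'   `"Mg C ha-1"`, `"Mg ha-1"`, `"Mg C km-2"`, `"Mg km-2"`,
#'   `"g C m-2"`, `"g m-2"`.
#' @return A `grid_layer` on the Mg km-2 scale (carbon basis preserved in
#'   the label).
#' @export
to_mg_per_km2 <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  u <- layer$units
  carbon <- grepl("\\bC\\b", u)
  base <- sub("\\s*C\\s*", " ", u)
  base <- gsub("\\s+", " ", trimws(base))
  factor <- switch(base,
    "Mg ha-1" = 100,
    "Mg km-2" = 1,
    "g m-2"   = 1,
    stop(sprintf("unsupported biomass unit '%s'", u), call. = FALSE)
  )
  out_units <- if (carbon) "Mg C km-2" else "Mg km-2"
  scale_layer(layer, factor, out_units)
}
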