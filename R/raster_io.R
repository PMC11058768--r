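# Raster I/O: Esri ASCII grid (.asc), the text interchange raster format.
# Continuous layers are written at full double precision (%.17g) so that a
# write -> read round trip is bit-exact; integer layers are written as
# integers. A JSON sidecar records units, pixel size and the row-order
# convention (row 1 = north); zone names travel in a label,name CSV.

ASC_NODATA <- -9999

#' Write one layer as an Esri ASCII grid
#'
#' @param layer A [grid_layer()].
#' @param path Output path (conventionally `.asc`).
#' @param integer Write values as integers (zone labels, masks).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, integer = FALSE) {
  stopifnot(inherits(layer, "grid_layer"))
  v <- layer$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.17g", layer$pixel_size_m),
    sprintf("NODATA_value %d", ASC_NODATA)
  ), con)
  fmt <- if (integer) function(x) sprintf("%d", as.integer(x)) else
    function(x) sprintf("%.17g", x)
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    out <- ifelse(is.na(row), as.character(ASC_NODATA), fmt(row))
    writeLines(paste(out, collapse = " "), con)
  }
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @param units Unit label to attach (ASCII grids carry none themselves).
#' @return A [grid_layer()] with nodata pixels as `NA`.
#' @export
read_ascii_grid <- function(path, units = "unknown") {
  if (!file.exists(path)) stop(sprintf("no such raster: %s", path), call. = FALSE)
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(tolower(hdr), "\\s+")
  hv <- stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                        vapply(kv, `[`, character(1), 1))
  nc <- as.integer(hv[["ncols"]]); nr <- as.integer(hv[["nrows"]])
  nodata <- if ("nodata_value" %in% names(hv)) hv[["nodata_value"]] else ASC_NODATA
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("raster %s: expected %d values, found %d", path, nr * nc,
                 length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_layer(m, units, pixel_size_m = hv[["cellsize"]])
}

#' Write a landscape stack to a directory
#'
#' Emits one single-band ASCII grid per layer (`agbc_mean.asc`,
#' `agbc_se.asc`, `cover_<pft>.asc`, `zones.asc`, `water_mask.asc`), a
#' `zone_names.csv` table (columns `label,name`) and a `metadata.json`
#' sidecar with units, pixel size and the north-at-row-1 convention. The
#' round trip through [read_stack()] reproduces all values bit-exactly.
#'
#' @param stack A [landscape_stack()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "landscape_stack"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop(sprintf("cannot write to '%s'", dir), call. = FALSE)
  }
  px <- stack$agbc_mean$pixel_size_m
  write_ascii_grid(stack$agbc_mean, file.path(dir, "agbc_mean.asc"))
  write_ascii_grid(stack$agbc_se, file.path(dir, "agbc_se.asc"))
  for (nm in names(stack$cover)) {
    write_ascii_grid(stack$cover[[nm]], file.path(dir, sprintf("cover_%s.asc", nm)))
  }
  write_ascii_grid(stack$zones, file.path(dir, "zones.asc"), integer = TRUE)
  write_ascii_grid(grid_layer(stack$water_mask + 0, "boolean", px),
                   file.path(dir, "water_mask.asc"), integer = TRUE)
  utils::write.csv(
    data.frame(label = names(stack$zone_names), name = unname(stack$zone_names),
               stringsAsFactors = FALSE),
    file.path(dir, "zone_names.csv"), row.names = FALSE, quote = FALSE)
  meta <- list(
    format = "esri_ascii_grid",
    row_order = "row 1 = northern edge",
    pixel_size_m = px,
    units = c(list(agbc_mean = stack$agbc_mean$units,
                   agbc_se = stack$agbc_se$units,
                   zones = "category", water_mask = "boolean"),
              lapply(stack$cover, function(x) x$units))
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a landscape stack from a directory
#'
#' Inverse of [write_stack()]; also accepts real co-registered rasters laid
#' out in the same directory convention.
#'
#' @param dir Directory written by [write_stack()].
#' @return A [landscape_stack()].
#' @export
read_stack <- function(dir) {
  metaf <- file.path(dir, "metadata.json")
  if (!file.exists(metaf)) {
    stop(sprintf("'%s' does not look like a stack directory (no metadata.json)",
                 dir), call. = FALSE)
  }
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  units_of <- function(nm, fallback) {
    u <- meta$units[[nm]]
    if (is.null(u)) fallback else u
  }
  cover_files <- list.files(dir, pattern = "^cover_.*\\.asc$")
  pfts <- sub("^cover_(.*)\\.asc$", "\\1", cover_files)
  pfts <- c(intersect(ALL_PFTS, pfts), sort(setdiff(pfts, ALL_PFTS)))
  cover <- list()
  for (pft in pfts) {
    cover[[pft]] <- read_ascii_grid(file.path(dir, sprintf("cover_%s.asc", pft)),
                                    units_of(pft, "fraction"))
  }
  zn <- utils::read.csv(file.path(dir, "zone_names.csv"),
                        colClasses = c("character", "character"))
  wm <- read_ascii_grid(file.path(dir, "water_mask.asc"), "boolean")
  landscape_stack(
    agbc_mean = read_ascii_grid(file.path(dir, "agbc_mean.asc"),
                                units_of("agbc_mean", "Mg C ha-1")),
    agbc_se = read_ascii_grid(file.path(dir, "agbc_se.asc"),
                              units_of("agbc_se", "Mg C ha-1")),
    cover = cover,
    zones = read_ascii_grid(file.path(dir, "zones.asc"), "category"),
    zone_names = stats::setNames(zn$name, zn$label),
    water_mask = wm$values == 1
  )
}
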