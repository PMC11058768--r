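#' Configuration for the synthetic landscape generator
#'
#' The generator emulates the statistical structure of the North Slope input
#' rasters: latitudinal ecoregion bands running coastal plain (north) to
#' boreal (south), roughly doubled biomass in the southern band relative to
#' the northern one, per-pixel biomass standard errors, PFT cover fields with
#' deciduous-shrub cover rising southward, and a water mask with zero forage.
#'
#' @param n_rows,n_cols Grid dimensions (rows run north to south).
#' @param n_bands Number of latitudinal ecoregion bands (default 4:
#'   coastal plain, foothills, mountains, boreal).
#' @param south_north_biomass_ratio Target ratio of southern-band to
#'   northern-band mean biomass (default 2, matching the observed roughly
#'   doubled biomass in the warmer south of the study area).
#' @param mean_agbc_north Mean aboveground biomass carbon density of the
#'   northern band, Mg C ha-1 (default 1.5; calibrated so default synthetic
#'   densities land in a plausible 0-0.4 individuals km-2 envelope).
#' @param se_fraction Per-pixel standard error as a fraction of the mean
#'   (default 0.15).
#' @param shrub_gradient Length-2 numeric, deciduous-shrub cover fraction at
#'   the southern and northern band respectively (default `c(0.35, 0.10)`).
#' @param water_fraction Fraction of pixels masked as water (default 0.05).
#' @param noise_sdlog Standard deviation (log scale) of the multiplicative
#'   lognormal biomass noise (default 0.25).
#' @param smooth_window Odd box-filter width (pixels) used to impose mild
#'   spatial autocorrelation on the noise and water fields (default 3).
#' @param pixel_size_m Pixel edge length in metres (default 300).
#' @param seed Integer seed; identical configs produce bit-identical stacks.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rows = 100, n_cols = 100, n_bands = 4,
                             south_north_biomass_ratio = 2.0,
                             mean_agbc_north = 1.5, se_fraction = 0.15,
                             shrub_gradient = c(0.35, 0.10),
                             water_fraction = 0.05, noise_sdlog = 0.25,
                             smooth_window = 3, pixel_size_m = 300,
                             seed = 1L) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(length(n_rows) == 1 && n_rows >= 1 && n_rows == round(n_rows),
      "`n_rows` must be a positive integer")
  chk(length(n_cols) == 1 && n_cols >= 1 && n_cols == round(n_cols),
      "`n_cols` must be a positive integer")
  chk(n_bands >= 1 && n_bands == round(n_bands) && n_bands <= n_rows,
      "`n_bands` must be an integer in [1, n_rows]")
  chk(south_north_biomass_ratio > 0, "`south_north_biomass_ratio` must be > 0")
  chk(mean_agbc_north > 0, "`mean_agbc_north` must be > 0")
  chk(se_fraction >= 0 && se_fraction < 1, "`se_fraction` must be in [0, 1)")
  chk(length(shrub_gradient) == 2 && all(shrub_gradient >= 0) &&
        all(shrub_gradient <= 1), "`shrub_gradient` must be two fractions")
  chk(water_fraction >= 0 && water_fraction <= 1,
      "`water_fraction` must be in [0, 1]")
  chk(noise_sdlog >= 0, "`noise_sdlog` must be >= 0")
  chk(smooth_window >= 1 && smooth_window %% 2 == 1,
      "`smooth_window` must be odd and >= 1")
  chk(pixel_size_m > 0, "`pixel_size_m` must be > 0")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         n_bands = as.integer(n_bands),
         south_north_biomass_ratio = south_north_biomass_ratio,
         mean_agbc_north = mean_agbc_north, se_fraction = se_fraction,
         shrub_gradient = as.numeric(shrub_gradient),
         water_fraction = water_fraction, noise_sdlog = noise_sdlog,
         smooth_window = as.integer(smooth_window),
         pixel_size_m = pixel_size_m, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# separable box smoother with edge renormalisation (window w, odd)
smooth_field <- function(mat, w) {
  if (w <= 1) return(mat)
  h <- (w - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (dr in -h:h) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr) # clamped shift (edge replicate)
    for (dc in -h:h) {
      cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
      acc <- acc + mat[rs, cs, drop = FALSE]
      cnt <- cnt + 1
    }
  }
  acc / cnt
}

# band index per row: 1 = northernmost band, n_bands = southernmost
band_of_rows <- function(n_rows, n_bands) {
  if (n_bands == 1L) return(rep(1L, n_rows))
  as.integer(cut(seq_len(n_rows), breaks = n_bands, labels = FALSE))
}

# linear north->south interpolation of a per-band quantity
band_interp <- function(north, south, n_bands) {
  if (n_bands == 1L) return(north)
  north + (south - north) * (seq_len(n_bands) - 1) / (n_bands - 1)
}

default_zone_names <- function(n_bands) {
  if (n_bands == 4L) {
    nm <- c("coastal_plain", "foothills", "mountains", "boreal")
  } else {
    nm <- sprintf("band_%02d", seq_len(n_bands))
  }
  c(stats::setNames(nm, as.character(seq_len(n_bands))), "0" = "water")
}

# a standardized smoothed Gaussian field (mean 0, sd 1 over the grid)
smooth_gaussian <- function(nr, nc, w) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- smooth_field(z, w)
  if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
}

#' Generate a synthetic landscape stack
#'
#' Builds a co-registered raster stack with the structure the downgrading
#' analysis assumes (see [synthetic_config()]). Biomass is a per-band mean
#' times spatially smoothed lognormal multiplicative noise (positive,
#' right-skewed, unit mean); band means interpolate geometrically from the
#' northern value to `south_north_biomass_ratio` times it in the south.
#' Deciduous-shrub cover rises linearly southward while graminoid cover
#' declines; water pixels (the `water_fraction` lowest values of a smoothed
#' random field) get zero biomass and zero cover, and carry zone label 0.
#'
#' @param config A [synthetic_config()].
#' @return A [landscape_stack()]. Identical configs (including seed) yield
#'   bit-identical stacks; the caller's RNG state is left untouched.
#' @examples
#' stk <- generate_stack(synthetic_config(n_rows = 40, n_cols = 40, seed = 7))
#' stk
#' @export
generate_stack <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  nr <- config$n_rows; nc <- config$n_cols; nb <- config$n_bands
  band <- band_of_rows(nr, nb)
  band_mat <- matrix(band, nr, nc) # constant along columns

  # geometric interpolation keeps the south/north band-mean ratio exact in
  # expectation for any number of bands
  ratio <- config$south_north_biomass_ratio
  band_means <- config$mean_agbc_north *
    ratio^((seq_len(nb) - 1) / max(nb - 1, 1))
  if (nb == 1L) band_means <- config$mean_agbc_north

  noise <- exp(config$noise_sdlog *
                 smooth_gaussian(nr, nc, config$smooth_window) -
                 config$noise_sdlog^2 / 2)
  agbc <- band_means[band_mat] * noise
  dim(agbc) <- c(nr, nc)

  # water: exactly round(f * n) lowest pixels of an independent smooth field
  wfield <- smooth_gaussian(nr, nc, config$smooth_window)
  k <- round(config$water_fraction * nr * nc)
  water <- matrix(rank(wfield, ties.method = "first") <= k, nr, nc)

  # per-band cover profiles (north -> south)
  profiles <- list(
    forb            = band_interp(0.05, 0.05, nb),
    graminoid       = band_interp(0.35, 0.20, nb),
    deciduous_shrub = band_interp(config$shrub_gradient[2],
                                  config$shrub_gradient[1], nb),
    evergreen_shrub = band_interp(0.05, 0.10, nb),
    other           = band_interp(0.15, 0.15, nb)
  )
  cover_vals <- lapply(profiles, function(p) {
    v <- p[band_mat] + 0.02 * smooth_gaussian(nr, nc, config$smooth_window)
    dim(v) <- c(nr, nc)
    pmin(pmax(v, 0), 1)
  })
  # enforce per-pixel closure: rescale where fractions would exceed 1
  total <- Reduce(`+`, cover_vals)
  scale <- ifelse(total > 1, 1 / total, 1)
  cover_vals <- lapply(cover_vals, function(v) v * scale)

  agbc[water] <- 0
  se <- config$se_fraction * agbc
  cover_vals <- lapply(cover_vals, function(v) { v[water] <- 0; v })

  zones_vals <- band_mat
  zones_vals[water] <- 0L
  px <- config$pixel_size_m

  landscape_stack(
    agbc_mean = grid_layer(agbc, "Mg C ha-1", px),
    agbc_se = grid_layer(se, "Mg C ha-1", px),
    cover = lapply(cover_vals, grid_layer, units = "fraction",
                   pixel_size_m = px),
    zones = grid_layer(zones_vals + 0, "category", px),
    zone_names = default_zone_names(nb),
    water_mask = water
  )
}

#' Per-band means of a layer, excluding water and nodata
#'
#' Diagnostic used to check the latitudinal biomass gradient of a generated
#' stack (e.g. the southern/northern band-mean ratio).
#'
#' @param stack A [landscape_stack()].
#' @param layer A [grid_layer()] from the stack (default the biomass mean).
#' @param n_bands Number of latitudinal bands to split rows into.
#' @return Numeric vector of band means, north first.
#' @export
band_means <- function(stack, layer = stack$agbc_mean, n_bands = NULL) {
  stopifnot(inherits(stack, "landscape_stack"))
  if (is.null(n_bands)) {
    labs <- stack$zones$values[!stack$water_mask & !is.na(stack$zones$values)]
    n_bands <- length(unique(labs[labs > 0]))
  }
  band <- band_of_rows(nrow(layer$values), n_bands)
  band_mat <- matrix(band, nrow(layer$values), ncol(layer$values))
  ok <- !stack$water_mask & !is.na(layer$values)
  vapply(seq_len(n_bands),
         function(b) mean(layer$values[ok & band_mat == b]), numeric(1))
}
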