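# Fixture builders. Everything is generated in code; nothing is read from
# disk except in the explicit round-trip tests.

# a constant-valued stack for hand-checkable oracles
make_uniform_stack <- function(agbc = 1, cover = list(forb = 1), nr = 2, nc = 2,
                               se = 0, water = matrix(FALSE, nr, nc),
                               zones = matrix(1, nr, nc),
                               zone_names = c(`1` = "only"),
                               pixel_size_m = 300, fill_preferred = TRUE) {
  const <- function(x, units) grid_layer(matrix(x, nr, nc), units, pixel_size_m)
  if (fill_preferred) {
    for (pft in setdiff(c("forb", "graminoid", "deciduous_shrub"), names(cover))) {
      cover[[pft]] <- 0
    }
  }
  cov <- lapply(cover, const, units = "fraction")
  for (nm in names(cov)) cov[[nm]]$values[water] <- 0
  am <- const(agbc, "Mg C ha-1"); am$values[water] <- 0
  as <- const(se, "Mg C ha-1"); as$values[water] <- 0
  landscape_stack(agbc_mean = am, agbc_se = as, cover = cov,
                  zones = grid_layer(zones, "category", pixel_size_m),
                  zone_names = zone_names, water_mask = water)
}

# a small random stack with valid cover closure, for property tests
make_random_stack <- function(nr = 8, nc = 8, seed = 1, water_fraction = 0.1,
                              n_zones = 3) {
  set.seed(seed)
  raw <- function() matrix(runif(nr * nc), nr, nc)
  agbc <- 3 * raw()
  se <- 0.2 * agbc * raw()
  # dirichlet-style cover: scale five positive fields to sum below 1
  fields <- replicate(5, raw(), simplify = FALSE)
  tot <- Reduce(`+`, fields)
  budget <- 0.95 * raw() # per-pixel total cover in [0, 0.95]
  cover_vals <- lapply(fields, function(f) f / tot * budget)
  names(cover_vals) <- c("forb", "graminoid", "deciduous_shrub",
                         "evergreen_shrub", "other")
  water <- raw() < water_fraction
  agbc[water] <- 0; se[water] <- 0
  cover_vals <- lapply(cover_vals, function(v) { v[water] <- 0; v })
  zones <- matrix(sample.int(n_zones, nr * nc, replace = TRUE), nr, nc)
  zones[water] <- 0
  landscape_stack(
    agbc_mean = grid_layer(agbc, "Mg C ha-1"),
    agbc_se = grid_layer(se, "Mg C ha-1"),
    cover = lapply(cover_vals, grid_layer, units = "fraction"),
    zones = grid_layer(zones, "category"),
    zone_names = stats::setNames(c("water", sprintf("z%d", seq_len(n_zones))),
                                 as.character(0:n_zones)),
    water_mask = water
  )
}

# independent scalar oracle for the cascade: loops over pixels and chains
# the factors by hand, never touching the vectorized implementation
agdb_scalar_oracle <- function(stack, config, forage_rate = config$forage_rate) {
  nr <- nrow(stack$agbc_mean$values); nc <- ncol(stack$agbc_mean$values)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (stack$water_mask[i, j]) { out[i, j] <- 0; next }
    a <- stack$agbc_mean$values[i, j]
    if (is.na(a)) next
    f <- 0
    for (pft in c("forb", "graminoid", "deciduous_shrub")) {
      adj <- if (pft == "deciduous_shrub") config$shrub_preference_adj else 1
      f <- f + stack$cover[[pft]]$values[i, j] * config$digestibility[[pft]] * adj
    }
    out[i, j] <- (a * 100) * config$carbon_to_biomass * f * forage_rate *
      config$npp_factor
  }
  out
}
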