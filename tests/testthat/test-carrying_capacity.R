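needs <- annual_needs(herbivore_params())

test_that("density continues the worked pixel: 6.496 / 28.47 = 0.2282 km-2", {
  stk <- make_uniform_stack(agbc = 1, cover = list(forb = 1))
  agdb <- compute_agdb_annual(stk)
  dens <- density_from_agdb(agdb, needs[["low_mass"]], 3900)
  expect_equal(dens$layer$values[1, 1], 6.496 / 28.47, tolerance = 1e-12)
  expect_equal(round_half_up(dens$layer$values[1, 1], 4), 0.2282)
  expect_identical(dens$layer$units, "individuals km-2")
  # doubling the need halves the density everywhere
  half <- density_from_agdb(agdb, 2 * needs[["low_mass"]])
  expect_equal(half$layer$values, dens$layer$values / 2, tolerance = 1e-12)
  zero <- density_from_agdb(grid_layer(matrix(0, 2, 2), "Mg km-2 yr-1"),
                            needs[["low_mass"]])
  expect_equal(zero$layer$values, matrix(0, 2, 2))
  expect_error(density_from_agdb(agdb, 0), "positive")
})

test_that("zonal summary matches hand arithmetic on a single-zone grid", {
  gl <- function(v) grid_layer(matrix(v, 2, 2, byrow = TRUE), "individuals km-2")
  dens <- gl(c(0.1, 0.1, 0.3, 0.3))
  agdb <- grid_layer(matrix(1, 2, 2), "Mg km-2 yr-1")
  zones <- grid_layer(matrix(1, 2, 2), "category")
  zs <- zonal_summary(dens, dens, agdb, zones, c(`1` = "only"),
                      pixel_area_km2 = 0.09)
  z1 <- zs[zs$zone == "1", ]
  expect_equal(z1$mean_density_low_mass, 0.2)
  expect_equal(z1$supported_low_mass, 0.072)
  expect_equal(z1$area_km2, 0.36)
})

test_that("the all-zones row is the pooled computation, not a mean of means", {
  # two equal-area zones with mean densities 0.1 and 0.3
  dvals <- matrix(c(0.1, 0.1, 0.3, 0.3), 2, 2)
  zvals <- matrix(c(1, 1, 2, 2), 2, 2)
  dens <- grid_layer(dvals, "individuals km-2")
  agdb <- grid_layer(dvals * 10, "Mg km-2 yr-1")
  zs <- zonal_summary(dens, dens, agdb, grid_layer(zvals, "category"))
  expect_equal(zs$mean_density_low_mass[zs$zone == "total"], 0.2)
  # conservation: zone totals sum to the global total
  expect_equal(sum(zs$supported_low_mass[zs$zone != "total"]),
               zs$supported_low_mass[zs$zone == "total"], tolerance = 1e-12)
})

test_that("all-water zones support zero individuals", {
  water <- matrix(TRUE, 3, 3)
  stk <- make_uniform_stack(agbc = 0, cover = list(forb = 0), nr = 3, nc = 3,
                            water = water, zones = matrix(0, 3, 3),
                            zone_names = c(`0` = "water"))
  agdb <- compute_agdb_annual(stk)
  dl <- density_from_agdb(agdb, needs[["low_mass"]])
  dh <- density_from_agdb(agdb, needs[["high_mass"]])
  zs <- zonal_summary(dl, dh, agdb, stk$zones, stk$zone_names)
  expect_equal(zs$mean_density_low_mass[zs$name == "water"], 0)
  tot <- total_population(zs)
  expect_equal(tot$count_low_mass, 0)
  expect_equal(tot$count_high_mass, 0)
})

test_that("density bounds are ordered by mass and their ratio is the mass ratio", {
  stk <- make_random_stack(nr = 9, nc = 9, seed = 23)
  agdb <- compute_agdb_annual(stk)
  dl <- density_from_agdb(agdb, needs[["low_mass"]], 3900)
  dh <- density_from_agdb(agdb, needs[["high_mass"]], 5200)
  ok <- !is.na(agdb$layer$values) & agdb$layer$values > 0
  expect_true(all(dh$layer$values[ok] < dl$layer$values[ok]))
  # density(5.2 t) / density(3.9 t) = 3900 / 5200 at every pixel
  expect_equal(dh$layer$values[ok] / dl$layer$values[ok],
               rep(3900 / 5200, sum(ok)), tolerance = 1e-12)
  zs <- zonal_summary(dl, dh, agdb, stk$zones, stk$zone_names)
  expect_true(all(zs$mean_density_high_mass <= zs$mean_density_low_mass))
})

test_that("pooled mean equals the area-weighted mean of zone means", {
  stk <- make_random_stack(nr = 12, nc = 10, seed = 29, n_zones = 4)
  agdb <- compute_agdb_annual(stk)
  dl <- density_from_agdb(agdb, needs[["low_mass"]])
  zs <- zonal_summary(dl, dl, agdb, stk$zones, stk$zone_names)
  zrows <- zs[zs$zone != "total", ]
  weighted <- sum(zrows$mean_density_low_mass * zrows$area_km2) / sum(zrows$area_km2)
  expect_equal(weighted, zs$mean_density_low_mass[zs$zone == "total"],
               tolerance = 1e-10)
})

test_that("zone labels named but absent are reported and omitted", {
  dens <- grid_layer(matrix(0.1, 2, 2), "individuals km-2")
  agdb <- grid_layer(matrix(1, 2, 2), "Mg km-2 yr-1")
  zones <- grid_layer(matrix(1, 2, 2), "category")
  expect_message(
    zs <- zonal_summary(dens, dens, agdb, zones, c(`1` = "a", `9` = "ghost")),
    "omitted")
  expect_false("9" %in% zs$zone)
})

test_that("count presentation rounds to the nearest thousand", {
  expect_identical(format_approx_count(47987.3), "~48,000")
  expect_identical(format_approx_count(41612), "~42,000")
  expect_identical(format_approx_count(55499), "~55,000")
})
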