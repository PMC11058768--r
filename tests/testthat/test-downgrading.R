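cfg <- downgrade_config()

test_that("carbon-to-biomass conversion scales values and relabels units", {
  gl <- grid_layer(matrix(1, 3, 3), "Mg C ha-1")
  out <- carbon_to_total(gl, 2.03)
  expect_equal(out$values, matrix(2.03, 3, 3))
  expect_equal(sum(out$values), 18.27)
  expect_identical(out$units, "Mg ha-1")
  expect_equal(carbon_to_total(grid_layer(matrix(0, 2, 2), "Mg C ha-1"))$values,
               matrix(0, 2, 2))
  expect_error(carbon_to_total(gl, -1), "positive")
})

test_that("confidence bounds follow mean +/- 1.96 SE with zero clipping", {
  gl <- function(x) grid_layer(matrix(x, 1, 1), "Mg C ha-1")
  cb <- confidence_bounds(gl(10), gl(0))
  expect_equal(cb$lcl$values[1, 1], 10)
  expect_equal(cb$ucl$values[1, 1], 10)
  cb <- confidence_bounds(gl(1), gl(2), 1.96)
  expect_equal(cb$lcl$values[1, 1], 0) # clipped: biomass cannot be negative
  expect_equal(cb$ucl$values[1, 1], 4.92)
  cb <- confidence_bounds(gl(100), gl(10), 1.96)
  expect_equal(cb$lcl$values[1, 1], 80.4)
  expect_equal(cb$ucl$values[1, 1], 119.6)
  expect_error(confidence_bounds(gl(1), grid_layer(matrix(1, 2, 2), "x")),
               "co-registered")
})

test_that("pixel downgrade factor combines cover, digestibility and shrub adjustment", {
  expect_equal(pixel_downgrade_factor(c(forb = 1), cfg), 0.8)
  expect_equal(pixel_downgrade_factor(c(deciduous_shrub = 1), cfg), 0.30)
  expect_equal(
    pixel_downgrade_factor(c(forb = 0.2, graminoid = 0.3, deciduous_shrub = 0.5),
                           cfg), 0.46)
  expect_equal(pixel_downgrade_factor(c(forb = 0, graminoid = 0), cfg), 0)
  # non-preferred PFTs contribute nothing
  expect_equal(pixel_downgrade_factor(c(evergreen_shrub = 0.6, other = 0.4), cfg), 0)
  expect_warning(pixel_downgrade_factor(c(forb = 0.1, lichen = 0.2), cfg),
                 "unknown PFT")
  expect_error(pixel_downgrade_factor(c(forb = 0.9, graminoid = 0.3), cfg),
               "sum")
})

test_that("downgrade factor stays within [0, max digestibility] on random cover", {
  set.seed(31)
  for (i in 1:200) {
    raw <- runif(5)
    cov <- raw / sum(raw) * runif(1)
    names(cov) <- c("forb", "graminoid", "deciduous_shrub", "evergreen_shrub",
                    "other")
    f <- pixel_downgrade_factor(cov, cfg)
    expect_gte(f, 0)
    expect_lte(f, max(cfg$digestibility))
  }
})

test_that("the worked full-forb pixel yields 6.496 Mg km-2 yr-1", {
  stk <- make_uniform_stack(agbc = 1, cover = list(forb = 1))
  agdb <- compute_agdb_annual(stk, cfg)
  expect_equal(agdb$layer$values, matrix(6.496, 2, 2), tolerance = 1e-12)
  expect_identical(agdb$layer$units, "Mg km-2 yr-1")
  expect_identical(agdb$stage, "annual")
  # order of the scalar multiplications is immaterial
  by_other_order <- (((100 * 0.4) * 0.10) * 0.8) * 2.03
  expect_equal(agdb$layer$values[1, 1], by_other_order, tolerance = 1e-12)
})

test_that("vectorized cascade matches the independent per-pixel oracle", {
  for (seed in c(5, 6)) {
    stk <- make_random_stack(nr = 8, nc = 8, seed = seed)
    agdb <- compute_agdb_annual(stk, cfg)
    expect_equal(agdb$layer$values, agdb_scalar_oracle(stk, cfg),
                 tolerance = 1e-10)
    # and for a non-default variant/rate
    agdb_u <- compute_agdb_annual(stk, cfg, biomass_variant = "ucl",
                                  forage_rate_override = 0.25)
    ucl <- confidence_bounds(stk$agbc_mean, stk$agbc_se, cfg$pi_multiplier)$ucl
    stk_u <- stk; stk_u$agbc_mean <- ucl
    expect_equal(agdb_u$layer$values, agdb_scalar_oracle(stk_u, cfg, 0.25),
                 tolerance = 1e-10)
  }
})

test_that("cascade preserves zeros, water and nodata", {
  stk <- make_random_stack(nr = 6, nc = 6, seed = 9)
  stk$cover$forb$values[2, 2] <- NA
  agdb <- compute_agdb_annual(stk, cfg)
  expect_true(all(agdb$layer$values[stk$water_mask] == 0, na.rm = TRUE))
  expect_true(is.na(agdb$layer$values[2, 2]) || stk$water_mask[2, 2])
  # zero preferred cover => zero output
  bare <- make_uniform_stack(agbc = 5, cover = list(evergreen_shrub = 0.5),
                             fill_preferred = FALSE)
  expect_error(compute_agdb_annual(bare, cfg), "missing preferred cover")
  none <- make_uniform_stack(agbc = 5, cover = list(forb = 0, graminoid = 0,
                                                    deciduous_shrub = 0))
  expect_equal(compute_agdb_annual(none, cfg)$layer$values, matrix(0, 2, 2))
})

test_that("cascade output is monotone in biomass, cover and every factor", {
  base <- make_uniform_stack(agbc = 2, cover = list(forb = 0.3, graminoid = 0.2,
                                                    deciduous_shrub = 0.1))
  val <- function(stk, cfg2 = cfg) compute_agdb_annual(stk, cfg2)$layer$values[1, 1]
  v0 <- val(base)
  more_biomass <- make_uniform_stack(agbc = 3, cover = list(forb = 0.3,
                                                            graminoid = 0.2,
                                                            deciduous_shrub = 0.1))
  expect_gt(val(more_biomass), v0)
  more_cover <- make_uniform_stack(agbc = 2, cover = list(forb = 0.5,
                                                          graminoid = 0.2,
                                                          deciduous_shrub = 0.1))
  expect_gt(val(more_cover), v0)
  expect_gt(val(base, downgrade_config(forage_rate = 0.2)), v0)
  expect_gt(val(base, downgrade_config(npp_factor = 0.5)), v0)
  expect_gt(val(base, downgrade_config(carbon_to_biomass = 3)), v0)
})

test_that("stage statistics shrink monotonically along the cascade", {
  stk <- make_random_stack(nr = 10, nc = 10, seed = 17)
  agdb <- compute_agdb_annual(stk, cfg, keep_stages = TRUE)
  st <- attr(agdb, "stages")
  m <- vapply(st, function(s) mean(s$values, na.rm = TRUE), numeric(1))
  expect_true(all(diff(m[c("total_biomass", "digestible", "foraged", "annual")]) <= 0))
})

test_that("config validation rejects out-of-range factors", {
  expect_error(downgrade_config(carbon_to_biomass = 0), "carbon_to_biomass")
  expect_error(downgrade_config(digestibility = c(forb = 0.8)), "keys")
  expect_error(downgrade_config(digestibility = c(forb = 2, graminoid = 0.5,
                                                  deciduous_shrub = 0.6)),
               "digestibility")
  expect_error(downgrade_config(forage_rate = 0), "forage rates")
  expect_error(downgrade_config(npp_factor = 1.5), "npp_factor")
})
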