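test_that("end-to-end runs write the full artifact set and reproduce byte-identically", {
  stk <- generate_stack(synthetic_config(n_rows = 20, n_cols = 16, seed = 77))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- end_to_end(stk, out_dir = d1, sensitivity = TRUE, seed = 77)
  r2 <- end_to_end(stk, out_dir = d2, sensitivity = TRUE, seed = 77)
  expected <- c("agdb_annual.asc", "config.yaml", "density_high_mass.asc",
                "density_low_mass.asc", "report.json", "sensitivity.csv",
                "zonal_summary.csv")
  expect_setequal(list.files(d1), expected)
  for (f in expected) {
    expect_identical(readBin(file.path(d1, f), "raw", 10^7),
                     readBin(file.path(d2, f), "raw", 10^7),
                     info = f)
  }
  expect_s3_class(r1, "run_report")
  expect_identical(r1$totals, r2$totals)
})

test_that("a stack directory path feeds the pipeline identically to the object", {
  stk <- generate_stack(synthetic_config(n_rows = 10, n_cols = 10, seed = 3))
  sd <- withr::local_tempdir()
  write_stack(stk, sd)
  r_obj <- end_to_end(stk)
  r_dir <- end_to_end(sd)
  expect_identical(r_obj$totals, r_dir$totals)
  expect_identical(r_obj$zonal, r_dir$zonal)
})

test_that("report stage statistics shrink along the cascade and echo the config", {
  stk <- generate_stack(synthetic_config(n_rows = 15, n_cols = 15, seed = 12))
  r <- end_to_end(stk)
  m <- vapply(r$stage_stats, function(s) s$mean, numeric(1))
  expect_true(all(diff(m[c("total_biomass", "digestible", "foraged", "annual")]) <= 0))
  expect_equal(r$config$carbon_to_biomass, 2.03)
  expect_equal(r$forage_rate, 0.1)
  expect_true(all(c("agbc_mean", "agbc_se", "zones", "forb") %in%
                    names(r$input_checksums)))
  # downgrade-factor distribution is reported for comparison with field data
  expect_gte(r$downgrade_factor$min, 0)
  expect_lte(r$downgrade_factor$max, 0.8)
})

test_that("upper-confidence-limit totals dominate lower-confidence-limit totals", {
  stk <- generate_stack(synthetic_config(n_rows = 12, n_cols = 12, seed = 19))
  r_l <- end_to_end(stk, biomass_variant = "lcl")
  r_u <- end_to_end(stk, biomass_variant = "ucl")
  expect_gte(r_u$totals$count_low_mass, r_l$totals$count_low_mass)
  expect_gte(r_u$totals$count_high_mass, r_l$totals$count_high_mass)
})

test_that("an all-water landscape supports nobody end to end", {
  stk <- generate_stack(synthetic_config(n_rows = 8, n_cols = 8,
                                         water_fraction = 1, seed = 2))
  r <- end_to_end(stk)
  expect_equal(r$totals$count_low_mass, 0)
  expect_equal(r$totals$count_high_mass, 0)
})

test_that("the comparison table reproduces its literature and allometric cells", {
  stk <- generate_stack(synthetic_config(n_rows = 10, n_cols = 10, seed = 14))
  r <- end_to_end(stk)
  tab <- render_comparison_table(r)
  get <- function(pattern, col) tab[grepl(pattern, tab$method), col]
  expect_equal(round_half_up(get("bone-remains", "density_low"), 2), 0.55)
  expect_equal(round_half_up(get("caribou", "density_low"), 2), 0.99)
  expect_equal(round_half_up(get("Damuth", "density_low"), 2), 0.17)
  expect_equal(round_half_up(get("Damuth", "biomass_low_t_km2"), 1), 0.8)
  # biomass columns are density x reference mass on every row
  expect_equal(tab$biomass_low_t_km2, tab$density_low * 4.55, tolerance = 1e-12)
  expect_equal(tab$biomass_high_t_km2, tab$density_high * 4.55, tolerance = 1e-12)
  # the forage-based range is ordered
  expect_lte(get("forage-based", "density_low"), get("forage-based", "density_high"))
})
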