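test_that("monthly climate respects ordering, coverage and ranges", {
  cfg <- tiny_config(3L)
  cl <- generate_monthly_climate(cfg)
  expect_true(all(cl$IT < cl$MT & cl$MT < cl$AT))
  expect_true(all(cl$PT >= 0))
  ## coverage: Dec 1999 through Aug 2008 for every site
  months_in_span <- 1 + 12 * 8 + 8
  expect_equal(nrow(cl), 3 * months_in_span)
  expect_true(any(cl$year == 1999 & cl$month == 12))
  expect_false(any(cl$year == 2008 & cl$month > 8))
  ## plausible upper-Midwest values
  expect_true(all(cl$MT > -35 & cl$MT < 40))
  expect_true(all(cl$PT < 1000))
  ## seasonality: July warmer than January on average
  expect_gt(mean(cl$MT[cl$month == 7]), mean(cl$MT[cl$month == 1]) + 15)
})

test_that("climate and topography are seed-deterministic", {
  cfg <- tiny_config(9L)
  expect_identical(generate_monthly_climate(cfg, seed = 4L),
                   generate_monthly_climate(cfg, seed = 4L))
  expect_identical(generate_topography(cfg, seed = 4L),
                   generate_topography(cfg, seed = 4L))
  b1 <- simulate_counts(cfg, seed = 12L)
  b2 <- simulate_counts(cfg, seed = 12L)
  expect_identical(b1$surveys, b2$surveys)
  expect_identical(b1$latent, b2$latent)
  expect_false(identical(b1$surveys, simulate_counts(cfg, seed = 13L)$surveys))
})

test_that("topography is per-site, time-invariant and in range", {
  topo <- generate_topography(study_config())
  expect_equal(nrow(topo), 48L)  # one row per site: constant across years
  expect_equal(anyDuplicated(topo$site), 0L)
  expect_true(all(topo$elevation_m >= 150 & topo$elevation_m <= 500))
  expect_true(all(topo$slope_deg >= 0 & topo$slope_deg <= 30))
  expect_true(all(topo$aspect_deg >= 0 & topo$aspect_deg < 360))
  expect_true(all(topo$canopy_pct >= 0 & topo$canopy_pct <= 100))
})

test_that("degenerate growth parameters give the expected dynamics", {
  cfg <- tiny_config(2L, n_sites = 1L, years = c(2000L, 2004L))
  flat <- truth_params(beta0 = 1, beta_lag1 = 0, beta_lag2 = 0,
                       beta_env = stats::setNames(numeric(16),
                                                  endoexo:::env_slot_names()),
                       noise_sd = 0, initial_density_range = c(10, 10))
  lat <- simulate_counts(cfg, flat)$latent
  expect_true(all(abs(lat$latent_density - 10) < 1e-12))  # lambda == 1

  doubling <- truth_params(beta0 = 2, beta_lag1 = 0, beta_lag2 = 0,
                           beta_env = stats::setNames(numeric(16),
                                                      endoexo:::env_slot_names()),
                           noise_sd = 0, initial_density_range = c(10, 10),
                           density_cap = 1e9)
  lat2 <- simulate_counts(cfg, doubling)$latent
  lat2 <- lat2[order(lat2$year, lat2$generation), ]
  ## both generations of the first year are initial draws; doubling starts
  ## with the next generation
  expect_equal(lat2$latent_density, 10 * 2^c(0, 0, 1:8))
})

test_that("the explosion guard clips runaway densities at the cap", {
  cfg <- tiny_config(2L, n_sites = 1L, years = c(2000L, 2006L))
  boom <- truth_params(beta0 = 3, beta_lag1 = 0, beta_lag2 = 0,
                       beta_env = stats::setNames(numeric(16),
                                                  endoexo:::env_slot_names()),
                       noise_sd = 0, initial_density_range = c(10, 10),
                       density_cap = 100)
  b <- simulate_counts(cfg, boom)
  expect_true(all(b$latent$latent_density <= 100))
  expect_gt(b$n_clipped, 0L)
})

test_that("counts are non-negative integers and densities non-negative", {
  b <- simulate_counts(tiny_config(21L))
  expect_true(all(b$surveys$count >= 0))
  expect_true(all(b$surveys$count == floor(b$surveys$count)))
  expect_true(all(b$latent$latent_density >= 0))
  ## every site-year-generation with nonzero density has surveys
  key_lat <- with(b$latent[b$latent$latent_density > 0, ],
                  paste(site, year, generation))
  key_sur <- with(b$surveys, paste(site, year, generation))
  expect_true(all(key_lat %in% key_sur))
})

test_that("processed densities invert the count model", {
  ## noise-free growth, many surveys: mean count/km / 2.5 ~ latent density
  cfg <- study_config(populations = data.frame(name = "P1", n_sites = 2L,
                                               first_year = 2000L,
                                               last_year = 2004L),
                      surveys_per_flight = 100L,
                      transect_length_km_range = c(0.8, 1.2), seed = 8L)
  truth <- truth_params(beta0 = 1.02, beta_lag1 = 0, beta_lag2 = 0,
                        beta_env = stats::setNames(numeric(16),
                                                   endoexo:::env_slot_names()),
                        noise_sd = 0, initial_density_range = c(8, 12))
  b <- simulate_counts(cfg, truth)
  dens <- generation_densities(b$surveys)
  m <- match(with(dens, paste(site, year, generation)),
             with(b$latent, paste(site, year, generation)))
  rel_err <- abs(dens$density_per_ha - b$latent$latent_density[m]) /
    b$latent$latent_density[m]
  expect_lt(mean(rel_err), 0.05)
  expect_lt(max(rel_err), 0.15)
})

test_that("bundles round-trip through plain-text files", {
  b <- simulate_counts(tiny_config(31L))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir, c("surveys.csv", "climate.csv",
                                               "topo.csv", "truth.json")))))
  s <- read_surveys(file.path(dir, "surveys.csv"))
  expect_equal(nrow(s), nrow(b$surveys))
  expect_equal(s$count, b$surveys$count)
  cl <- read_climate(file.path(dir, "climate.csv"))
  expect_equal(cl$MT, b$climate$MT, tolerance = 1e-12)
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$beta_env, b$truth$beta_env, tolerance = 1e-12)
  expect_equal(tr$noise_sd, b$truth$noise_sd)
})
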