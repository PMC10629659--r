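test_that("trasp maps north to 0, south to 1, east/west to 0.5", {
  expect_equal(trasp(30), 0)
  expect_equal(trasp(210), 1)
  expect_equal(trasp(120), 0.5)
  expect_equal(trasp(300), 0.5)
})

test_that("trasp is bounded, periodic, and symmetric about north", {
  a <- seq(0, 359.5, by = 0.5)
  v <- trasp(a)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(trasp(a + 360), v, tolerance = 1e-12)
  x <- seq(0, 180, by = 7.5)
  expect_equal(trasp(30 + x), trasp(30 - x), tolerance = 1e-12)
})

test_that("flat cells with undefined aspect get the neutral index 0.5", {
  expect_equal(trasp(NA), 0.5)
  expect_equal(trasp(c(90, NA, 270)), c(trasp(90), 0.5, trasp(270)))
})

test_that("window means average the life-stage months", {
  cl <- expand.grid(site = "S1", year = 2000:2001, month = 1:12)
  cl$MT <- 10; cl$AT <- 15; cl$IT <- 5; cl$PT <- 50
  ## overwinter: Dec of previous year + Jan-Mar of current year
  cl$MT[cl$year == 2000 & cl$month == 12] <- -8
  cl$MT[cl$year == 2001 & cl$month == 1] <- -10
  cl$MT[cl$year == 2001 & cl$month == 2] <- -6
  cl$MT[cl$year == 2001 & cl$month == 3] <- 0
  w <- window_means(cl, "S1", 2001, 1)
  expect_equal(w$MT_OW, -6.0)
  ## single-month window equals the monthly value unchanged
  cl$MT[cl$year == 2001 & cl$month == 6] <- 17.3
  w <- window_means(cl, "S1", 2001, 1)
  expect_equal(w$MT_JN, 17.3)
  ## constant series: every window equals the constant
  w2 <- window_means(cl, "S1", 2001, 2)
  expect_equal(unlist(w2[c("AT_JN", "AT_JL", "AT_AG")]),
               c(AT_JN = 15, AT_JL = 15, AT_AG = 15))
})

test_that("windowed climate matches a brute-force mean oracle", {
  set.seed(11)
  cl <- expand.grid(site = c("A", "B"), year = 2000:2003, month = 1:12)
  for (v in c("MT", "AT", "IT", "PT")) cl[[v]] <- rnorm(nrow(cl), 10, 5)
  wc <- windowed_climate(cl, 1)
  pick <- function(site, year, month)
    cl$MT[cl$site == site & cl$year == year & cl$month == month]
  for (site in c("A", "B")) for (year in 2001:2003) {
    oracle <- mean(c(pick(site, year - 1, 12), pick(site, year, 1),
                     pick(site, year, 2), pick(site, year, 3)))
    got <- wc$MT_OW[wc$site == site & wc$year == year]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  ## invariant to row order of the climate table
  wc2 <- windowed_climate(cl[sample(nrow(cl)), ], 1)
  expect_equal(wc2, wc, tolerance = 1e-12)
  ## missing constituent month -> window missing
  cl2 <- cl[!(cl$site == "A" & cl$year == 2002 & cl$month == 3), ]
  wc3 <- windowed_climate(cl2, 1)
  expect_true(is.na(wc3$MT_OW[wc3$site == "A" & wc3$year == 2002]))
  expect_false(is.na(wc3$MT_SP[wc3$site == "A" & wc3$year == 2002]))
})

test_that("assembled designs have the 18 canonical candidate columns", {
  b <- simulate_counts(tiny_config(5L))
  dens <- attach_lags(generation_densities(b$surveys))
  ds1 <- assemble_design(dens, b$climate, b$topo, "P1", 1)
  expect_equal(colnames(ds1$X),
               c("PS", "PF", "MT_OW", "MT_SP", "MT_JN", "AT_OW", "AT_SP",
                 "AT_JN", "IT_OW", "IT_SP", "IT_JN", "PT_OW", "PT_SP",
                 "PT_JN", "Canopy", "Elevation", "Slope", "Trasp"))
  ds2 <- assemble_design(dens, b$climate, b$topo, "P1", 2)
  expect_equal(colnames(ds2$X),
               c("CF", "PS", "MT_JN", "MT_JL", "MT_AG", "AT_JN", "AT_JL",
                 "AT_AG", "IT_JN", "IT_JL", "IT_AG", "PT_JN", "PT_JL",
                 "PT_AG", "Canopy", "Elevation", "Slope", "Trasp"))
  ## no silent row loss
  expect_equal(nrow(ds1$X) + ds1$n_dropped, ds1$n_candidates)
  expect_equal(length(ds1$y), nrow(ds1$X))
})

test_that("a missing climate month drops exactly the affected rows", {
  b <- simulate_counts(tiny_config(6L))
  dens <- attach_lags(generation_densities(b$surveys))
  full <- assemble_design(dens, b$climate, b$topo, "P1", 1)
  site <- full$rows$site[1]
  year <- full$rows$year[1]
  cl <- b$climate[!(b$climate$site == site & b$climate$year == year &
                      b$climate$month == 3), ]
  cut <- assemble_design(dens, cl, b$topo, "P1", 1)
  expect_equal(nrow(cut$X), nrow(full$X) - 1L)
  expect_false(any(cut$rows$site == site & cut$rows$year == year))
  ## the second generation (Jun-Aug windows) is unaffected by March
  expect_equal(nrow(assemble_design(dens, cl, b$topo, "P1", 2)$X),
               nrow(assemble_design(dens, b$climate, b$topo, "P1", 2)$X))
})
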