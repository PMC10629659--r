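test_that("known active predictors are recovered from synthetic data", {
  rep <- recovery_replicate(424L)
  f <- rep$fit
  expect_s3_class(f, "endoexo_fit")
  active <- names(rep$truth_std)[abs(rep$truth_std) > 1e-12]
  ## all six active predictors selected with the right signs
  expect_true(all(active %in% f$selected))
  est <- rep$report
  expect_equal(est$recall, 1)
  expect_equal(est$sign_agreement, 1)
  expect_lt(est$coef_rmse, 0.15)
  expect_gt(f$adj_r_squared, 0.5)
  expect_true(all(f$table$se[!is.na(f$table$se)] > 0))
})

test_that("degenerate datasets are skipped with a structured reason", {
  ds <- list(population = "P", generation = 1L,
             X = matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b"))),
             y = rep(1, 20))
  s <- fit_population(ds, rf = FALSE)
  expect_s3_class(s, "endoexo_skip")
  expect_match(s$reason, "zero-variance")
  ds2 <- list(population = "P", generation = 1L,
              X = matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b"))),
              y = rnorm(4))
  expect_match(fit_population(ds2, rf = FALSE)$reason, "fewer than 10")
})

test_that("fit_population is deterministic given its seed", {
  b <- simulate_counts(tiny_config(44L, n_sites = 4L))
  dens <- attach_lags(generation_densities(b$surveys))
  ds <- assemble_design(dens, b$climate, b$topo, "P1", 1)
  f1 <- fit_population(ds, seed = 5L, rf = FALSE)
  f2 <- fit_population(ds, seed = 5L, rf = FALSE)
  expect_identical(f1$table, f2$table)
  expect_identical(f1$selected, f2$selected)
})

test_that("random-forest baseline reports OOB fit and importances", {
  rep <- recovery_replicate(77L, rf = TRUE)
  expect_true(is.numeric(rep$fit$rf$oob_r2))
  expect_gt(rep$fit$rf$oob_r2, 0)
  expect_equal(length(rep$fit$rf$importance), 18L)
  ## strongest importance should sit on an active variable
  active <- names(rep$truth_std)[abs(rep$truth_std) > 1e-12]
  expect_true(names(which.max(rep$fit$rf$importance)) %in% active)
})

make_pooled_dataset <- function(n_big = 200L, n_small = 25L,
                                slope_big = 1, slope_small = -1,
                                seed = 1L) {
  ## two populations, one informative predictor with opposite slopes, one
  ## noise predictor; the big population dominates a naive pooled fit
  set.seed(seed)
  n <- n_big + n_small
  X <- cbind(x = rnorm(n), z = rnorm(n))
  pop <- rep(c("BIG", "SMALL"), c(n_big, n_small))
  slope <- ifelse(pop == "BIG", slope_big, slope_small)
  y <- slope * X[, "x"] + rnorm(n, 1, 0.3)
  list(population = "All", generation = 1L, X = X, y = y,
       rows = data.frame(site = "s", population = pop, year = 1L))
}

test_that("balanced bootstrap resamples an equal quota per population", {
  ds <- make_pooled_dataset()
  rep <- endoexo:::boot_replicate(ds$X, ds$y, ds$rows$population,
                                  quota = 25L, ga = ga_config(), seed = 3L)
  expect_equal(as.integer(table(ds$rows$population[rep$idx])), c(25L, 25L))
  ## identical replicate seed -> identical coefficients
  rep2 <- endoexo:::boot_replicate(ds$X, ds$y, ds$rows$population,
                                   quota = 25L, ga = ga_config(), seed = 3L)
  expect_identical(rep$coef, rep2$coef)
})

test_that("balancing pulls the pooled estimate toward the population mean", {
  ds <- make_pooled_dataset(seed = 8L)
  bal <- bootstrap_balanced_fit(ds, B = 30L, seed = 9L)
  naive <- fit_population(ds, seed = 9L, rf = FALSE)
  bal_x <- bal$table$coefficient[bal$table$variable == "x"]
  naive_x <- naive$table$coefficient[naive$table$variable == "x"]
  ## truth: slopes +1 (oversampled) and -1 (rare); unweighted mean is 0 on
  ## the standardized scale as well
  if (is.na(naive_x)) naive_x <- 0
  if (is.na(bal_x)) bal_x <- 0
  expect_lt(abs(bal_x), abs(naive_x))
  expect_error(bootstrap_balanced_fit(list(
    population = "All", generation = 1L, X = ds$X, y = ds$y,
    rows = data.frame(population = rep("ONE", length(ds$y)))),
    B = 30L), "at least 2")
  expect_warning(bootstrap_balanced_fit(ds, B = 5L, seed = 2L), "unstable")
})

test_that("adjusted R-squared never exceeds R-squared", {
  for (seed in c(3L, 11L)) {
    rep <- recovery_replicate(seed)
    f <- rep$fit
    expect_lte(f$adj_r_squared, f$r_squared)
    expect_lte(f$r_squared, 1)
  }
})
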