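## Shared fixtures: everything is generated in code at test time.

tiny_config <- function(seed = 1L, n_sites = 3L, years = c(2000L, 2008L)) {
  study_config(populations = data.frame(name = "P1", n_sites = n_sites,
                                        first_year = years[1],
                                        last_year = years[2]),
               seed = seed)
}

## A hand-sized density table: one site, two generations, consecutive years.
toy_density_table <- function(years = 2000:2002,
                              d1 = c(2, 4, 8), d2 = c(3, 6, 12)) {
  data.frame(site = "S1", population = "P1",
             year = rep(years, each = 2),
             generation = rep(1:2, length(years)),
             density_per_ha = as.vector(rbind(d1, d2)))
}

## Configuration of the parameter-recovery experiment: one population,
## 24 sites x 22 years (~400 eligible first-generation rows), 12 surveys
## per flight so that count noise stays well below the process signal,
## and 6 of 18 candidate predictors active.
recovery_config <- function(seed) {
  study_config(populations = data.frame(name = "SYN", n_sites = 24L,
                                        first_year = 2000L,
                                        last_year = 2021L),
               surveys_per_flight = 12L,
               transect_length_km_range = c(0.5, 1.0), seed = seed)
}

recovery_truth <- function() {
  be <- stats::setNames(numeric(16), endoexo:::env_slot_names())
  be[c("MT_w1", "AT_w2", "PT_w2", "Slope")] <- c(-0.28, 0.22, -0.22, -0.18)
  truth_params(beta0 = 1.6, beta_lag1 = -0.02, beta_lag2 = -0.01,
               beta_env = be, noise_sd = 0.1,
               initial_density_range = c(10, 30), density_cap = 500)
}

## One recovery replicate: simulate, process, assemble, fit generation 1.
recovery_replicate <- function(seed, rf = FALSE) {
  b <- simulate_counts(recovery_config(seed), recovery_truth())
  dens <- attach_lags(generation_densities(b$surveys))
  ds <- assemble_design(dens, b$climate, b$topo, "SYN", 1)
  f <- fit_population(ds, seed = seed + 1L, rf = rf)
  run <- structure(list(fits = list(f), bundle = b), class = "endoexo_run")
  list(bundle = b, dataset = ds, fit = f,
       report = recovery_report(run),
       truth_std = endoexo:::truth_on_fit_scale(f, b$truth, b$env_stats))
}
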