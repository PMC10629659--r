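## Synthetic study generator. Emulates the survey configuration of the
## five-population Karner blue monitoring program (48 permanent sites,
## 8-27 year spans, two flight periods per year) with a known-coefficient
## endo-exogenous growth model plus Gaussian process noise and Poisson
## observation noise, so that every downstream stage has a
## parameter-recovery test surface.

#' Study configuration for the synthetic generator
#'
#' The default mirrors the monitoring program the package models: five
#' populations (CW 14 sites 1990-2018, NW 8 sites 2005-2013, FM 12 sites
#' 1997-2018, IDNP 6 sites 1994-2011, APBP 8 sites 2007-2018 -- 48 sites in
#' total), four surveys per flight period and transect lengths of
#' 0.3-1.2 km.
#'
#' @param populations data.frame with columns `name, n_sites, first_year,
#'   last_year`. Each span must allow at least two prior generations
#'   (`last_year >= first_year + 2`).
#' @param surveys_per_flight surveys walked per site and flight period.
#' @param transect_length_km_range range the per-site transect length is
#'   drawn from (km).
#' @param seed base seed stored with the configuration.
#' @export
study_config <- function(populations = NULL, surveys_per_flight = 4L,
                         transect_length_km_range = c(0.3, 1.2),
                         seed = 1L) {
  if (is.null(populations))
    populations <- data.frame(
      name = c("CW", "NW", "FM", "IDNP", "APBP"),
      n_sites = c(14L, 8L, 12L, 6L, 8L),
      first_year = c(1990L, 2005L, 1997L, 1994L, 2007L),
      last_year = c(2018L, 2013L, 2018L, 2011L, 2018L))
  stopifnot_cols(populations, c("name", "n_sites", "first_year", "last_year"),
                 "populations")
  stopifnot(all(populations$n_sites >= 1L),
            all(populations$last_year >= populations$first_year + 2L),
            surveys_per_flight >= 1L,
            transect_length_km_range[1] > 0,
            diff(transect_length_km_range) >= 0)
  structure(list(populations = populations,
                 surveys_per_flight = as.integer(surveys_per_flight),
                 transect_length_km_range = transect_length_km_range,
                 seed = as.integer(seed)),
            class = "study_config")
}

## Names of the 16 environmental coefficient slots. Windows are positional
## (w1-w3 map to OW/SP/JN for generation 1 and JN/JL/AG for generation 2).
env_slot_names <- function() {
  c(as.vector(t(outer(climate_vars, paste0("w", 1:3), paste, sep = "_"))),
    "Canopy", "Elevation", "Slope", "Trasp")
}

#' Ground-truth parameters of the generative growth model
#'
#' The generative model for the growth rate of each generation t is
#' `lambda_t = beta0 + beta_lag1 * Y_(t-1) + beta_lag2 * Y_(t-2) +
#' sum(beta_env * z) + N(0, noise_sd)`, where Y are raw lagged densities
#' (adults/ha), z are the 16 environmental covariates standardized per
#' generation over the whole bundle, and the next density is
#' `D_t = max(0, lambda_t * D_(t-1))`. The default truth encodes weak
#' density dependence around a stable equilibrium with a handful of active
#' climate and topography effects.
#'
#' @param beta0 intercept of the growth model.
#' @param beta_lag1,beta_lag2 coefficients on the raw densities one and two
#'   generations back (per adult/ha).
#' @param beta_env named 16-vector of coefficients on the standardized
#'   environmental covariates, in the slot order of [env_slot_names()];
#'   zeros mark inactive variables.
#' @param noise_sd standard deviation of the Gaussian process noise on
#'   lambda (>= 0).
#' @param initial_density_range range (adults/ha) initial densities are
#'   drawn from.
#' @param density_cap explosion guard: densities are clipped here.
#' @export
truth_params <- function(beta0 = 1.15, beta_lag1 = -0.05, beta_lag2 = -0.02,
                         beta_env = NULL, noise_sd = 0.15,
                         initial_density_range = c(2, 8),
                         density_cap = 500) {
  slots <- env_slot_names()
  if (is.null(beta_env)) {
    beta_env <- stats::setNames(numeric(16), slots)
    ## default active set: overwinter/June temperatures, spring/July
    ## precipitation, slope and canopy (signs as in northern-range
    ## bivoltine populations: warm egg stages and wet springs depress
    ## spring-generation growth)
    beta_env[c("MT_w1", "IT_w1", "PT_w2", "Slope", "Canopy")] <-
      c(-0.15, -0.10, -0.12, -0.08, 0.06)
  }
  if (is.null(names(beta_env))) names(beta_env) <- slots
  stopifnot(length(beta_env) == 16L, identical(names(beta_env), slots),
            noise_sd >= 0, initial_density_range[1] >= 0, density_cap > 0)
  structure(list(beta0 = beta0, beta_lag1 = beta_lag1, beta_lag2 = beta_lag2,
                 beta_env = beta_env, noise_sd = noise_sd,
                 initial_density_range = initial_density_range,
                 density_cap = density_cap),
            class = "truth_params")
}

site_table <- function(config) {
  p <- config$populations
  data.frame(population = rep(p$name, p$n_sites),
             site = unlist(lapply(seq_len(nrow(p)), function(i)
               sprintf("%s-%02d", p$name[i], seq_len(p$n_sites[i])))),
             first_year = rep(p$first_year, p$n_sites),
             last_year = rep(p$last_year, p$n_sites))
}

#' Generate a monthly climate table
#'
#' Monthly mean temperature follows a seasonal sinusoid (July peak) with a
#' persistent site offset and independent year-month noise; monthly maximum
#' and minimum temperatures add and subtract strictly positive diurnal
#' spreads, so `IT < MT < AT` always holds; total precipitation is
#' log-normal. Values sit in plausible upper-Midwest ranges. The table
#' covers December of the year before the earliest first survey year
#' through August of the last, for every site.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return data.frame with columns `site, year, month, MT, AT, IT, PT`.
#' @export
generate_monthly_climate <- function(config, seed = config$seed) {
  sites <- site_table(config)
  y0 <- min(sites$first_year) - 1L
  y1 <- max(sites$last_year)
  ## months: Dec of y0, all of y0+1 .. y1-1, Jan-Aug of y1
  ym <- rbind(data.frame(year = y0, month = 12L),
              expand.grid(month = 1:12, year = seq(y0 + 1L, y1 - 1L))[, 2:1],
              data.frame(year = y1, month = 1:8))
  with_seed(derive_seed(seed, "climate"), {
    site_off <- stats::setNames(stats::rnorm(nrow(sites), 0, 1.2), sites$site)
    grid <- merge(sites["site"], ym)
    n <- nrow(grid)
    seasonal <- 7 + 14.5 * cos(2 * pi * (grid$month - 7) / 12)
    MT <- seasonal + site_off[grid$site] + stats::rnorm(n, 0, 1.8)
    spread_hi <- 4.5 + abs(stats::rnorm(n, 0, 1.2))
    spread_lo <- 4.5 + abs(stats::rnorm(n, 0, 1.2))
    out <- data.frame(site = grid$site, year = grid$year, month = grid$month,
                      MT = MT, AT = MT + spread_hi, IT = MT - spread_lo,
                      PT = stats::rlnorm(n, meanlog = log(65), sdlog = 0.55))
    out <- out[order(out$site, out$year, out$month), ]
    rownames(out) <- NULL
    out
  })
}

#' Generate per-site topography and canopy attributes
#'
#' Elevation (150-500 m), slope (0-30 degrees), aspect (0-360 degrees,
#' circular-uniform) and canopy cover (0-100 %) are drawn once per site and
#' held fixed across years, matching the assumption that terrain and canopy
#' are constant over the study span.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return data.frame with `site, population, elevation_m, slope_deg,
#'   aspect_deg, canopy_pct`.
#' @export
generate_topography <- function(config, seed = config$seed) {
  sites <- site_table(config)
  with_seed(derive_seed(seed, "topo"), {
    data.frame(site = sites$site, population = sites$population,
               elevation_m = stats::runif(nrow(sites), 150, 500),
               slope_deg = pmin(abs(stats::rnorm(nrow(sites), 0, 9)), 30),
               aspect_deg = stats::runif(nrow(sites), 0, 360),
               canopy_pct = 100 * stats::rbeta(nrow(sites), 2, 2))
  })
}

## Standardized per-generation environmental covariate matrices for all
## site-years, plus the raw means/sds used (needed to map fitted
## standardized coefficients back to truth).
env_design <- function(config, climate, topo) {
  sc <- site_covariates(topo)
  lapply(1:2, function(gen) {
    wc <- windowed_climate(climate, gen)
    m <- match(wc$site, sc$site)
    wins <- names(stage_windows(gen))
    clim_order <- as.vector(t(outer(climate_vars, wins, paste, sep = "_")))
    raw <- cbind(as.matrix(wc[, clim_order, drop = FALSE]),
                 as.matrix(sc[m, c("Canopy", "Elevation", "Slope", "Trasp")]))
    colnames(raw) <- env_slot_names()  # w1-w3 now align with window order
    ok <- stats::complete.cases(raw)
    ctr <- colMeans(raw[ok, , drop = FALSE])
    scl <- apply(raw[ok, , drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    z <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
    list(site = wc$site, year = wc$year, z = z, center = ctr, scale = scl)
  })
}

#' Simulate transect counts from the generative growth model
#'
#' Iterates the endo-exogenous growth model site by site and generation by
#' generation (see [truth_params()]), then overlays Poisson observation
#' noise: each of the `surveys_per_flight` transect walks of a flight period
#' observes `Poisson(density * 2.5 * transect_km)` adults, so that the mean
#' count per km inverts back to the latent density in expectation under the
#' 2.5 ha-per-km assumption. Densities are floored at zero (an extinct
#' series stays extinct) and clipped at `truth$density_cap` (with a log
#' entry) as an explosion guard.
#'
#' @param config a [study_config()].
#' @param truth a [truth_params()].
#' @param climate,topo tables from [generate_monthly_climate()] /
#'   [generate_topography()]; generated from `config` when omitted.
#' @param seed integer seed; all internal streams derive from it.
#' @return an object of class `endoexo_bundle`: list with `surveys`,
#'   `climate`, `topo`, `truth`, `latent` (latent densities and growth
#'   rates), `env_stats` (per-generation standardization of the
#'   environmental covariates) and `config`.
#' @export
simulate_counts <- function(config, truth = truth_params(),
                            climate = generate_monthly_climate(config, seed),
                            topo = generate_topography(config, seed),
                            seed = config$seed) {
  sites <- site_table(config)
  env <- env_design(config, climate, topo)
  env_key <- lapply(env, function(e) paste(e$site, e$year))
  n_clipped <- 0L

  lat <- with_seed(derive_seed(seed, "dynamics"), {
    rows <- list()
    for (s in seq_len(nrow(sites))) {
      site <- sites$site[s]
      yrs <- sites$first_year[s]:sites$last_year[s]
      D <- matrix(NA_real_, length(yrs), 2)  # rows = years, cols = generations
      L <- matrix(NA_real_, length(yrs), 2)  # latent lambda draws
      D[1, ] <- stats::runif(2, truth$initial_density_range[1],
                             truth$initial_density_range[2])
      zrow <- function(gen, year) {
        i <- match(paste(site, year), env_key[[gen]])
        env[[gen]]$z[i, ]
      }
      step <- function(lag1, lag2, gen, year) {
        lam <- truth$beta0 + truth$beta_lag1 * lag1 + truth$beta_lag2 * lag2 +
          sum(truth$beta_env * zrow(gen, year)) +
          stats::rnorm(1, 0, truth$noise_sd)
        d <- max(0, lam * lag1)
        if (d > truth$density_cap) {
          n_clipped <<- n_clipped + 1L
          d <- truth$density_cap
        }
        c(lam, d)
      }
      for (j in seq_along(yrs)[-1]) {
        r1 <- step(D[j - 1, 2], D[j - 1, 1], 1L, yrs[j])
        L[j, 1] <- r1[1]; D[j, 1] <- r1[2]
        r2 <- step(D[j, 1], D[j - 1, 2], 2L, yrs[j])
        L[j, 2] <- r2[1]; D[j, 2] <- r2[2]
      }
      rows[[s]] <- data.frame(site = site, population = sites$population[s],
                              year = rep(yrs, 2),
                              generation = rep(1:2, each = length(yrs)),
                              latent_density = c(D[, 1], D[, 2]),
                              latent_lambda = c(L[, 1], L[, 2]))
    }
    do.call(rbind, rows)
  })
  if (n_clipped > 0L)
    ee_log("simulate_counts: %d density value(s) clipped at cap %g",
           n_clipped, truth$density_cap)

  surveys <- with_seed(derive_seed(seed, "observation"), {
    transect_km <- stats::setNames(
      stats::runif(nrow(sites), config$transect_length_km_range[1],
                   config$transect_length_km_range[2]), sites$site)
    S <- config$surveys_per_flight
    idx <- rep(seq_len(nrow(lat)), each = S)
    walk <- rep(seq_len(S), nrow(lat))
    tk <- transect_km[lat$site[idx]]
    mu <- lat$latent_density[idx] * HA_PER_KM * tk
    start <- ifelse(lat$generation[idx] == 1L, "-06-01", "-07-15")
    data.frame(site = lat$site[idx], population = lat$population[idx],
               date = as.Date(paste0(lat$year[idx], start)) + 4L * (walk - 1L),
               year = lat$year[idx], generation = lat$generation[idx],
               count = stats::rpois(length(mu), mu),
               transect_m = round(1000 * tk))
  })

  structure(list(surveys = surveys, climate = climate, topo = topo,
                 truth = truth, latent = lat,
                 env_stats = lapply(env, function(e)
                   list(center = e$center, scale = e$scale)),
                 config = config, n_clipped = n_clipped),
            class = "endoexo_bundle")
}

#' @export
print.endoexo_bundle <- function(x, ...) {
  cat(sprintf("endoexo synthetic bundle: %d sites, %d populations, %d surveys\n",
              length(unique(x$surveys$site)),
              length(unique(x$surveys$population)), nrow(x$surveys)))
  invisible(x)
}

#' Write or read a synthetic bundle as plain-text files
#'
#' `write_bundle()` writes `surveys.csv`, `climate.csv`, `topo.csv` and
#' `truth.json` into a directory; `read_surveys()`, `read_climate()`,
#' `read_topo()` and `read_truth()` read them back (and accept any files
#' with the same schema, synthetic or real).
#'
#' @param bundle an `endoexo_bundle`.
#' @param dir output directory (created if needed).
#' @return `write_bundle()` returns `dir` invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$surveys[, c("site", "population", "date",
                                      "generation", "count", "transect_m")],
                   file.path(dir, "surveys.csv"), row.names = FALSE)
  utils::write.csv(bundle$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$topo, file.path(dir, "topo.csv"), row.names = FALSE)
  truth <- unclass(bundle$truth)
  truth$env_stats <- bundle$env_stats
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_bundle
#' @param path a CSV file path.
#' @export
read_surveys <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(s, c("site", "population", "date", "generation", "count",
                      "transect_m"), "surveys.csv")
  s$date <- as.Date(s$date)
  s
}

#' @rdname write_bundle
#' @export
read_climate <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(cl, c("site", "year", "month", climate_vars), "climate.csv")
  cl
}

#' @rdname write_bundle
#' @export
read_topo <- function(path) {
  tp <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(tp, c("site", "elevation_m", "slope_deg", "aspect_deg",
                       "canopy_pct"), "topo.csv")
  tp
}

#' @rdname write_bundle
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$beta_env <- stats::setNames(as.numeric(tr$beta_env), env_slot_names())
  tr
}
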