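## Transect counts -> per-generation densities, growth rates and lag
## predictors. A kilometre of transect is assumed to survey a 2.5 ha band,
## so density (adults/ha) = mean count per km / 2.5.

HA_PER_KM <- 2.5

#' Mean transect count per kilometre
#'
#' Averages count-per-kilometre over the repeated surveys of one
#' site-year-generation: `mean(count / (transect_m / 1000))`.
#'
#' @param records data.frame of surveys for a single site, year and
#'   generation with columns `count` and `transect_m`.
#' @return mean count per km; `NA` (with a log entry) for an empty set.
#' @export
mean_count_per_km <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    ee_log("mean_count_per_km: empty survey set -> NA")
    return(NA_real_)
  }
  stopifnot_cols(records, c("count", "transect_m"), "records")
  if (any(records$transect_m <= 0)) stop("transect_m must be positive")
  mean(records$count / (records$transect_m / 1000))
}

#' Convert mean count per km to density per hectare
#'
#' One kilometre of transect is taken to represent a 2.5 ha area, so the
#' density of adults per hectare is the mean count per km divided by 2.5.
#'
#' @param mean_count_per_km non-negative mean count per km of transect.
#' @return adults per hectare.
#' @export
density_from_count <- function(mean_count_per_km) {
  if (any(mean_count_per_km < 0, na.rm = TRUE))
    stop("mean count per km must be non-negative")
  mean_count_per_km / HA_PER_KM
}

#' Generation-to-generation growth rate
#'
#' The growth rate lambda from the previous generation to the current one is
#' the density ratio `current / previous`. When the previous density is zero
#' or missing, lambda is undefined and returned as `NA` (such rows are later
#' excluded from model datasets).
#'
#' @param current_density,previous_density non-negative densities per ha.
#' @return lambda, or `NA` where undefined.
#' @export
growth_rate <- function(current_density, previous_density) {
  if (any(c(current_density, previous_density) < 0, na.rm = TRUE))
    stop("densities must be non-negative")
  ifelse(!is.na(previous_density) & previous_density > 0,
         current_density / previous_density, NA_real_)
}

#' Per-generation densities from raw survey records
#'
#' Aggregates repeated transect surveys to one row per site, year and
#' generation, computing the mean count per km and the implied density per
#' hectare.
#'
#' @param surveys data.frame with columns `site, population, date,
#'   generation, count, transect_m`.
#' @return data.frame sorted by site, year, generation with
#'   `mean_count_per_km` and `density_per_ha`.
#' @export
generation_densities <- function(surveys) {
  stopifnot_cols(surveys, c("site", "population", "generation", "count",
                            "transect_m"), "surveys")
  if (any(surveys$count < 0) || any(surveys$count != floor(surveys$count)))
    stop("counts must be non-negative integers")
  year <- if ("year" %in% names(surveys)) surveys$year
          else as.integer(format(as.Date(surveys$date), "%Y"))
  key <- paste(surveys$site, year, surveys$generation, sep = "\r")
  cpk <- surveys$count / (surveys$transect_m / 1000)
  agg <- tapply(cpk, key, mean)
  first <- !duplicated(key)
  out <- data.frame(site = surveys$site[first],
                    population = surveys$population[first],
                    year = year[first],
                    generation = as.integer(surveys$generation[first]),
                    mean_count_per_km = as.numeric(agg[key[first]]))
  out$density_per_ha <- density_from_count(out$mean_count_per_km)
  out <- out[order(out$site, out$year, out$generation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach growth rates and lagged-density predictors
#'
#' Fills, for every site-year-generation row, the growth rate lambda
#' (density ratio to the immediately preceding generation) and the two
#' lagged-density predictors used by the endo-exogenous model:
#' first-generation rows of year y get `lag1 = PS` (previous-year second
#' generation) and `lag2 = PF` (previous-year first generation);
#' second-generation rows get `lag1 = CF` (current-year first generation)
#' and `lag2 = PS` (previous-year second generation). Rows whose lags are
#' unavailable (a population's first observed year, or a gap year) or whose
#' previous-generation density is zero are flagged for exclusion, so models
#' start from the second year of each series.
#'
#' @param densities data.frame from [generation_densities()] (or any table
#'   with `site, population, year, generation, density_per_ha`).
#' @return the input with columns `lambda`, `lag1_density`, `lag2_density`,
#'   `lag1_name`, `lag2_name` and logical `exclude` added.
#' @export
attach_lags <- function(densities) {
  stopifnot_cols(densities, c("site", "population", "year", "generation",
                              "density_per_ha"), "densities")
  d <- densities[order(densities$site, densities$year, densities$generation), ,
                 drop = FALSE]
  key <- paste(d$site, d$year, d$generation, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate site-year-generation rows in density table")
  look <- function(site, year, gen) {
    m <- match(paste(site, year, gen, sep = "\r"), key)
    d$density_per_ha[m]
  }
  g1 <- d$generation == 1L
  prev <- ifelse(g1, look(d$site, d$year - 1L, 2L),   # previous generation
                     look(d$site, d$year,      1L))
  d$lag1_density <- prev                              # PS for gen 1, CF for gen 2
  d$lag2_density <- ifelse(g1, look(d$site, d$year - 1L, 1L),
                               look(d$site, d$year - 1L, 2L))
  d$lag1_name <- ifelse(g1, "PS", "CF")
  d$lag2_name <- ifelse(g1, "PF", "PS")
  d$lambda <- growth_rate(d$density_per_ha, prev)
  d$exclude <- is.na(d$lag1_density) | is.na(d$lag2_density) | is.na(d$lambda)
  n_excl <- sum(d$exclude)
  if (n_excl) ee_log("attach_lags: %d row(s) flagged (missing lags or zero previous density)",
                     n_excl)
  rownames(d) <- NULL
  d
}
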