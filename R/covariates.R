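#' Topographic solar radiation index (trasp)
#'
#' Rescales circular aspect to a linear index of solar exposure in `[0, 1]`:
#' `trasp = (1 - cos(pi/180 * (aspect - 30))) / 2`. North-oriented slopes
#' (aspect 30 degrees) map to 0 and south-oriented slopes (210 degrees) to 1,
#' so the index increases towards warmer, sun-exposed orientations.
#'
#' @param aspect_deg aspect in degrees clockwise from north. `NA` (flat
#'   cells with undefined aspect) returns the neutral value 0.5.
#' @return numeric vector in `[0, 1]`, periodic in aspect with period 360.
#' @examples
#' trasp(c(30, 210, 120))
#' @export
trasp <- function(aspect_deg) {
  out <- (1 - cos(pi / 180 * (aspect_deg - 30))) / 2
  flat <- is.na(aspect_deg)
  if (any(flat)) {
    ee_log("trasp: %d flat cell(s) with undefined aspect set to 0.5", sum(flat))
    out[flat] <- 0.5
  }
  out
}

## Life-stage month windows per generation. Each element: window label ->
## data.frame(month, year_offset). Overwinter December belongs to the
## previous calendar year.
stage_windows <- function(generation) {
  if (generation == 1L) {
    list(OW = data.frame(month = c(12L, 1L, 2L, 3L),
                         year_offset = c(-1L, 0L, 0L, 0L)),
         SP = data.frame(month = 4:5, year_offset = 0L),
         JN = data.frame(month = 6L, year_offset = 0L))
  } else if (generation == 2L) {
    list(JN = data.frame(month = 6L, year_offset = 0L),
         JL = data.frame(month = 7L, year_offset = 0L),
         AG = data.frame(month = 8L, year_offset = 0L))
  } else stop("generation must be 1 or 2")
}

climate_vars <- c("MT", "AT", "IT", "PT")

## Ordered covariate labels for one generation's design matrix.
design_labels <- function(generation) {
  lags <- if (generation == 1L) c("PS", "PF") else c("CF", "PS")
  wins <- names(stage_windows(generation))
  clim <- as.vector(t(outer(climate_vars, wins, paste, sep = "_")))
  c(lags, clim, "Canopy", "Elevation", "Slope", "Trasp")
}

#' Stage-windowed climate means
#'
#' Collapses a monthly climate table to the life-stage windows of one
#' generation: for the first (spring) generation the egg stage overwinters
#' Dec-Mar (OW, December taken from the previous calendar year), larvae and
#' pupae develop Apr-May (SP) and adults fly in June (JN); for the second
#' (summer) generation the windows are June (JN), July (JL) and August (AG).
#' Each of the four monthly variables (MT, AT, IT, PT) is averaged
#' arithmetically over the months of each window.
#'
#' @param climate data.frame with columns `site, year, month, MT, AT, IT, PT`.
#' @param generation 1 or 2.
#' @param pt_sum if `TRUE`, total precipitation (PT) is summed over the
#'   window months instead of averaged. Off by default.
#' @return data.frame with one row per site-year and one column per
#'   variable-window combination (e.g. `MT_OW`, `PT_SP`). A window with any
#'   constituent month absent is `NA` for that site-year.
#' @export
windowed_climate <- function(climate, generation, pt_sum = FALSE) {
  stopifnot_cols(climate, c("site", "year", "month", climate_vars), "climate")
  wins <- stage_windows(generation)
  keys <- unique(climate[, c("site", "year")])
  keys <- keys[order(keys$site, keys$year), , drop = FALSE]
  out <- keys
  rownames(out) <- NULL
  idx <- paste(climate$site, climate$year, climate$month)
  for (w in names(wins)) {
    spec <- wins[[w]]
    ## value matrix: rows = site-years, cols = months of the window
    for (v in climate_vars) {
      vals <- matrix(NA_real_, nrow(keys), nrow(spec))
      for (j in seq_len(nrow(spec))) {
        want <- paste(keys$site, keys$year + spec$year_offset[j], spec$month[j])
        m <- match(want, idx)
        vals[, j] <- climate[[v]][m]
      }
      agg <- if (v == "PT" && pt_sum) rowSums(vals) else rowMeans(vals)
      out[[paste(v, w, sep = "_")]] <- agg
    }
  }
  out
}

#' @rdname windowed_climate
#' @param site,year a single site-year to extract.
#' @return `window_means()` returns the single matching row as a named list.
#' @export
window_means <- function(climate, site, year, generation, pt_sum = FALSE) {
  wc <- windowed_climate(climate[climate$site == site &
                                   climate$year %in% c(year - 1L, year), ,
                                 drop = FALSE],
                         generation, pt_sum = pt_sum)
  row <- wc[wc$site == site & wc$year == year, , drop = FALSE]
  if (nrow(row) == 0L) stop(sprintf("no climate rows for site %s year %d",
                                    site, year))
  as.list(row[1, setdiff(names(row), c("site", "year"))])
}

## Normalise a topo table: accept canopy as percent, derive trasp from aspect
## if not already present.
site_covariates <- function(topo) {
  stopifnot_cols(topo, c("site", "elevation_m", "slope_deg"), "topo")
  out <- data.frame(site = topo$site,
                    Elevation = topo$elevation_m,
                    Slope = topo$slope_deg)
  out$Trasp <- if ("trasp" %in% names(topo)) topo$trasp
               else trasp(ifelse(!is.na(topo$slope_deg) & topo$slope_deg == 0,
                                 NA_real_, topo$aspect_deg))
  out$Canopy <- topo$canopy_pct
  out
}

#' Assemble the candidate design matrix for one population and generation
#'
#' Joins the per-generation density table (growth rate and lagged densities)
#' with stage-windowed climate and site topography into the 18-column
#' candidate predictor matrix: two lagged densities, four climate variables
#' by three life-stage windows, plus canopy, elevation, slope and trasp.
#' Rows flagged for exclusion (no previous-year lags, zero previous density)
#' or with any missing covariate are dropped and counted.
#'
#' @param densities data.frame from [attach_lags()].
#' @param climate monthly climate table (see [windowed_climate()]).
#' @param topo per-site table with `site, elevation_m, slope_deg, aspect_deg,
#'   canopy_pct` (or a precomputed `trasp` column).
#' @param population population label, or `"All"` to pool every population.
#' @param generation 1 or 2.
#' @param pt_sum passed to [windowed_climate()].
#' @return an object of class `endoexo_dataset`: list with `population`,
#'   `generation`, `X` (raw predictor matrix, labelled columns), `y` (lambda),
#'   `rows` (site/population/year bookkeeping), `n_candidates`, `n_dropped`
#'   and a `drop_log` naming each exclusion filter with its count.
#' @export
assemble_design <- function(densities, climate, topo, population, generation,
                            pt_sum = FALSE) {
  stopifnot_cols(densities,
                 c("site", "population", "year", "generation", "lambda",
                   "lag1_density", "lag2_density", "exclude"),
                 "densities")
  d <- densities[densities$generation == generation, , drop = FALSE]
  if (!identical(population, "All"))
    d <- d[d$population == population, , drop = FALSE]
  n_cand <- nrow(d)
  drop_log <- c()

  keep <- !d$exclude & !is.na(d$lambda)
  drop_log["no_lags_or_lambda"] <- sum(!keep)
  d <- d[keep, , drop = FALSE]

  wc <- windowed_climate(climate, generation, pt_sum = pt_sum)
  m <- match(paste(d$site, d$year), paste(wc$site, wc$year))
  clim_cols <- setdiff(names(wc), c("site", "year"))
  Xc <- as.matrix(wc[m, clim_cols, drop = FALSE])

  sc <- site_covariates(topo)
  mt <- match(d$site, sc$site)
  Xt <- as.matrix(sc[mt, c("Canopy", "Elevation", "Slope", "Trasp"),
                     drop = FALSE])

  labs <- design_labels(generation)
  X <- cbind(d$lag1_density, d$lag2_density, Xc, Xt)
  colnames(X) <- c(labs[1:2], clim_cols, "Canopy", "Elevation", "Slope",
                   "Trasp")
  X <- X[, labs, drop = FALSE]  # canonical order

  complete <- stats::complete.cases(X) & !is.na(d$lambda)
  drop_log["missing_covariate"] <- sum(!complete)
  if (!any(complete))
    stop(sprintf(
      "no eligible rows for %s generation %d (first blocking filter: %s)",
      population, generation,
      names(drop_log)[which(drop_log > 0)[1]]))

  out <- list(population = population, generation = as.integer(generation),
              X = X[complete, , drop = FALSE],
              y = d$lambda[complete],
              rows = d[complete, c("site", "population", "year")],
              n_candidates = n_cand,
              n_dropped = n_cand - sum(complete),
              drop_log = drop_log)
  class(out) <- "endoexo_dataset"
  out
}

#' @export
print.endoexo_dataset <- function(x, ...) {
  cat(sprintf("endoexo design: %s, generation %d\n", x$population,
              x$generation))
  cat(sprintf("  %d rows x %d candidate predictors (%d candidate rows, %d dropped)\n",
              nrow(x$X), ncol(x$X), x$n_candidates, x$n_dropped))
  invisible(x)
}
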