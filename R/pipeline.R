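#' Pipeline configuration
#'
#' Either `synthetic = TRUE` (inputs generated from `config`/`truth`) or
#' file paths to `surveys.csv`, `climate.csv` and `topo.csv` -- not both.
#'
#' @param synthetic generate inputs with [simulate_counts()].
#' @param config a [study_config()] (synthetic runs).
#' @param truth a [truth_params()] (synthetic runs).
#' @param surveys,climate,topo input CSV paths (file-based runs).
#' @param ga a [ga_config()].
#' @param B,quota balanced-bootstrap settings for the pooled models (see
#'   [bootstrap_balanced_fit()]).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir output directory for the run artifacts.
#' @param pt_sum aggregate window precipitation by sum instead of mean.
#' @param rf run the random-forest baseline per model.
#' @export
pipeline_config <- function(synthetic = TRUE, config = study_config(),
                            truth = truth_params(), surveys = NULL,
                            climate = NULL, topo = NULL, ga = ga_config(),
                            B = 50L, quota = NULL, seed = 1L,
                            out_dir = tempfile("endoexo-run-"),
                            pt_sum = FALSE, rf = TRUE) {
  files <- !is.null(surveys)
  if (synthetic && files)
    stop("give either synthetic = TRUE or input file paths, not both")
  if (!synthetic && !files)
    stop("file-based run needs surveys, climate and topo paths")
  structure(list(synthetic = synthetic, config = config, truth = truth,
                 surveys = surveys, climate = climate, topo = topo,
                 ga = ga, B = B, quota = quota, seed = as.integer(seed),
                 out_dir = out_dir, pt_sum = pt_sum, rf = rf),
            class = "pipeline_config")
}

fit_to_list <- function(f) {
  if (inherits(f, "endoexo_skip"))
    return(list(population = f$population, generation = f$generation,
                skipped = TRUE, reason = f$reason))
  list(population = f$population, generation = f$generation, n = f$n,
       selected = f$selected, table = f$table,
       n_components = f$n_components, r_squared = f$r_squared,
       adj_r_squared = f$adj_r_squared,
       rf_oob_r2 = if (!is.null(f$rf)) f$rf$oob_r2 else NULL,
       bootstrap = if (!is.null(f$bootstrap))
         f$bootstrap[c("B", "quota")] else NULL)
}

#' Render fitted models as a coefficient table per generation
#'
#' One column per population model, one row per candidate predictor; cells
#' show `coefficient +/- SE stars`, and stay blank for variables removed by
#' the GA feature selection. The last row carries each model's adjusted
#' R-squared.
#'
#' @param fits list of `endoexo_fit` objects for one generation.
#' @return character data.frame.
#' @export
coefficient_table <- function(fits) {
  fits <- Filter(function(f) inherits(f, "endoexo_fit"), fits)
  stopifnot(length(fits) > 0L)
  vars <- fits[[1]]$candidates
  out <- data.frame(Variable = c(vars, "Adj-R2"))
  for (f in fits) {
    cell <- rep("", length(vars))
    t <- f$table
    sel <- !is.na(t$coefficient)
    cell[match(t$variable[sel], vars)] <-
      sprintf("%.2f±%.3f %s", t$coefficient[sel], t$se[sel],
              t$stars[sel])
    out[[f$population]] <- c(cell, sprintf("%.2f", f$adj_r_squared))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the inputs, derives per-generation densities and
#' growth rates, assembles the 18-candidate design per population and
#' generation, fits each per-population model with [fit_population()] and
#' each pooled "All" model with [bootstrap_balanced_fit()], and writes
#' `densities.csv`, `fits.json`, per-generation coefficient tables
#' (`coefficients_gen1.csv`, `coefficients_gen2.csv`) and
#' `run-manifest.json` (seeds, toggles, row accounting) to the output
#' directory. Synthetic runs also write the input bundle and `truth.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return an object of class `endoexo_run`: list with `fits` (named
#'   `<population>_gen<g>`), `densities`, `manifest`, `out_dir` and, for
#'   synthetic runs, the `bundle`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (cfg$synthetic) {
    bundle <- simulate_counts(cfg$config, cfg$truth, seed = cfg$seed)
    write_bundle(bundle, cfg$out_dir)
    surveys <- bundle$surveys
    climate <- bundle$climate
    topo <- bundle$topo
  } else {
    bundle <- NULL
    for (f in c(surveys = cfg$surveys, climate = cfg$climate,
                topo = cfg$topo))
      if (!file.exists(f)) stop("input file not found: ", f)
    surveys <- read_surveys(cfg$surveys)
    climate <- read_climate(cfg$climate)
    topo <- read_topo(cfg$topo)
  }
  dens <- attach_lags(generation_densities(surveys))
  utils::write.csv(dens, file.path(cfg$out_dir, "densities.csv"),
                   row.names = FALSE)

  pops <- c("All", unique(dens$population))
  fits <- list()
  accounting <- list()
  for (gen in 1:2) for (pop in pops) {
    key <- sprintf("%s_gen%d", pop, gen)
    ds <- tryCatch(
      assemble_design(dens, climate, topo, pop, gen, pt_sum = cfg$pt_sum),
      error = function(e) e)
    if (inherits(ds, "error")) {
      fits[[key]] <- structure(list(population = pop, generation = gen,
                                    n = 0L, reason = conditionMessage(ds)),
                               class = "endoexo_skip")
      next
    }
    accounting[[key]] <- list(candidate_rows = ds$n_candidates,
                              used = nrow(ds$X), dropped = ds$n_dropped,
                              drop_log = as.list(ds$drop_log))
    fits[[key]] <- if (pop == "All")
      bootstrap_balanced_fit(ds, ga = cfg$ga, B = cfg$B, quota = cfg$quota,
                             seed = derive_seed(cfg$seed, key))
    else
      fit_population(ds, ga = cfg$ga, seed = derive_seed(cfg$seed, key),
                     rf = cfg$rf)
  }

  jsonlite::write_json(lapply(fits, fit_to_list),
                       file.path(cfg$out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  for (gen in 1:2) {
    gf <- Filter(function(f) identical(f$generation, gen) ||
                   identical(f$generation, as.integer(gen)), fits)
    ok <- Filter(function(f) inherits(f, "endoexo_fit"), gf)
    if (length(ok))
      utils::write.csv(coefficient_table(ok),
                       file.path(cfg$out_dir,
                                 sprintf("coefficients_gen%d.csv", gen)),
                       row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("endoexo")),
    seed = cfg$seed,
    toggles = list(pt_sum = cfg$pt_sum, lambda = "ratio", rf = cfg$rf),
    bootstrap = list(B = cfg$B, quota = cfg$quota),
    synthetic = cfg$synthetic,
    n_models = length(fits),
    n_fitted = sum(vapply(fits, inherits, logical(1), "endoexo_fit")),
    row_accounting = accounting)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run-manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  structure(list(fits = fits, densities = dens, manifest = manifest,
                 out_dir = cfg$out_dir, bundle = bundle),
            class = "endoexo_run")
}

#' @export
print.endoexo_run <- function(x, ...) {
  cat(sprintf("endoexo run: %d models (%d fitted) in %s\n",
              x$manifest$n_models, x$manifest$n_fitted, x$out_dir))
  invisible(x)
}

## Truth on the scale of a fit's standardized predictors. The generator's
## lag coefficients act on raw densities and its environmental coefficients
## on bundle-standardized covariates; a fitted coefficient multiplies the
## dataset-standardized column, so truth maps via the two sets of sds.
truth_on_fit_scale <- function(fit, truth, env_stats) {
  gen <- fit$generation
  labels <- fit$candidates
  out <- stats::setNames(numeric(length(labels)), labels)
  scl <- fit$standardization$scale
  out[labels[1]] <- truth$beta_lag1 * scl[[labels[1]]]
  out[labels[2]] <- truth$beta_lag2 * scl[[labels[2]]]
  env_names <- labels[-(1:2)]
  gen_scale <- env_stats[[gen]]$scale
  slot <- env_slot_names()
  for (j in seq_along(env_names)) {
    lab <- env_names[j]
    if (!lab %in% names(scl)) next  # dropped constant column
    out[lab] <- truth$beta_env[[slot[j]]] * scl[[lab]] / gen_scale[[slot[j]]]
  }
  out
}

#' Parameter-recovery report for a synthetic run
#'
#' For every fitted model of a synthetic run, compares the selected variables
#' and coefficients against the generator's ground truth: precision and
#' recall of the active set, sign agreement of recovered active
#' coefficients, and the RMSE of the standardized coefficients (unselected
#' variables counted as 0) against truth mapped onto the fitted scale.
#'
#' @param run an `endoexo_run` from a synthetic [run_pipeline()] call (or a
#'   run directory containing `truth.json`).
#' @return data.frame with one row per fitted model.
#' @export
recovery_report <- function(run) {
  if (is.character(run)) stop("pass the endoexo_run object of a synthetic run")
  if (is.null(run$bundle)) stop("recovery_report needs a synthetic run with truth")
  truth <- run$bundle$truth
  env_stats <- run$bundle$env_stats
  fits <- Filter(function(f) inherits(f, "endoexo_fit"), run$fits)
  rows <- lapply(fits, function(f) {
    tr <- truth_on_fit_scale(f, truth, env_stats)
    active <- names(tr)[abs(tr) > 1e-12]
    sel <- f$selected
    est <- stats::setNames(rep(0, length(tr)), names(tr))
    t <- f$table
    got <- !is.na(t$coefficient)
    est[t$variable[got]] <- t$coefficient[got]
    hit <- intersect(sel, active)
    data.frame(population = f$population, generation = f$generation,
               n = f$n,
               precision = if (length(sel)) length(hit) / length(sel) else NA,
               recall = if (length(active)) length(hit) / length(active) else NA,
               sign_agreement = if (length(hit))
                 mean(sign(est[hit]) == sign(tr[hit])) else NA,
               coef_rmse = sqrt(mean((est - tr)^2)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
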