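#' Fit the endo-exogenous model for one population and generation
#'
#' Runs the full per-model pipeline on an assembled design: standardization
#' of the candidate predictors, a random-forest regression baseline (500
#' trees; out-of-bag R-squared and permutation importances, kept as
#' diagnostics only), genetic-algorithm subset selection by OLS-AIC,
#' leave-one-out choice of PLS components, the PLS fit on the selected
#' subset and jack-knife standard errors, p-values and significance stars.
#' Adjusted R-squared is `1 - (1 - R2) (n - 1) / (n - k - 1)` for k selected
#' predictors. Deterministic given `seed`.
#'
#' @param dataset an `endoexo_dataset` from [assemble_design()], or any list
#'   with elements `X`, `y`, `population`, `generation`.
#' @param ga a [ga_config()]; its `seed` is overridden from `seed`.
#' @param seed integer master seed for the stochastic stages (GA, RF).
#' @param rf run the random-forest baseline (set `FALSE` to skip the
#'   diagnostic when only selection and coefficients are needed).
#' @return an object of class `endoexo_fit`; or class `endoexo_skip` (with a
#'   `reason`) when the dataset has fewer than 10 rows or a constant
#'   response.
#' @export
fit_population <- function(dataset, ga = ga_config(), seed = 1L, rf = TRUE) {
  X <- dataset$X; y <- dataset$y
  skip <- function(reason) {
    ee_log("skipping %s gen %s: %s", dataset$population %||% "?",
           dataset$generation %||% "?", reason)
    structure(list(population = dataset$population,
                   generation = dataset$generation,
                   n = length(y), reason = reason),
              class = "endoexo_skip")
  }
  if (length(y) < 10L) return(skip("fewer than 10 rows after exclusions"))
  if (stats::sd(y) == 0) return(skip("zero-variance response"))

  std <- standardize(X)
  Xs <- std$X
  labels <- colnames(X)

  rf_out <- NULL
  if (isTRUE(rf)) {
    rf_out <- with_seed(derive_seed(seed, "rf"), {
      f <- randomForest::randomForest(Xs, y, ntree = 500, importance = TRUE)
      list(oob_r2 = f$rsq[length(f$rsq)],
           importance = randomForest::importance(f, type = 1)[, 1])
    })
  }

  ga$seed <- derive_seed(seed, "ga")
  sel <- ga_select(Xs, y, ga)
  chosen <- names(sel$mask)[sel$mask]

  tab <- data.frame(variable = labels, coefficient = NA_real_, se = NA_real_,
                    p = NA_real_, stars = NA_character_)
  ncomp <- 0L; r2 <- 0; adj_r2 <- 0
  if (length(chosen) > 0L) {
    Xsel <- Xs[, chosen, drop = FALSE]
    ncomp <- choose_components(Xsel, y)
    inf <- jackknife_inference(Xsel, y, ncomp)
    idx <- match(inf$variable, tab$variable)
    tab$coefficient[idx] <- inf$coefficient
    tab$se[idx] <- inf$se
    tab$p[idx] <- inf$p
    tab$stars[idx] <- inf$stars
    fit <- pls_fit(Xsel, y, ncomp)
    r2 <- fit$r_squared
    n <- length(y); k <- length(chosen)
    adj_r2 <- if (n - k - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - k - 1) else NA_real_
  }

  structure(list(population = dataset$population,
                 generation = dataset$generation,
                 n = length(y),
                 candidates = labels,
                 selected = chosen,
                 table = tab,
                 n_components = ncomp,
                 r_squared = r2, adj_r_squared = adj_r2,
                 ga = list(best_aic = sel$aic, trace = sel$trace,
                           n_evaluated = sel$n_evaluated),
                 rf = rf_out,
                 standardization = list(center = std$center,
                                        scale = std$scale,
                                        dropped = std$dropped),
                 seed = seed),
            class = "endoexo_fit")
}

#' @export
print.endoexo_fit <- function(x, ...) {
  cat(sprintf("endoexo fit: %s, generation %d (n = %d)\n",
              x$population, x$generation, x$n))
  sel <- x$table[!is.na(x$table$coefficient), ]
  if (nrow(sel)) {
    cat(sprintf("  %d of %d candidates selected, %d PLS component(s)\n",
                nrow(sel), length(x$candidates), x$n_components))
    for (i in seq_len(nrow(sel)))
      cat(sprintf("  %-10s %6.2f +/- %.3f %s\n", sel$variable[i],
                  sel$coefficient[i], sel$se[i], sel$stars[i]))
  } else cat("  intercept-only model (no predictors selected)\n")
  cat(sprintf("  adjusted R2 = %.2f", x$adj_r_squared))
  if (!is.null(x$rf)) cat(sprintf("  (RF OOB R2 = %.2f)", x$rf$oob_r2))
  cat("\n")
  invisible(x)
}

#' @export
print.endoexo_skip <- function(x, ...) {
  cat(sprintf("endoexo fit skipped: %s, generation %s -- %s\n",
              x$population, x$generation, x$reason))
  invisible(x)
}

## One bootstrap replicate: balanced resample, standardize, GA, PLS.
## Returns named coefficient vector over all candidates (NA = not selected).
boot_replicate <- function(X, y, pop_of, quota, ga, seed) {
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), pop_of),
                  function(i) sample(i, quota, replace = TRUE)),
           use.names = FALSE)
  })
  Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
  std <- standardize(Xb)
  ga$seed <- derive_seed(seed, "ga")
  sel <- ga_select(std$X, yb, ga)
  chosen <- names(sel$mask)[sel$mask]
  out <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  adj <- NA_real_
  if (length(chosen)) {
    Xsel <- std$X[, chosen, drop = FALSE]
    ncomp <- choose_components(Xsel, yb)
    fit <- pls_fit(Xsel, yb, ncomp)
    out[chosen] <- fit$coefficients
    n <- length(yb); k <- length(chosen)
    adj <- if (n - k - 1 > 0)
      1 - (1 - fit$r_squared) * (n - 1) / (n - k - 1) else NA_real_
  }
  list(coef = out, adj_r2 = adj, idx = idx)
}

#' Balanced-bootstrap fit for the pooled ("All") model
#'
#' When the populations contribute very different numbers of site-year rows,
#' a naive pooled fit is dominated by the oversampled ones. This fit draws
#' `B` stratified bootstrap replicates, each resampling the same `quota` of
#' rows (with replacement) from every population, and refits the
#' GA-selection + PLS pipeline on each. A variable is reported if it is
#' selected in at least half the replicates; its coefficient is the mean and
#' its standard error the standard deviation over the replicates that
#' selected it, with a normal-approximation two-sided p-value.
#'
#' @param dataset pooled `endoexo_dataset` whose `rows$population` labels at
#'   least two populations.
#' @param ga a [ga_config()].
#' @param B bootstrap replicates (a warning is issued below 20: the
#'   replicate SD is then an unstable SE estimate).
#' @param quota rows drawn per population; defaults to the smallest
#'   population's row count.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return an `endoexo_fit` with a `bootstrap` element (`B`, `quota`,
#'   per-variable selection frequency).
#' @export
bootstrap_balanced_fit <- function(dataset, ga = ga_config(), B = 50L,
                                   quota = NULL, seed = 1L) {
  X <- dataset$X; y <- dataset$y
  pop_of <- dataset$rows$population
  if (length(unique(pop_of)) < 2L)
    stop("balanced bootstrap needs at least 2 populations")
  if (B < 20L) warning("B < 20 bootstrap replicates: SEs will be unstable")
  quota <- quota %||% min(table(pop_of))
  reps <- lapply(seq_len(B), function(b)
    boot_replicate(X, y, pop_of, quota, ga, derive_seed(seed, "boot", b)))
  Cf <- do.call(rbind, lapply(reps, `[[`, "coef"))
  freq <- colMeans(!is.na(Cf))
  keep <- freq >= 0.5
  coef <- ifelse(keep, colMeans(Cf, na.rm = TRUE), NA_real_)
  se <- ifelse(keep, apply(Cf, 2, stats::sd, na.rm = TRUE), NA_real_)
  p <- 2 * stats::pnorm(-abs(coef / se))
  tab <- data.frame(variable = colnames(X), coefficient = unname(coef),
                    se = unname(se), p = unname(p),
                    stars = ifelse(keep, star_code(unname(p)), NA_character_))
  adj <- mean(vapply(reps, `[[`, numeric(1), "adj_r2"), na.rm = TRUE)
  structure(list(population = dataset$population,
                 generation = dataset$generation,
                 n = length(y),
                 candidates = colnames(X),
                 selected = colnames(X)[keep],
                 table = tab,
                 n_components = NA_integer_,
                 r_squared = NA_real_, adj_r_squared = adj,
                 ga = NULL, rf = NULL,
                 bootstrap = list(B = B, quota = quota,
                                  selection_freq = freq),
                 standardization = {
                   std <- standardize(X)
                   list(center = std$center, scale = std$scale,
                        dropped = std$dropped)
                 },
                 seed = seed),
            class = "endoexo_fit")
}
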