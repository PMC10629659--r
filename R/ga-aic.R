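## Genetic-algorithm subset selection scored by the AIC of an ordinary
## least-squares fit. The GA searches binary inclusion masks over the
## candidate predictors; only the AIC *ranking* at fixed n matters, so the
## additive constants in the AIC formula are immaterial.

#' AIC of an OLS fit on a predictor subset
#'
#' Fits ordinary least squares with intercept on the given columns and
#' returns `n * log(RSS / n) + 2 * (k + 2)`, counting the intercept, the k
#' slopes and the error variance as estimated parameters. Only differences
#' at fixed n are meaningful. A rank-deficient subset, or one with too few
#' residual degrees of freedom (`n <= k + 2`), scores `+Inf` so it can never
#' win the search.
#'
#' @param X numeric matrix (0 columns allowed: intercept-only model).
#' @param y numeric response.
#' @return scalar AIC.
#' @export
aic_of_subset <- function(X, y) {
  n <- length(y)
  k <- if (is.null(X)) 0L else ncol(X)
  if (n <= k + 2L) return(Inf)
  if (k == 0L) {
    rss <- sum((y - mean(y))^2)
  } else {
    fit <- stats::lm.fit(cbind(1, X), y)
    if (fit$rank < k + 1L) return(Inf)
    rss <- sum(fit$residuals^2)
  }
  rss <- max(rss, 1e-300)  # guard log(0) for exact fits
  n * log(rss / n) + 2 * (k + 2)
}

#' Genetic-algorithm configuration
#'
#' @param population_size number of candidate masks per generation (>= 2).
#' @param generations number of GA generations.
#' @param crossover_rate probability a child is produced by uniform
#'   crossover of two tournament-selected parents (else it copies one).
#' @param mutation_rate per-bit flip probability.
#' @param elitism_count best masks copied unchanged into the next generation.
#' @param seed optional integer seed for the GA's own RNG stream.
#' @export
ga_config <- function(population_size = 30L, generations = 40L,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      elitism_count = 2L, seed = NULL) {
  stopifnot(population_size >= 2L, generations >= 1L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism_count >= 0L, elitism_count < population_size)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = seed),
            class = "ga_config")
}

#' Select a predictor subset by genetic algorithm
#'
#' Evolves a population of binary inclusion masks over the columns of `X`,
#' scored by [aic_of_subset()]: tournament selection (size 2), uniform
#' crossover, per-bit mutation and elitism. The best AIC found is tracked
#' across generations and is non-increasing. Deterministic given
#' `config$seed`.
#'
#' @param X candidate predictor matrix (p >= 1 columns).
#' @param y response vector.
#' @param config a [ga_config()].
#' @param init optional logical matrix (`population_size` x p) of starting
#'   masks; defaults to random masks with inclusion probability 1/2.
#' @return list with `mask` (logical inclusion vector, named by column),
#'   `aic` (its AIC), `trace` (best AIC after each generation) and
#'   `n_evaluated` (distinct subsets scored).
#' @export
ga_select <- function(X, y, config = ga_config(), init = NULL) {
  p <- ncol(X)
  stopifnot(p >= 1L)
  run <- function() {
    np <- config$population_size
    pop <- init %||% matrix(stats::runif(np * p) < 0.5, np, p)
    stopifnot(nrow(pop) == np, ncol(pop) == p)
    cache <- new.env(parent = emptyenv())
    score <- function(mask) {
      keyv <- paste(which(mask), collapse = ",")
      key <- if (nzchar(keyv)) keyv else "0"
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      val <- aic_of_subset(X[, mask, drop = FALSE], y)
      cache[[key]] <- val
      val
    }
    fit <- apply(pop, 1, score)
    best_i <- which.min(fit)
    best_mask <- pop[best_i, ]
    best_aic <- fit[best_i]
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit)
      new_pop <- matrix(FALSE, np, p)
      ne <- config$elitism_count
      if (ne > 0L) new_pop[seq_len(ne), ] <- pop[ord[seq_len(ne)], ]
      tournament <- function() {
        ij <- sample.int(np, 2L)
        if (fit[ij[1]] <= fit[ij[2]]) pop[ij[1], ] else pop[ij[2], ]
      }
      for (i in seq.int(ne + 1L, np)) {
        child <- tournament()
        if (stats::runif(1) < config$crossover_rate) {
          other <- tournament()
          take <- stats::runif(p) < 0.5
          child[take] <- other[take]
        }
        flip <- stats::runif(p) < config$mutation_rate
        child[flip] <- !child[flip]
        new_pop[i, ] <- child
      }
      pop <- new_pop
      fit <- apply(pop, 1, score)
      gi <- which.min(fit)
      if (fit[gi] < best_aic) {
        best_aic <- fit[gi]
        best_mask <- pop[gi, ]
      }
      trace[g] <- best_aic
    }
    names(best_mask) <- colnames(X)
    list(mask = best_mask, aic = best_aic, trace = trace,
         n_evaluated = length(ls(cache)))
  }
  if (is.null(config$seed)) run() else with_seed(config$seed, run())
}

## Brute-force oracle: enumerate all 2^p subsets (p <= 20 guard).
exhaustive_select <- function(X, y) {
  p <- ncol(X)
  stopifnot(p <= 20L)
  best_aic <- Inf
  best_mask <- rep(FALSE, p)
  for (code in 0:(2^p - 1)) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(p - 1)), 1L))
    a <- aic_of_subset(X[, mask, drop = FALSE], y)
    if (a < best_aic) {
      best_aic <- a
      best_mask <- mask
    }
  }
  names(best_mask) <- colnames(X)
  list(mask = best_mask, aic = best_aic)
}
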