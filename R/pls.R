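## Partial least squares (PLS1, NIPALS) with leave-one-out machinery for
## component selection and jack-knife inference. With as many components as
## the (full-rank) predictor matrix has columns, the PLS solution coincides
## with ordinary least squares; with fewer, it regularizes towards the
## leading covariance directions, which is what makes it usable for
## collinear ecological covariates.

## Core NIPALS loop. Returns the coefficient path B (k x A): column a holds
## the coefficients using the first a latent components, on the scale of the
## supplied X. Deflation stops early if the X-residual no longer covaries
## with y; later columns of B then repeat the last attainable solution.
nipals_path <- function(X, y, ncomp) {
  n <- nrow(X); k <- ncol(X)
  xc <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xc); f <- y - ym
  A <- min(ncomp, k, n - 1L)
  W <- P <- matrix(0, k, A)
  q <- numeric(A)
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    P[, a] <- drop(crossprod(E, t)) / tt
    q[a] <- sum(f * t) / tt
    W[, a] <- w
    E <- E - tcrossprod(t, P[, a])
    f <- f - t * q[a]
    a_used <- a
  }
  B <- matrix(0, k, max(ncomp, 1L))
  if (a_used > 0L) {
    Wa <- W[, seq_len(a_used), drop = FALSE]
    Pa <- P[, seq_len(a_used), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))   # X-rotation: B_a = R[,1:a] q[1:a]
    for (a in seq_len(a_used))
      B[, a] <- R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]
    if (ncomp > a_used) for (a in seq.int(a_used + 1L, ncomp)) B[, a] <- B[, a_used]
  }
  rownames(B) <- colnames(X)
  list(B = B, x_center = xc, y_mean = ym, ncomp_used = a_used)
}

#' Fit a PLS1 regression
#'
#' NIPALS partial least squares of a single response on a predictor matrix,
#' using `n_components` latent components. Coefficients are reported on the
#' scale of the supplied predictors (standardize first for comparable
#' coefficients).
#'
#' @param X predictor matrix (columns named).
#' @param y numeric response; must not be constant.
#' @param n_components number of latent components,
#'   `1 <= n_components <= min(n - 1, ncol(X))`.
#' @return list with `coefficients` (named), `intercept`, `fitted`,
#'   `residuals`, `r_squared` and `ncomp` (components actually used; fewer
#'   than requested if the predictors run out of rank).
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  if (stats::sd(y) == 0) stop("response has zero variance")
  stopifnot(n_components >= 1L, n_components <= min(nrow(X) - 1L, ncol(X)))
  path <- nipals_path(X, y, n_components)
  b <- path$B[, n_components]
  intercept <- path$y_mean - sum(path$x_center * b)
  fitted <- drop(X %*% b) + intercept
  res <- y - fitted
  list(coefficients = stats::setNames(b, colnames(X)), intercept = intercept,
       fitted = fitted, residuals = res,
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       ncomp = min(n_components, path$ncomp_used))
}

#' Choose the number of PLS components by leave-one-out cross-validation
#'
#' Computes the LOO root-mean-squared error of prediction for
#' `1 ... min(n - 1, ncol(X), max_components)` components and returns the
#' fewest components whose RMSEP lies within `tol` (relative) of the
#' minimum, so that near-ties resolve toward parsimony (on a pure-noise
#' response this collapses to very few components).
#'
#' @param X predictor matrix; `y` response (n >= 4).
#' @param y numeric response.
#' @param max_components upper cap on the candidate component counts.
#' @param tol relative near-tie tolerance on the RMSEP minimum.
#' @return integer component count.
#' @export
choose_components <- function(X, y, max_components = 10L, tol = 0.02) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4L)
  A <- min(n - 2L, ncol(X), max_components)  # LOO fits have n - 1 rows
  press <- numeric(A)
  for (i in seq_len(n)) {
    path <- nipals_path(X[-i, , drop = FALSE], y[-i], A)
    pred <- drop(crossprod(path$B, X[i, ] - path$x_center)) + path$y_mean
    press <- press + (y[i] - pred)^2
  }
  rmsep <- sqrt(press / n)
  which(rmsep <= min(rmsep) * (1 + tol))[1]
}

#' Jack-knife standard errors and p-values for PLS coefficients
#'
#' Refits the PLS model leaving out each observation in turn and derives a
#' Tukey jack-knife standard error for every coefficient:
#' `SE_j = sqrt(((m - 1) / m) * sum_i (b_(-i)j - mean(b_(.)j))^2)` with
#' `m = n` leave-one-out segments. Two-sided p-values use a t reference
#' distribution with `m - 1` degrees of freedom on `t = b_full / SE`.
#' Significance stars follow the conventional thresholds: `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param X predictor matrix (n >= 5 rows); `y` response.
#' @param y numeric response.
#' @param n_components latent components, held fixed across refits.
#' @return data.frame with `variable, coefficient, se, t, p, stars`.
#' @export
jackknife_inference <- function(X, y, n_components) {
  X <- as.matrix(X)
  m <- nrow(X)
  stopifnot(m >= 5L)
  full <- pls_fit(X, y, n_components)
  b_full <- full$coefficients
  Bi <- matrix(0, m, ncol(X))
  for (i in seq_len(m)) {
    path <- nipals_path(X[-i, , drop = FALSE], y[-i], n_components)
    Bi[i, ] <- path$B[, n_components]
  }
  bbar <- colMeans(Bi)
  se <- sqrt((m - 1) / m * colSums(sweep(Bi, 2, bbar)^2))
  tval <- b_full / se
  p <- 2 * stats::pt(-abs(tval), df = m - 1)
  zero <- se < 1e-10 * pmax(1, abs(b_full))  # numerically stable coefficient
  if (any(zero)) {
    warning("jack-knife SE of 0 for: ",
            paste(names(b_full)[zero], collapse = ", "),
            "; p reported as 0")
    p[zero] <- 0
  }
  data.frame(variable = names(b_full), coefficient = unname(b_full),
             se = unname(se), t = unname(tval), p = unname(p),
             stars = star_code(unname(p)), row.names = NULL)
}

star_code <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "ns")))
}
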