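#' Standardize a design matrix
#'
#' Columnwise z-scores using the sample standard deviation (n - 1
#' denominator). Constant columns cannot be standardized; they are dropped
#' with a warning and recorded so reports can show them as removed.
#'
#' @param X numeric matrix with column names.
#' @return list with `X` (standardized matrix), `center`, `scale` (named,
#'   for the retained columns) and `dropped` (labels of constant columns).
#' @export
standardize <- function(X) {
  if (nrow(X) < 3L) stop("standardize needs at least 3 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  const <- scl == 0 | !is.finite(scl)
  if (all(const)) stop("all columns are constant; nothing to standardize")
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
  }
  keep <- !const
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  list(X = Xs, center = ctr[keep], scale = scl[keep],
       dropped = colnames(X)[const])
}

## Inverse of standardize() for round-trip checks.
unstandardize <- function(std) {
  sweep(sweep(std$X, 2, std$scale, "*"), 2, std$center, "+")
}
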