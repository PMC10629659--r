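#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic fan-out of a master seed into per-stage seeds.
## Keeps every derived seed strictly below 2^31.
derive_seed <- function(master, ..., salt = 0L) {
  parts <- c(as.numeric(master), as.numeric(salt),
             vapply(list(...), function(x) {
               if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
               else as.numeric(x)
             }, numeric(1)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Structured INFO logging; quiet by default in tests.
ee_log <- function(..., verbose = getOption("endoexo.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[endoexo] ", sprintf(...))
  invisible(NULL)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
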