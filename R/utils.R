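# Internal helpers shared across modules.

# Round half away from zero at `digits` decimals (printed-precision rounding;
# base round() is banker's rounding, which would turn 0.5% steps unstably).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# z-score the columns of a numeric matrix, dropping zero-variance columns
# with a warning. Returns the scaled matrix (attributes stripped).
zscore_columns <- function(x, warn = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  v <- apply(x, 2, sd)
  constant <- !is.finite(v) | v == 0
  if (any(constant)) {
    if (warn) {
      warning(sprintf("dropping %d constant feature(s): %s",
                      sum(constant),
                      paste(head(colnames(x)[constant], 5), collapse = ", ")),
              call. = FALSE)
    }
    x <- x[, !constant, drop = FALSE]
    v <- v[!constant]
  }
  if (ncol(x) == 0L) stop("no non-constant features left after filtering")
  sweep(sweep(x, 2, colMeans(x), "-"), 2, v, "/")
}

# Validate that `x` is a single finite number, optionally positive.
check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` with the RNG seeded, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
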