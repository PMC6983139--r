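# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses (and advances) the
# current RNG state, matching base R conventions for simulation functions.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a user seed. Keeps all seeds
# well inside 32-bit integer range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + k * 1117) %% 2147483587 + 1
}

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
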