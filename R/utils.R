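# Internal helpers shared across modules.

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stream label; keeps results
# independent across pipeline stages while remaining a function of one seed.
# Stays below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s.", name, format(min)))
  }
  invisible(x)
}

# named numeric vector -> one-row tibble-friendly list column helper
compact_named <- function(x) x[x != 0]
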