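# RNG discipline: all randomness flows from one top-level seed through named
# substreams so that, e.g., changing the noise draw cannot perturb geometry.

# Deterministic 32-bit sub-seed from a base seed and a stream name.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Clamp numeric vector to [lo, hi]; NULL bound means unbounded.
clamp <- function(x, lo = NULL, hi = NULL) {
  if (!is.null(lo)) x <- pmax(x, lo)
  if (!is.null(hi)) x <- pmin(x, hi)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
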