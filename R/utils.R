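# Internal helpers: seed management and small validators.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never disturbs user-level randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and integer offsets.  Uses a fixed
# affine recurrence mod (2^31 - 1) so streams are stable: adding subjects or
# repetitions never perturbs the seeds of earlier ones.
derive_seed <- function(seed, ...) {
  off <- as.double(c(...))
  s <- as.double(seed) %% 2147483647
  for (k in seq_along(off)) {
    s <- (s * 69069 + off[k] * 1000003 + 12345) %% 2147483647
  }
  as.integer(s)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
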