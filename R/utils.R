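# Internal helpers shared across modules.

# Run `code` under a temporary R RNG state seeded with `seed`, restoring the
# caller's state afterwards so library randomness never leaks into user code.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
sub_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 13L + 7919L * as.integer(stream) %% 2147480000L
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("%s must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
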