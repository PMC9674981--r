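# session-level cache (memoized E^2 spline, Gauss-Hermite nodes)
.vs_cache <- new.env(parent = emptyenv())

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. With seed = NULL the current stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-stream seed; keeps results below 2^31
sub_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 69069 + offset) %% 2147483647)
}
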