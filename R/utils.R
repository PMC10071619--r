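# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible 31-bit sub-seed from a master seed and a stream
# name, so independent stages (and independent subjects within a stage)
# consume independent, individually addressable random substreams.
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1, is.finite(seed))
  h <- 0
  for (b in utf8ToInt(paste0(name, ":", as.integer(seed)))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded from (seed, name) without disturbing
# the caller's RNG state.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

stop_if_not_count <- function(x, what) {
  if (length(x) != 1 || !is.finite(x) || x <= 0 || x != round(x))
    stop(what, " must be a positive integer, got ", deparse(x))
  invisible(as.integer(x))
}
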