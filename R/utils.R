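# Internal helpers shared across modules.

# Run code with a temporary RNG state seeded at `seed`, restoring the caller's
# stream afterwards so simulators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable per-subject stream: a fixed integer hash of (master seed, id, stream).
# Kept below 2^31 - 1 so it is always a valid set.seed() argument.
subject_seed <- function(seed, id, stream = 0L) {
  m <- 2147483647
  h <- (as.double(seed) %% m) * 2654435 + as.double(id) * 9973 + as.double(stream) * 7919
  as.integer(h %% m)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_binary <- function(x) {
  x <- x[!is.na(x)]
  is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
}
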