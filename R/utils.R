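# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's .Random.seed is restored afterwards.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic derived seeds, kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in seq_along(parts)) {
    s <- (s * 48271 + as.double(parts[i]) * 16807 + i) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
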