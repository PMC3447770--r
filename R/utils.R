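# Internal helpers: seeding, clipping.

# Derive a child seed from a base seed and one or more integer salts.
# Keeps results in [1, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(base, ...) {
  salts <- c(...)
  x <- as.double(base) %% 2147483647
  for (s in salts) {
    x <- (x * 48271 + as.double(s) * 16807 + 12345) %% 2147483647
  }
  as.integer(x %/% 1 + 1)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
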