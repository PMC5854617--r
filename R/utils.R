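# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results in 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k) * 97 + 1) %%
               .Machine$integer.max)
}

is_binary_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
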