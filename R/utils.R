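# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic stream of derived seeds, kept within 32-bit integer range.
# Multiplicative congruential step per index; collision-free in practice for
# the grid sizes used here.
derive_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  for (i in seq_len(2)) {
    s <- (s * 48271 + as.numeric(index) * 2654435761) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
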