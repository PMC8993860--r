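# RNG scoping: run `expr` under a given seed without disturbing the caller's
# RNG stream. Mersenne-Twister throughout for cross-platform reproducibility.
local_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  expr
}

# Spawn n child seeds from one master seed (documented scheme: a single
# sample.int draw under the master seed). Keeps every seed in 1..2^31-2.
spawn_seeds <- function(master_seed, n) {
  local_rng(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
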