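# Evaluate `code` in the caller's frame under a temporary RNG seed, restoring
# the caller's RNG state afterwards. Keeps package randomness from disturbing
# the user's stream and makes every generator reproducible in isolation.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(code))
}

# Deterministic per-item sub-seed derived from (seed, index); kept well below
# .Machine$integer.max.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483123)
}
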