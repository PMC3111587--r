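# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Weighted categorical draw over a named probability vector.
draw1 <- function(probs) {
  sample(names(probs), 1L, prob = probs)
}

normalize_probs <- function(w) {
  stopifnot(all(w >= 0), sum(w) > 0)
  w / sum(w)
}
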