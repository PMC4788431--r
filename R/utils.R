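# Internal helpers.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream; with seed = NULL the current stream is used as-is.
with_preserved_rng <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  code
}

# Derive a stream of per-run seeds from a base seed, kept within 32-bit range.
derive_seeds <- function(base_seed, n, stream = 0L) {
  (as.numeric(base_seed) * 2654435761 + stream * 97003 + seq_len(n)) %%
    .Machine$integer.max
}
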