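# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive n independent sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Canonical string key of a pitch-set state, e.g. "60+64+67".
state_key <- function(pitches) {
  paste(sort(unique(as.integer(pitches))), collapse = "+")
}

key_pitches <- function(key) {
  as.integer(strsplit(key, "+", fixed = TRUE)[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
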