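# Internal helpers: seeded RNG scoping and deterministic string hashing.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic polynomial hash of a string to [0, 2^31 - 1].
# Platform-independent: depends only on the character codes.
str_hash <- function(s, mod = 2147483647) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% mod
  h
}

# Combine a base seed with a string key into a derived seed < 2^31.
derive_seed <- function(seed, key) {
  as.integer((as.numeric(seed) * 1000003 + str_hash(key)) %% 2147483647)
}

stop_if_not_ids <- function(ids, what = "entity ids") {
  if (anyDuplicated(ids))
    stop(sprintf("duplicate %s: %s", what,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
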