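# Internal helpers: seed management shared by every stochastic stage.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. A NULL seed runs in the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stage sub-seed from one global seed, kept inside the
# 32-bit integer range. Distinct stage names give distinct streams.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
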