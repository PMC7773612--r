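# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child-seed derivation: master seed plus a stage offset mapped
# through a large prime, kept inside the 32-bit integer range.
deriveSeed <- function(master, offset) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(offset)) %%
               2147483647)
}

# round-half-up (base round() is banker's and 0.9*115 is not exact in binary)
roundHalfUp <- function(x) floor(x + 0.5 + 1e-9)

# sample() without the length-1 surprise
sampleInt <- function(x, size) x[sample.int(length(x), size)]
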