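# fixtures shared across test files; everything is generated in code

toySet <- function(values, wl = NULL, ...) {
  values <- as.matrix(values)
  if (is.null(wl)) wl <- seq(1000, by = 6.55, length.out = ncol(values))
  SpectraSet(values, wl, ...)
}

# a small noisy random spectra set on an arbitrary axis
randomSet <- function(n = 6, p = 30, seed = 99) {
  set.seed(seed)
  toySet(matrix(rnorm(n * p, mean = 1, sd = 0.3), n, p))
}

# the three retained wavelength intervals used throughout
paperRanges <- function() list(c(1060, 1172), c(1211, 1366), c(1560, 1840))

# fraction of a selection result falling in / out of the informative block
recoveryStats <- function(selected, info, p) {
  dead <- setdiff(seq_len(p), info)
  c(info = mean(info %in% selected), dead = mean(dead %in% selected))
}
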