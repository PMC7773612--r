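test_that("cropping keeps exactly the channels inside closed intervals", {
  axis <- defaultWavelengthAxis()
  s <- toySet(matrix(rnorm(3 * length(axis)), 3), wl = axis)
  c1 <- cropRanges(s, list(c(1060, 1172)))
  expect_true(all(wavelengths(c1) >= 1060 & wavelengths(c1) <= 1172))
  # brute-force per-channel membership oracle over the three study ranges
  rngs <- paperRanges()
  keep <- vapply(axis, function(wl)
    any(vapply(rngs, function(r) wl >= r[1] && wl <= r[2], logical(1))),
    logical(1))
  c3 <- cropRanges(s, rngs)
  expect_equal(nChannels(c3), sum(keep))
  expect_equal(wavelengths(c3), axis[keep])
  expect_equal(max(segmentIds(c3)), 3)
  # full-axis range is the identity
  cf <- cropRanges(s, list(range(axis)))
  expect_equal(spectraValues(cf), spectraValues(s))
  expect_error(cropRanges(s, list(c(1, 2))), "every channel")
})

test_that("snv centres to mean 0 / sample sd 1 and is affine invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(50, sd = runif(1, 0.1, 5))
    z <- snv(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(snv(a * x + b), z, tolerance = 1e-10)
  }
  expect_error(snv(rep(2, 10)), "zero spread")
  expect_error(snv(1), "2 channels")
})

test_that("rnv is affine invariant, robust to spikes, and affine to snv", {
  set.seed(9)
  x <- rnorm(60)
  z <- rnv(x)
  expect_equal(rnv(3.1 * x + 0.7), z, tolerance = 1e-10)
  # a large spike shifts the RNV centring far less than the SNV centring
  xs <- x; xs[5] <- 50
  shift_rnv <- abs(median(rnv(xs)[-5] - rnv(x)[-5]))
  shift_snv <- abs(median(snv(xs)[-5] - snv(x)[-5]))
  expect_lt(shift_rnv, shift_snv / 3)
  # both are affine in x, so they agree up to a fixed affine map
  fit <- lm(rnv(x) ~ snv(x))
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_error(rnv(c(1, 2, 3)), "4 channels")
})

test_that("msc removes exact multiplicative/additive scatter", {
  set.seed(10)
  ref <- abs(rnorm(40, mean = 1))
  gains <- c(0.5, 1.2, 2, 0.8)
  offs <- c(-0.2, 0.1, 0.3, 0)
  v <- t(vapply(1:4, function(i) gains[i] * ref + offs[i], numeric(40)))
  s <- toySet(v)
  corr <- msc(s, reference = ref)
  for (i in 1:4)
    expect_equal(spectraValues(corr)[i, ], ref, tolerance = 1e-10)
  # a row used as explicit reference maps to itself
  corr2 <- msc(s, reference = v[2, ])
  expect_equal(spectraValues(corr2)[2, ], v[2, ], tolerance = 1e-12)
})

test_that("msc equals a per-row two-parameter regression oracle", {
  s <- randomSet(5, 25)
  corr <- msc(s)
  ref <- attr(corr, "mscReference")
  expect_equal(ref, colMeans(spectraValues(s)))
  for (i in 1:5) {
    x <- spectraValues(s)[i, ]
    co <- coef(lm(x ~ ref))
    expect_equal(spectraValues(corr)[i, ], (x - co[[1]]) / co[[2]],
                 tolerance = 1e-10)
  }
  flat <- toySet(rbind(rep(1, 10), rnorm(10)))
  expect_error(msc(flat, reference = rnorm(10)), "flat fit")
})

test_that("savitzky-golay reproduces polynomials and their derivatives", {
  wl <- seq(1000, 1300, by = 6.55)
  lam <- wl - 1150
  a <- 2; b <- 0.05; cc <- 3e-4; d <- -2e-6
  cubic <- a + b * lam + cc * lam^2 + d * lam^3
  s <- toySet(rbind(cubic), wl = wl)
  # smoothing (deriv 0) with poly 3 reproduces the cubic everywhere
  sm <- savitzkyGolay(s, 7, 3, 0)
  expect_equal(spectraValues(sm)[1, ], cubic, tolerance = 1e-9)
  # first and second analytic derivatives, interior points
  d1 <- savitzkyGolay(s, 7, 3, 1)
  d2 <- savitzkyGolay(s, 7, 3, 2)
  inner <- 4:(length(wl) - 3)
  expect_equal(spectraValues(d1)[1, inner],
               (b + 2 * cc * lam + 3 * d * lam^2)[inner], tolerance = 1e-8)
  expect_equal(spectraValues(d2)[1, inner],
               (2 * cc + 6 * d * lam)[inner], tolerance = 1e-8)
  # quadratic with window 5 / poly 2 / deriv 1
  quad <- 1 + 0.02 * lam + 1e-4 * lam^2
  sq <- toySet(rbind(quad), wl = wl)
  dq <- savitzkyGolay(sq, 5, 2, 1)
  inner5 <- 3:(length(wl) - 2)
  expect_equal(spectraValues(dq)[1, inner5],
               (0.02 + 2e-4 * lam)[inner5], tolerance = 1e-9)
  # constants are unchanged under any deriv-0 config
  cs <- toySet(rbind(rep(4, 40)), wl = seq(1000, by = 5, length.out = 40))
  expect_equal(spectraValues(savitzkyGolay(cs, 17, 2, 0))[1, ], rep(4, 40))
})

test_that("savitzky-golay is linear and respects segment boundaries", {
  set.seed(11)
  wl <- seq(1000, 2500, by = 6.55)
  x <- rnorm(length(wl)); y <- rnorm(length(wl))
  sx <- toySet(rbind(x), wl = wl); sy <- toySet(rbind(y), wl = wl)
  sxy <- toySet(rbind(2 * x - 3 * y), wl = wl)
  f <- function(s) spectraValues(savitzkyGolay(s, 9, 2, 1))[1, ]
  expect_equal(f(sxy), 2 * f(sx) - 3 * f(sy), tolerance = 1e-10)

  # filtering cropped segments never mixes channels across the gap
  s2 <- toySet(rbind(x, y), wl = wl)
  cropped <- cropRanges(s2, paperRanges())
  filt <- savitzkyGolay(cropped, 9, 2, 0)
  seg <- segmentIds(cropped)
  for (sg in unique(seg)) {
    idx <- which(seg == sg)
    solo <- toySet(spectraValues(cropped)[, idx, drop = FALSE],
                   wl = wavelengths(cropped)[idx])
    expect_equal(spectraValues(filt)[, idx],
                 spectraValues(savitzkyGolay(solo, 9, 2, 0)),
                 tolerance = 1e-12)
  }
  expect_error(savitzkyGolay(cropped, 19, 2, 0), "segment")
})

test_that("the configuration enumerator matches the combinatorial counts", {
  # 3 candidate ranges -> 7 non-empty subsets
  one <- enumerateConfigs(scatter = "none", windows = 5, polyorders = 2,
                          derivs = 0)
  expect_length(one, 7)
  # SG grid 8 windows x 2 polys x 3 derivs -> 48 valid triples (brute force)
  grid <- expand.grid(w = seq(5, 19, 2), p = 2:3, d = 0:2)
  nValid <- sum(grid$p < grid$w & grid$d <= grid$p)
  expect_equal(nValid, 48)
  sgOnly <- enumerateConfigs(ranges = list(c(1060, 1172)), scatter = "none")
  expect_length(sgOnly, nValid)
  # full study grid: 7 x 4 x 48
  full <- enumerateConfigs()
  expect_length(full, 7 * 4 * 48)
  # deterministic ordering
  full2 <- enumerateConfigs()
  expect_identical(vapply(full, menirmap:::configLabel, character(1)),
                   vapply(full2, menirmap:::configLabel, character(1)))
})

test_that("configs serialize to lists and back bit-exactly", {
  cfg <- preprocessConfig(paperRanges(), "rnv", 17, 3, 2, rnvPercentile = 30)
  l <- configToList(cfg)
  expect_equal(l$sg$window, 17L)
  back <- configFromList(l)
  expect_equal(back@ranges, cfg@ranges)
  expect_identical(back@scatter, cfg@scatter)
  expect_identical(back@sgWindow, cfg@sgWindow)
  expect_equal(back@rnvPercentile, 30)
  # through YAML text as well
  y <- yaml::yaml.load(yaml::as.yaml(l))
  expect_equal(configFromList(y)@ranges, cfg@ranges)
})

test_that("invalid configurations are rejected by validity checks", {
  expect_error(preprocessConfig(list(c(1060, 1172)), sgWindow = 6), "odd")
  expect_error(preprocessConfig(list(c(1060, 1172)), sgWindow = 5,
                                sgPolyOrder = 5), "2 or 3")
  expect_error(preprocessConfig(list(c(1060, 1172)), sgPolyOrder = 2,
                                sgDeriv = 3), "0, 1 or 2")
  expect_error(preprocessConfig(list(c(1200, 1100))), "low < high")
  expect_error(preprocessConfig(list(c(1000, 1200), c(1100, 1300))),
               "overlap")
})

test_that("the pipeline applies crop, scatter and SG in order", {
  sp <- phantomSpec(noiseSd = 0)
  ds <- generateDataset(sp, 8, c(2, 2), 4, seed = 3)
  s <- averageReplicates(ds$train)
  cfg <- preprocessConfig(paperRanges(), "snv", 5, 2, 0)
  manual <- savitzkyGolay(scatterCorrect(cropRanges(s, paperRanges()), "snv"),
                          5, 2, 0)
  expect_equal(spectraValues(applyPipeline(s, cfg)), spectraValues(manual))
  # a config whose range misses the axis propagates the crop error
  bad <- preprocessConfig(list(c(5000, 6000)), "none", 5, 2, 0)
  expect_error(applyPipeline(s, bad), "every channel")
  # scatter 'none', deriv 0 on a smooth cubic segment is crop-only up to the
  # SG smoothing residual of a local polynomial fit
  wl <- seq(1000, 1300, by = 6.55)
  lam <- wl - 1150
  cub <- toySet(rbind(1 + 0.01 * lam + 1e-5 * lam^2 + 1e-8 * lam^3), wl = wl)
  cfg2 <- preprocessConfig(list(c(1000, 1300)), "none", 5, 2, 0)
  out <- applyPipeline(cub, cfg2)
  expect_equal(spectraValues(out), spectraValues(cub), tolerance = 1e-6)
})

test_that("msc reference from training is reused for test spectra", {
  sp <- phantomSpec()
  ds <- generateDataset(sp, 10, c(2, 3), 6, seed = 6)
  tr <- averageReplicates(ds$train)
  cfg <- preprocessConfig(paperRanges(), "msc", 5, 2, 0)
  ref <- pipelineReference(tr, cfg)
  expect_equal(ref, colMeans(spectraValues(cropRanges(tr, cfg@ranges))))
  te <- applyPipeline(ds$test, cfg, reference = ref)
  # correcting a single test spectrum against the stored reference matches
  # msc() with that explicit reference
  teCrop <- cropRanges(ds$test, cfg@ranges)
  manual <- savitzkyGolay(msc(teCrop, reference = ref), 5, 2, 0)
  expect_equal(spectraValues(te), spectraValues(manual))
})
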