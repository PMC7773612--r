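test_that("a single deterministic split reduces MCCV to one hold-out RMSE", {
  set.seed(31)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  cv <- mccv(X, y, 3, iterations = 1, trainRatio = 0.8, seed = 42)
  # replay the same split by hand
  seedUsed <- 42L
  sp <- withr::with_seed(seedUsed, sample.int(20, 16))
  va <- setdiff(1:20, sp)
  manual <- vapply(1:3, function(k) {
    fit <- fitNipals(X[sp, ], y[sp], k)
    rmse(y[va], predict(fit, X[va, , drop = FALSE]))
  }, numeric(1))
  expect_equal(cv@meanRmsecv, manual, tolerance = 1e-12)
})

test_that("mccv is seed-deterministic and chooses the curve minimum", {
  set.seed(32)
  X <- matrix(rnorm(400), 40, 10)
  y <- X %*% rnorm(10) + rnorm(40)
  cv1 <- mccv(X, y, 6, iterations = 25, seed = 7)
  cv2 <- mccv(X, y, 6, iterations = 25, seed = 7)
  expect_identical(rmsecvCurve(cv1), rmsecvCurve(cv2))
  expect_identical(chosenComponents(cv1), chosenComponents(cv2))
  m <- cv1@meanRmsecv
  expect_true(all(m[chosenComponents(cv1)] <= m))
  expect_error(mccv(X, y, 39, iterations = 5), "too small")
})

test_that("mccv uses round-half-up subset sizes (90% of 115 is 104)", {
  expect_equal(menirmap:::roundHalfUp(0.9 * 115), 104)
  expect_equal(menirmap:::roundHalfUp(0.75 * 115), 86)
})

test_that("component count recovers the phantom rank on noise-free data", {
  sp <- phantomSpec(gainSd = 0, offsetSd = 0, slopeSd = 0, noiseSd = 0)
  hits <- 0
  for (s in 1:3) {
    ds <- generateDataset(sp, 40, c(3, 3), 9, seed = s)
    X <- spectraValues(averageReplicates(ds$train))
    cv <- mccv(X, ds$trainRef$water, 8, iterations = 40, seed = s)
    hits <- hits + (chosenComponents(cv) == 3)
  }
  expect_gte(hits, 2)
})

test_that("monte carlo sd of the cv error shrinks like one over sqrt(n)", {
  sp <- phantomSpec()
  ds <- generateDataset(sp, 40, c(2, 2), 4, seed = 4)
  X <- spectraValues(averageReplicates(ds$train))
  y <- ds$trainRef$water
  sdAt <- function(iters) {
    reps <- vapply(1:8, function(r) {
      cv <- mccv(X, y, 3, iterations = iters, seed = 100 * r)
      min(cv@meanRmsecv)
    }, numeric(1))
    sd(reps)
  }
  s100 <- sdAt(100)
  s400 <- sdAt(400)
  ratio <- s100 / s400   # expected ~ sqrt(400/100) = 2
  expect_gt(ratio, 1)
  expect_lt(ratio, 4)
})

test_that("outlier screening flags planted outliers but not clean samples", {
  sp <- phantomSpec()
  ds <- generateDataset(sp, 60, c(2, 2), 4, seed = 11)
  avg <- averageReplicates(ds$train)
  cfg <- preprocessConfig(paperRanges(), "snv", 11, 2, 0)
  X <- spectraValues(applyPipeline(avg, cfg))
  y <- ds$trainRef$water
  clean <- detectOutliers(X, y, 4, iterations = 150, seed = 1,
                          sampleIds = sampleIds(avg))
  expect_lte(length(flaggedSamples(clean)), 1)
  y2 <- y
  y2[7] <- y2[7] + 10 * diff(range(y))
  bad <- detectOutliers(X, y2, 4, iterations = 150, seed = 1,
                        sampleIds = sampleIds(avg))
  expect_true(sampleIds(avg)[7] %in% flaggedSamples(bad))
  # kSd = Inf disables flagging entirely
  none <- detectOutliers(X, y2, 4, iterations = 150, seed = 1, kSd = Inf)
  expect_length(flaggedSamples(none), 0)
  # determinism and the always-complete table
  clean2 <- detectOutliers(X, y, 4, iterations = 150, seed = 1,
                           sampleIds = sampleIds(avg))
  expect_identical(outlierTable(clean), outlierTable(clean2))
  expect_equal(nrow(outlierTable(clean)), 60)
})

test_that("grid search ranks configurations and survives failures", {
  sp <- phantomSpec(noiseSd = 5e-4)
  ds <- generateDataset(sp, 30, c(2, 2), 4, seed = 13)
  avg <- averageReplicates(ds$train)
  idc <- preprocessConfig(list(range(defaultWavelengthAxis())), "none", 5, 2, 0)
  one <- gridSearch(avg, ds$trainRef, list(idc), "water", maxComp = 5,
                    iterations = 10, seed = 1)
  expect_equal(nrow(one$ranking), 1)
  expect_equal(one$ranking$rank, 1)

  # two identical configs keep their serialization order on the tie
  two <- gridSearch(avg, ds$trainRef, list(idc, idc), "water", maxComp = 5,
                    iterations = 10, seed = 1)
  expect_equal(two$ranking$index, c(1, 2))

  # a config whose SG window exceeds a cropped segment fails but does not
  # abort the search
  narrow <- preprocessConfig(list(c(1060, 1080)), "none", 19, 2, 0)
  mix <- gridSearch(avg, ds$trainRef, list(narrow, idc), "water",
                    maxComp = 5, iterations = 10, seed = 1)
  expect_equal(sum(mix$ranking$status == "ok"), 1)
  expect_match(mix$ranking$status[2], "failed")
  expect_error(gridSearch(avg, ds$trainRef, list(), "water"), "non-empty")
})

test_that("grid search recovers the wavelength region carrying the signal", {
  # phantom whose bands live only inside 1560-1840 nm
  bands <- list(water = rbind(componentBand(1650, 40, 0.012),
                              componentBand(1760, 50, 0.006)),
                uronic_acid = rbind(componentBand(1600, 30, 0.5)),
                hydroxyproline = rbind(componentBand(1700, 35, 0.015)))
  hits <- 0
  for (s in 1:3) {
    sp <- phantomSpec(bands = bands, residualBands = NULL, noiseSd = 1e-3)
    ds <- generateDataset(sp, 40, c(2, 2), 4, seed = 20 + s)
    avg <- averageReplicates(ds$train)
    cfgs <- lapply(paperRanges(), function(r)
      preprocessConfig(list(r), "none", 5, 2, 0))
    gs <- gridSearch(avg, ds$trainRef, cfgs, "water", maxComp = 5,
                     iterations = 15, seed = s)
    if (gs$best@ranges[1, 1] == 1560) hits <- hits + 1
  }
  expect_gte(hits, 2)
})
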