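# light per-method checks; the full five-seed recovery benchmark lives in
# test-acceptance.R

test_that("the cars retention schedule matches its closed form", {
  N <- 50; p <- 200
  r <- carsSchedule(N, p)
  k <- log(p / 2) / (N - 1)
  a <- exp(k)
  expect_equal(r, a * exp(-k * (1:N)), tolerance = 1e-12)
  expect_equal(r[1], 1)                      # first iteration keeps all
  expect_equal(round(r[N] * p), 2)           # last keeps two channels
  expect_true(all(diff(r) < 0))
})

test_that("stochastic selectors are bit-reproducible under a fixed seed", {
  d <- generatePlantedChannels(n = 60, p = 40, info = 11:18, seed = 5)
  for (m in c("uve", "cars", "frog", "iriv")) {
    r1 <- menirmap:::runSelector(m, d$X, d$y, 5, 77,
                                 args = list(iterations = 20)[m != "iriv"])
    r2 <- menirmap:::runSelector(m, d$X, d$y, 5, 77,
                                 args = list(iterations = 20)[m != "iriv"])
    expect_identical(selectedChannels(r1), selectedChannels(r2))
    expect_identical(selectionScore(r1), selectionScore(r2))
  }
})

test_that("frog selection probabilities account for the visited subsets", {
  d <- generatePlantedChannels(n = 50, p = 30, info = 11:16, seed = 2)
  fr <- randomFrog(d$X, d$y, 4, iterations = 200, initSize = 8, seed = 3)
  expect_equal(sum(selectionScore(fr)),
               fr@hyperparameters$meanSubsetSize, tolerance = 1e-10)
  expect_true(all(selectionScore(fr) >= 0 & selectionScore(fr) <= 1))
})

test_that("mwpls profile has the expected length and degenerate behaviour", {
  d <- generatePlantedChannels(n = 60, p = 40, info = 15:24, seed = 4)
  mw <- mwpls(d$X, d$y, 4, window = 11, cvIterations = 4, seed = 1)
  expect_length(selectionScore(mw), 40 - 11 + 1)
  expect_length(selectedChannels(mw), 11)
  # window = n_channels reduces to the base model over all channels
  full <- mwpls(d$X, d$y, 4, window = 40, cvIterations = 4, seed = 1)
  expect_identical(selectedChannels(full), 1:40)
  expect_error(mwpls(d$X, d$y, 4, window = 41), "exceeds")
  expect_error(mwpls(d$X, d$y, 10, window = 5), "nComp \\+ 1")
})

test_that("uve recovers a planted signal in a single-seed smoke run", {
  d <- generatePlantedChannels(n = 100, p = 80, info = 31:40, seed = 6)
  u <- uve(d$X, d$y, 8, iterations = 60, seed = 6)
  st <- recoveryStats(selectedChannels(u), d$info, 80)
  expect_gte(st[["info"]], 0.7)
  expect_lte(st[["dead"]], 0.15)
  # a response independent of X selects (almost) nothing
  yNull <- withr::with_seed(1, rnorm(100))
  u0 <- uve(d$X, yNull, 8, iterations = 60, seed = 6)
  expect_lte(length(selectedChannels(u0)), 0.05 * 80)
})

test_that("iriv terminates, shrinks monotonically, and reports diagnostics", {
  d <- generatePlantedChannels(n = 60, p = 24, info = 9:14, seed = 8)
  ir <- iriv(d$X, d$y, 5, nRows = 32, cvIterations = 3, maxRounds = 4,
             seed = 8)
  sel <- selectedChannels(ir)
  expect_true(all(sel %in% 1:24))
  expect_lte(ir@hyperparameters$rounds, 5)
  expect_error(iriv(d$X[, 1:3], d$y, 2), "at least 4")
})

test_that("compareMethods builds the comparison table schema", {
  d <- generatePlantedChannels(n = 70, p = 30, info = 11:18, seed = 9)
  idx <- 1:50
  tst <- 51:70
  # empty method list: Base row only
  t0 <- compareMethods(d$X[idx, ], d$y[idx], d$X[tst, ], d$y[tst],
                       methods = character(0), maxComp = 6,
                       cvIterations = 10, seed = 1)
  expect_equal(t0$method, "Base")
  expect_true(t0$best)
  expect_named(t0, c("method", "rho_training", "rmsec", "rmsecv", "rho_test",
                     "rmsep", "n_comp", "n_channels", "status", "best"))
  # with methods: one extra row each, best flagged at minimum RMSEP
  tb <- compareMethods(d$X[idx, ], d$y[idx], d$X[tst, ], d$y[tst],
                       methods = c("uve", "mwpls"), maxComp = 6,
                       cvIterations = 10, seed = 1,
                       methodArgs = list(uve = list(iterations = 30),
                                         mwpls = list(window = 9,
                                                      cvIterations = 4)))
  expect_equal(nrow(tb), 3)
  expect_equal(sum(tb$best), 1)
  okRmsep <- tb$rmsep[tb$status == "ok"]
  expect_equal(tb$rmsep[tb$best], min(okRmsep))
  expect_true(all(tb$rmsep[tb$status == "ok"] >= 0))
})

test_that("a failing method is recorded without aborting the comparison", {
  d <- generatePlantedChannels(n = 40, p = 20, info = 6:10, seed = 10)
  tb <- compareMethods(d$X[1:30, ], d$y[1:30], d$X[31:40, ], d$y[31:40],
                       methods = "mwpls", maxComp = 4, cvIterations = 8,
                       seed = 2,
                       methodArgs = list(mwpls = list(window = 50)))
  expect_match(tb$status[tb$method == "MWPLS"], "failed")
  expect_equal(tb$status[tb$method == "Base"], "ok")
})

test_that("null responses never let selection beat the base model clearly", {
  # permuted response: selected subsets cannot outperform the full model by
  # more than Monte Carlo noise
  d <- generatePlantedChannels(n = 60, p = 40, info = 11:20, seed = 12)
  diffs <- vapply(1:3, function(s) {
    yPerm <- withr::with_seed(s, sample(d$y))
    u <- uve(d$X, yPerm, 4, iterations = 40, seed = s)
    sel <- selectedChannels(u)
    if (length(sel) < 2) return(0)
    base <- menirmap:::quickRmsecv(d$X, yPerm, 4, iterations = 20, seed = s)
    subm <- menirmap:::quickRmsecv(d$X[, sel, drop = FALSE], yPerm, 4,
                                   iterations = 20, seed = s)
    (base - subm) / base
  }, numeric(1))
  expect_lt(max(diffs), 0.25)
})
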