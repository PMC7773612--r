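test_that("predictions assemble onto the measurement lattice", {
  set.seed(41)
  vals <- runif(55, 70, 75)
  coords <- cbind(rep(0:8, length.out = 55), rep(0:13, each = 4)[1:55])
  coords <- unique(coords)[1:55, ]
  # build 55 unique in-range coordinates deterministically
  all126 <- as.matrix(expand.grid(0:8, 0:13))
  coords <- all126[1:55, ]
  g <- assembleGrid(vals, coords)
  expect_equal(dim(gridValues(g)), c(9, 14))
  expect_equal(sum(measuredMask(g)), 55)
  expect_equal(sum(!measuredMask(g)), 71)
  expect_equal(sum(gridProvenance(g) == "background"), 71)
  # full grid leaves nothing unmeasured
  gf <- assembleGrid(runif(126), all126)
  expect_true(all(measuredMask(gf)))
  expect_error(assembleGrid(c(1, 2), rbind(c(0, 0), c(9, 0))), "outside")
  expect_error(assembleGrid(c(1, 2), rbind(c(0, 0), c(0, 0))), "duplicate")
})

test_that("neighbour-mean imputation fills adjacent cells with exact means", {
  vals <- c(1, 2, 3, 4)
  coords <- rbind(c(0, 1), c(2, 1), c(1, 0), c(1, 2))
  g <- assembleGrid(vals, coords, shape = c(3, 3))
  filled <- fillMissingNeighbors(g)
  expect_equal(gridValues(filled)[2, 2], 2.5)
  expect_equal(gridProvenance(filled)[2, 2], "imputed")
  # fully measured grid is untouched
  full <- assembleGrid(1:9, as.matrix(expand.grid(0:2, 0:2)), c(3, 3))
  expect_equal(gridValues(fillMissingNeighbors(full)), gridValues(full))
  empty <- new("GridMap", values = matrix(NA_real_, 2, 2),
               measured = matrix(FALSE, 2, 2),
               provenance = matrix("background", 2, 2))
  expect_error(fillMissingNeighbors(empty), "no measured")
})

test_that("multi-sweep imputation matches a brute-force BFS oracle", {
  set.seed(42)
  for (rep in 1:5) {
    shape <- c(6, 7)
    nMeas <- 12
    idx <- sample(prod(shape), nMeas)
    coords <- cbind((idx - 1) %% shape[1], (idx - 1) %/% shape[1])
    vals <- runif(nMeas, 60, 80)
    g <- assembleGrid(vals, coords, shape)
    filled <- fillMissingNeighbors(g)

    # independent sweep simulation, computed from the previous state only
    V <- gridValues(g); has <- measuredMask(g)
    repeat {
      newV <- V; newHas <- has; changed <- FALSE
      for (i in 1:shape[1]) for (j in 1:shape[2]) {
        if (has[i, j]) next
        nb <- c()
        if (i > 1 && has[i - 1, j]) nb <- c(nb, V[i - 1, j])
        if (i < shape[1] && has[i + 1, j]) nb <- c(nb, V[i + 1, j])
        if (j > 1 && has[i, j - 1]) nb <- c(nb, V[i, j - 1])
        if (j < shape[2] && has[i, j + 1]) nb <- c(nb, V[i, j + 1])
        if (length(nb)) { newV[i, j] <- mean(nb); newHas[i, j] <- TRUE; changed <- TRUE }
      }
      V <- newV; has <- newHas
      if (!changed) break
    }
    got <- gridValues(filled); got[is.na(got)] <- -1; V[is.na(V)] <- -1
    expect_equal(got, V, tolerance = 1e-12)

    # idempotence and range preservation
    again <- fillMissingNeighbors(filled)
    expect_equal(gridValues(again), gridValues(filled))
    imput <- gridValues(filled)[gridProvenance(filled) == "imputed"]
    expect_true(all(imput >= min(vals) - 1e-12 & imput <= max(vals) + 1e-12))
  }
})

test_that("8-connected imputation uses diagonal neighbours", {
  g <- assembleGrid(c(2, 4), rbind(c(0, 0), c(2, 2)), c(3, 3))
  f8 <- fillMissingNeighbors(g, neighborhood = 8)
  expect_equal(gridValues(f8)[2, 2], 3)  # mean of the two diagonal values
  f4 <- fillMissingNeighbors(g, neighborhood = 4)
  # 4-connected reaches the centre only via imputed edge cells
  expect_equal(gridProvenance(f4)[2, 2], "imputed")
})

test_that("embedding centres the grid and the dimension law holds", {
  g <- assembleGrid(matrix(1:12, 3)[1:12], as.matrix(expand.grid(0:2, 0:3)),
                    c(3, 4))
  for (sp in c(1, 0.5, 0.1, 0.01)) {
    cm <- embedAndInterpolate(g, canvasSide = 20, spacing = sp)
    side <- (20 - 1) / sp + 1
    expect_equal(dim(cm@interpolated), c(side, side))
  }
  cm <- embedAndInterpolate(g, canvasSide = 20, spacing = 0.5)
  expect_equal(cm@offset, c(floor((20 - 3) / 2), floor((20 - 4) / 2)))
  expect_error(embedAndInterpolate(g, canvasSide = 2), "larger")
})

test_that("interpolated values are exact at nodes and between them", {
  set.seed(43)
  z <- matrix(runif(12, 60, 80), 3, 4)
  g <- assembleGrid(as.vector(z),
                    cbind(rep(0:2, 4), rep(0:3, each = 3)), c(3, 4))
  cm <- embedAndInterpolate(g, canvasSide = 8, spacing = 0.25)
  fine <- seq(1, 8, by = 0.25)
  nodeIdx <- match(1:8, fine)
  expect_equal(cm@interpolated[nodeIdx, nodeIdx], cm@canvas)
  # midpoint on a flat row between horizontally adjacent nodes a, b
  r <- cm@offset[1] + 2
  cmid <- cm@offset[2] + 2
  a <- cm@canvas[r, cmid]; b <- cm@canvas[r, cmid + 1]
  i <- match(r, fine); j <- which(fine == cmid + 0.5)
  expect_equal(cm@interpolated[i, j], (a + b) / 2)
  # constant full canvas stays constant
  gc <- assembleGrid(rep(5, 16), as.matrix(expand.grid(0:3, 0:3)), c(4, 4))
  cmc <- embedAndInterpolate(gc, canvasSide = 4, spacing = 0.5, background = 5)
  expect_true(all(abs(cmc@interpolated - 5) < 1e-12))
})

test_that("separable interpolation agrees with a general bilinear oracle", {
  skip_if_not_installed("pracma")
  set.seed(44)
  z <- matrix(runif(25), 5, 5)
  g <- new("GridMap", values = z, measured = matrix(TRUE, 5, 5),
           provenance = matrix("measured", 5, 5))
  cm <- embedAndInterpolate(g, canvasSide = 7, spacing = 0.2)
  fine <- seq(1, 7, by = 0.2)
  m <- length(fine)
  oracle <- matrix(pracma::interp2(1:7, 1:7, cm@canvas,
                                   rep(fine, each = m), rep(fine, times = m),
                                   method = "linear"), m, m)
  expect_equal(cm@interpolated, oracle, tolerance = 1e-12)
})

test_that("error maps summarise percent errors over measured cells", {
  coords <- as.matrix(expand.grid(0:2, 0:2))
  meas <- assembleGrid(rep(50, 9), coords, c(3, 3))
  pred <- assembleGrid(rep(51, 9), coords, c(3, 3))
  em <- errorMap(meas, pred)
  expect_true(all(abs(em$map - 2) < 1e-12))
  expect_equal(unname(em$summary), rep(2, 4))
  same <- errorMap(meas, meas)
  expect_equal(unname(same$summary), rep(0, 4))
  # random pair vs direct recomputation oracle
  set.seed(45)
  mv <- runif(9, 40, 60); pv <- runif(9, 40, 60)
  em2 <- errorMap(assembleGrid(mv, coords, c(3, 3)),
                  assembleGrid(pv, coords, c(3, 3)))
  expErr <- 100 * abs(pv - mv) / mv
  expect_equal(sort(as.vector(em2$map)), sort(expErr))
  expect_equal(em2$summary[["mean"]], mean(expErr))
  expect_equal(em2$summary[["median"]], median(expErr))
  # zero measured values are excluded with a count
  mv0 <- mv; mv0[3] <- 0
  em3 <- errorMap(assembleGrid(mv0, coords, c(3, 3)),
                  assembleGrid(pv, coords, c(3, 3)))
  expect_equal(em3$excluded, 1)
  expect_equal(sum(!is.na(em3$map)), 8)
  # mask mismatch is rejected
  part <- assembleGrid(mv[1:8], coords[1:8, ], c(3, 3))
  expect_error(errorMap(meas, part), "masks differ")
})
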