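#' Default instrument wavelength axis
#'
#' The axis of the emulated spectrometer: 1000-2500 nm sampled every 6.55 nm
#' (229 channels).
#'
#' @return numeric vector of wavelengths in nm.
#' @export
defaultWavelengthAxis <- function() seq(1000, 2500, by = 6.55)

#' Absorbance band of a constituent
#'
#' A Gaussian absorbance band: contribution per unit concentration at
#' wavelength lambda is \code{amplitude * exp(-(lambda - center)^2 /
#' (2 width^2))}.
#'
#' @param center band center in nm.
#' @param width Gaussian sigma in nm (> 0).
#' @param amplitude absorbance units per unit concentration (% wet weight).
#' @return a one-row data.frame with columns center, width, amplitude.
#' @export
componentBand <- function(center, width, amplitude) {
  if (!is.finite(center) || !is.finite(width) || !is.finite(amplitude))
    stop("band parameters must be finite")
  if (width <= 0) stop("band width must be > 0")
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Default constituent band library
#'
#' Three constituents with 2-3 Gaussian bands each, all centred inside
#' 1060-1840 nm so the retained spectral ranges keep signal. Water carries a
#' dominant band on the shoulder of its strong 1400-1450 nm absorption plus a
#' secondary band inside 1560-1840 nm; the hydroxyproline (collagen) proxy
#' sits in the C-H overtone regions; the uronic-acid proxy has high
#' per-unit amplitudes to compensate for its sub-percent concentration.
#'
#' @return named list of band data.frames (water, uronic_acid,
#'   hydroxyproline).
#' @export
defaultBands <- function() {
  list(
    water = rbind(componentBand(1440, 40, 0.012),
                  componentBand(1790, 70, 0.004)),
    uronic_acid = rbind(componentBand(1300, 25, 0.50),
                        componentBand(1610, 35, 0.30)),
    hydroxyproline = rbind(componentBand(1130, 30, 0.015),
                           componentBand(1240, 35, 0.008),
                           componentBand(1690, 45, 0.010))
  )
}

#' Phantom specification for synthetic meniscus NIR data
#'
#' Collects everything the generator needs: constituent concentration ranges
#' (% of wet weight, matching the literature composition of meniscus),
#' per-constituent absorbance bands, the scatter model (per-spectrum
#' multiplicative gain, additive offset and linear baseline slope), channel
#' noise, and the replicate count per measurement location.
#'
#' @param ranges named list of \code{c(low, high)} concentration ranges;
#'   defaults to water 70-75, hydroxyproline 20-22, uronic acid 0.6-0.8
#'   (% wet weight).
#' @param bands named list of band data.frames per constituent (see
#'   \code{\link{defaultBands}}); names must match \code{ranges}.
#' @param residualBands band data.frame for the residual dry matter that
#'   closes the mass balance: constituents are % of wet weight, so the
#'   remainder \code{100 - sum(constituents)} also absorbs. Closure is what
#'   lets scale-removing scatter corrections (SNV/RNV/MSC) retain absolute
#'   concentration information, as in real tissue. \code{NULL} disables the
#'   residual component.
#' @param axis wavelength axis in nm.
#' @param gainSd sd of the multiplicative gain around 1.
#' @param offsetSd sd of the additive offset (absorbance units).
#' @param slopeSd sd of the linear baseline slope (absorbance per nm).
#' @param noiseSd per-channel Gaussian noise sd (absorbance units).
#' @param replicates measurements per location (>= 1).
#' @return a list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(ranges = list(water = c(70, 75),
                                      uronic_acid = c(0.6, 0.8),
                                      hydroxyproline = c(20, 22)),
                        bands = defaultBands(),
                        residualBands = rbind(componentBand(1190, 60, 0.010),
                                              componentBand(1755, 80, 0.008)),
                        axis = defaultWavelengthAxis(),
                        gainSd = 0.05, offsetSd = 0.02, slopeSd = 2e-5,
                        noiseSd = 1e-3, replicates = 3L) {
  stopifnot(length(ranges) >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
      stop(sprintf("range for '%s' must be positive with low < high", nm))
    if (!nm %in% names(bands))
      stop(sprintf("no band set for constituent '%s'", nm))
    b <- bands[[nm]]
    if (any(b$center < min(axis)) || any(b$center > max(axis)))
      stop(sprintf("band center outside axis span for '%s'", nm))
    if (any(b$width <= 0)) stop("band widths must be > 0")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(list(ranges = ranges, bands = bands[names(ranges)],
                 residualBands = residualBands, axis = axis,
                 gainSd = gainSd, offsetSd = offsetSd, slopeSd = slopeSd,
                 noiseSd = noiseSd, replicates = as.integer(replicates)),
            class = "PhantomSpec")
}

#' Generate a spatially smooth constituent field on a grid
#'
#' Draws an i.i.d. uniform field per constituent, smooths it with a
#' moving-average kernel (half-width = \code{smoothness} cells, truncated at
#' grid edges) so neighbouring cells are correlated, then rescales back into
#' the target range. Every cell value is therefore inside its configured range
#' by construction.
#'
#' @param gridShape integer \code{c(rows, cols)}.
#' @param ranges named list of \code{c(low, high)} per constituent.
#' @param smoothness correlation half-width in cells (0 = no smoothing).
#' @param seed RNG seed.
#' @return data.frame with columns location_id, row, col (0-based) and one
#'   column per constituent.
#' @export
generateConstituentField <- function(gridShape, ranges, smoothness = 2,
                                     seed = 1L) {
  rows <- gridShape[1]; cols <- gridShape[2]
  if (rows < 1 || cols < 1) stop("grid dimensions must be >= 1")
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (r[1] >= r[2]) stop(sprintf("range for '%s' must have low < high", nm))
  }
  withSeed(seed, {
    fields <- lapply(names(ranges), function(nm) {
      r <- ranges[[nm]]
      f <- matrix(runif(rows * cols), rows, cols)
      f <- smoothField(f, smoothness)
      span <- diff(range(f))
      if (span < .Machine$double.eps^0.5) {
        # fully smoothed / degenerate grid: place at mid-range
        f[] <- mean(r)
      } else {
        f <- r[1] + (f - min(f)) / span * (r[2] - r[1])
      }
      as.vector(f)  # column-major: row index varies fastest
    })
  })
  names(fields) <- names(ranges)
  coord <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  out <- data.frame(location_id = sprintf("L%03d", seq_len(rows * cols)),
                    row = coord$row, col = coord$col)
  cbind(out, as.data.frame(fields))
}

# moving-average smoothing with edge truncation (kernel renormalised at edges)
smoothField <- function(f, halfWidth) {
  if (halfWidth <= 0) return(f)
  rows <- nrow(f); cols <- ncol(f)
  out <- matrix(0, rows, cols)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      ri <- max(1, i - halfWidth):min(rows, i + halfWidth)
      rj <- max(1, j - halfWidth):min(cols, j + halfWidth)
      out[i, j] <- mean(f[ri, rj])
    }
  }
  out
}

#' Generate a single synthetic NIR spectrum
#'
#' Beer-Lambert mixture of Gaussian constituent bands,
#' \eqn{A(\lambda) = \sum_k c_k \sum_b a_b e^{-(\lambda-\mu_b)^2/2\sigma_b^2}},
#' distorted by a per-spectrum multiplicative gain, additive offset, linear
#' baseline in lambda, and i.i.d. channel noise. With all distortion sds at
#' zero the output equals the deterministic mixture exactly and is linear in
#' each concentration.
#'
#' @param concentrations named numeric vector (% wet weight), names matching
#'   \code{bands}.
#' @param bands named list of band data.frames.
#' @param axis wavelength axis in nm (strictly increasing).
#' @param gainSd,offsetSd,slopeSd,noiseSd distortion standard deviations.
#' @param seed RNG seed (only consulted when any sd is > 0).
#' @return numeric vector of absorbance values along \code{axis}.
#' @export
generateSpectrum <- function(concentrations, bands, axis = defaultWavelengthAxis(),
                             gainSd = 0, offsetSd = 0, slopeSd = 0,
                             noiseSd = 0, seed = NULL) {
  if (any(diff(axis) <= 0)) stop("axis must be strictly increasing")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  a <- pureMixture(concentrations, bands, axis)
  if (gainSd == 0 && offsetSd == 0 && slopeSd == 0 && noiseSd == 0)
    return(a)
  if (is.null(seed)) seed <- 1L
  withSeed(seed, {
    gain <- 1 + stats::rnorm(1, 0, gainSd)
    offset <- stats::rnorm(1, 0, offsetSd)
    slope <- stats::rnorm(1, 0, slopeSd)
    eps <- stats::rnorm(length(axis), 0, noiseSd)
    gain * a + offset + slope * axis + eps
  })
}

pureMixture <- function(concentrations, bands, axis) {
  a <- numeric(length(axis))
  for (nm in names(concentrations)) {
    b <- bands[[nm]]
    if (is.null(b)) stop(sprintf("no bands for constituent '%s'", nm))
    for (i in seq_len(nrow(b))) {
      a <- a + concentrations[[nm]] * b$amplitude[i] *
        exp(-(axis - b$center[i])^2 / (2 * b$width[i]^2))
    }
  }
  a
}

#' Generate a full phantom dataset (training set + test grid)
#'
#' Emulates the study design: \code{nTrainLocations} training locations with
#' \code{spec$replicates} replicate spectra each (concentrations drawn
#' uniformly inside the configured ranges), and a test grid whose constituent
#' fields are spatially smooth. Exactly \code{measuredCells} grid cells are
#' marked measured; the unmeasured cells are those furthest from the grid
#' centre, mimicking edge locations a probe cannot reach. Ground-truth
#' concentrations are retained for recovery tests.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param nTrainLocations number of training locations (default 115).
#' @param testGrid integer \code{c(rows, cols)} of the test lattice (default
#'   9 x 14).
#' @param measuredCells number of grid cells actually measured (default 55).
#' @param seed RNG seed.
#' @return list of class \code{PhantomDataset} with elements \code{train}
#'   (SpectraSet, replicates labelled by group), \code{trainRef} (data.frame),
#'   \code{test} (SpectraSet, one spectrum per measured cell), \code{testRef}
#'   (data.frame over all grid cells, with a \code{measured} column),
#'   \code{mask} (logical rows x cols matrix), and \code{spec}.
#' @export
generateDataset <- function(spec, nTrainLocations = 115L,
                            testGrid = c(9L, 14L), measuredCells = 55L,
                            seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  nCells <- prod(testGrid)
  if (measuredCells > nCells)
    stop("measuredCells exceeds the number of grid cells")
  axis <- spec$axis
  cons <- names(spec$ranges)
  allBands <- spec$bands
  withRes <- !is.null(spec$residualBands)
  if (withRes) allBands$residual <- spec$residualBands
  # mass closure: the remaining dry matter (100% minus the tracked
  # constituents) absorbs too
  fullConc <- function(conc) {
    if (withRes) c(conc, residual = max(0, 100 - sum(conc))) else conc
  }

  trainRef <- withSeed(deriveSeed(seed, 1L), {
    vals <- lapply(cons, function(nm) {
      r <- spec$ranges[[nm]]
      stats::runif(nTrainLocations, r[1], r[2])
    })
    names(vals) <- cons
    data.frame(location_id = sprintf("T%03d", seq_len(nTrainLocations)),
               as.data.frame(vals))
  })

  # training spectra: spec$replicates noisy acquisitions per location
  nTrain <- nTrainLocations * spec$replicates
  trainMat <- matrix(0, nTrain, length(axis))
  ids <- character(nTrain); grp <- character(nTrain)
  k <- 0L
  for (i in seq_len(nTrainLocations)) {
    conc <- fullConc(unlist(trainRef[i, cons]))
    for (r in seq_len(spec$replicates)) {
      k <- k + 1L
      trainMat[k, ] <- generateSpectrum(conc, allBands, axis,
                                        spec$gainSd, spec$offsetSd,
                                        spec$slopeSd, spec$noiseSd,
                                        seed = deriveSeed(seed, 100L + k))
      grp[k] <- trainRef$location_id[i]
      ids[k] <- sprintf("%s_r%d", trainRef$location_id[i], r)
    }
  }
  train <- SpectraSet(trainMat, axis, sampleIds = ids, groups = grp)

  # test grid: smooth constituent fields, central cells measured
  field <- generateConstituentField(testGrid, spec$ranges, smoothness = 2,
                                    seed = deriveSeed(seed, 2L))
  ctr <- (testGrid - 1) / 2
  d2 <- (field$row - ctr[1])^2 + (field$col - ctr[2])^2
  ordIdx <- order(d2, field$row, field$col)
  measuredIdx <- sort(ordIdx[seq_len(measuredCells)])
  mask <- matrix(FALSE, testGrid[1], testGrid[2])
  mask[cbind(field$row[measuredIdx] + 1L, field$col[measuredIdx] + 1L)] <- TRUE
  field$measured <- seq_len(nrow(field)) %in% measuredIdx

  testMat <- matrix(0, measuredCells, length(axis))
  for (j in seq_along(measuredIdx)) {
    conc <- fullConc(unlist(field[measuredIdx[j], cons]))
    testMat[j, ] <- generateSpectrum(conc, allBands, axis,
                                     spec$gainSd, spec$offsetSd,
                                     spec$slopeSd, spec$noiseSd,
                                     seed = deriveSeed(seed, 20000L + j))
  }
  test <- SpectraSet(testMat, axis,
                     sampleIds = field$location_id[measuredIdx],
                     groups = field$location_id[measuredIdx])

  structure(list(train = train, trainRef = trainRef, test = test,
                 testRef = field, mask = mask, spec = spec, seed = seed),
            class = "PhantomDataset")
}

#' Generate a planted-channel benchmark problem for variable selection
#'
#' Builds a regression problem in which exactly \code{length(info)} channels
#' are informative and the rest are dead noise. Each informative channel j
#' carries its own latent signal \code{g_j}; the response is the
#' weight-averaged sum of the latents with a band-shaped (Gaussian) weight
#' profile over the informative block, so every informative channel
#' contributes unique predictive information and a selection algorithm that
#' drops one genuinely loses accuracy. Used by the recovery benchmarks of the
#' selection algorithms.
#'
#' @param n samples.
#' @param p channels.
#' @param info indices of the informative channels (default: 20 channels
#'   centred in the axis).
#' @param channelNoise sd of the measurement noise added to informative
#'   channels (dead channels are unit-variance noise).
#' @param yNoise sd of the response noise.
#' @param seed RNG seed.
#' @return list with \code{X} (n x p), \code{y}, \code{info}, \code{weights}
#'   (the band profile over \code{info}).
#' @export
generatePlantedChannels <- function(n = 200, p = 220,
                                    info = seq(101, 120),
                                    channelNoise = 0.2, yNoise = 0.05,
                                    seed = 1L) {
  k <- length(info)
  # mild taper: every informative channel carries a comparable share of the
  # response so none is statistically expendable
  w <- 0.9 + 0.3 * exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * (k / 3)^2))
  withSeed(seed, {
    G <- matrix(stats::rnorm(n * k), n, k)
    X <- matrix(stats::rnorm(n * p), n, p)
    X[, info] <- G + matrix(stats::rnorm(n * k, 0, channelNoise), n, k)
    y <- as.numeric(G %*% w) / k + stats::rnorm(n, 0, yNoise)
  })
  list(X = X, y = y, info = info, weights = w)
}

#' Write a phantom dataset to disk
#'
#' Emits the spectra and reference tables as CSV plus a JSON sidecar with the
#' generating parameters.
#'
#' @param dataset a \code{PhantomDataset}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    train_spectra = file.path(dir, "train_spectra.csv"),
    train_references = file.path(dir, "train_references.csv"),
    test_spectra = file.path(dir, "test_spectra.csv"),
    test_references = file.path(dir, "test_references.csv"),
    spec = file.path(dir, "phantom_spec.json")
  )
  writeSpectra(dataset$train, paths["train_spectra"])
  utils::write.csv(dataset$trainRef, paths["train_references"], row.names = FALSE)
  writeSpectra(dataset$test, paths["test_spectra"])
  utils::write.csv(dataset$testRef, paths["test_references"], row.names = FALSE)
  sp <- dataset$spec
  jsonlite::write_json(
    list(ranges = sp$ranges,
         bands = lapply(sp$bands, function(b) as.list(b)),
         gainSd = sp$gainSd, offsetSd = sp$offsetSd, slopeSd = sp$slopeSd,
         noiseSd = sp$noiseSd, replicates = sp$replicates,
         axis = range(sp$axis), seed = dataset$seed),
    paths["spec"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
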