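#' Build a pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: the phantom (or input
#' paths), the constituents to model, the preprocessing search grid, MCCV and
#' outlier-screening settings, the variable-selection method list, mapping
#' settings, and the master seed from which every stage derives its own seed.
#'
#' @param phantom a \code{\link{phantomSpec}} (used when \code{paths} is
#'   NULL).
#' @param paths optional named list with train_spectra, train_references,
#'   test_spectra, test_references CSV paths.
#' @param constituents character vector of reference columns to model.
#' @param configs list of \linkS4class{PreprocessConfig} candidates; default
#'   is a compact grid over the three retained wavelength ranges, all four
#'   scatter options and a reduced SG grid.
#' @param maxComp largest PLS component count.
#' @param cvIterations MCCV iterations for the grid search and component
#'   choice.
#' @param outlierIterations,outlierRatio,outlierKSd outlier-screening
#'   settings.
#' @param methods variable-selection methods to compare (may be empty).
#' @param methodArgs named list of per-method argument lists.
#' @param gridShape test lattice shape.
#' @param canvasSide,spacing mapping canvas side and interpolation step.
#' @param nTrainLocations,measuredCells phantom sampling design.
#' @param seed master seed.
#' @param outputDir run directory.
#' @return a validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(phantom = phantomSpec(), paths = NULL,
                           constituents = c("water", "uronic_acid",
                                            "hydroxyproline"),
                           configs = enumerateConfigs(
                             windows = c(5, 11, 17), polyorders = 2,
                             derivs = c(0, 1)),
                           maxComp = 10L, cvIterations = 30L,
                           outlierIterations = 250L, outlierRatio = 0.75,
                           outlierKSd = 3,
                           methods = character(0), methodArgs = list(),
                           gridShape = c(9L, 14L), canvasSide = 20L,
                           spacing = 0.01, nTrainLocations = 115L,
                           measuredCells = 55L, seed = 1L,
                           outputDir = tempfile("menirmap_run_")) {
  cfg <- structure(list(phantom = phantom, paths = paths,
                        constituents = constituents, configs = configs,
                        maxComp = as.integer(maxComp),
                        cvIterations = as.integer(cvIterations),
                        outlierIterations = as.integer(outlierIterations),
                        outlierRatio = outlierRatio, outlierKSd = outlierKSd,
                        methods = methods, methodArgs = methodArgs,
                        gridShape = as.integer(gridShape),
                        canvasSide = as.integer(canvasSide),
                        spacing = spacing,
                        nTrainLocations = as.integer(nTrainLocations),
                        measuredCells = as.integer(measuredCells),
                        seed = as.integer(seed), outputDir = outputDir),
                   class = "PipelineConfig")
  errs <- configErrors(cfg)
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  cfg
}

# collect every invariant violation with its field path
configErrors <- function(cfg) {
  errs <- character(0)
  add <- function(field, msg) errs <<- c(errs, sprintf("%s: %s", field, msg))
  if (!length(cfg$constituents)) add("constituents", "must be non-empty")
  if (is.null(cfg$seed) || is.na(cfg$seed)) add("seed", "must be set")
  if (!length(cfg$configs)) add("configs", "must be non-empty")
  for (i in seq_along(cfg$configs)) {
    v <- methods::validObject(cfg$configs[[i]], test = TRUE)
    if (!isTRUE(v)) add(sprintf("configs[[%d]]", i), paste(v, collapse = "; "))
  }
  if (cfg$maxComp < 1) add("maxComp", "must be >= 1")
  if (cfg$cvIterations < 1) add("cvIterations", "must be >= 1")
  if (cfg$outlierRatio <= 0 || cfg$outlierRatio >= 1)
    add("outlierRatio", "must be in (0, 1)")
  bad <- setdiff(cfg$methods, c("uve", "cars", "frog", "mwpls", "iriv"))
  if (length(bad)) add("methods", paste("unknown:", paste(bad, collapse = ", ")))
  if (any(cfg$gridShape < 1)) add("gridShape", "dimensions must be >= 1")
  if (cfg$measuredCells > prod(cfg$gridShape))
    add("measuredCells", "exceeds grid size")
  if (max(cfg$gridShape) > cfg$canvasSide)
    add("canvasSide", "grid does not fit inside the canvas")
  if (cfg$spacing <= 0 || cfg$spacing > 1) add("spacing", "must be in (0, 1]")
  errs
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) pipeline configuration and either returns the
#' validated \code{PipelineConfig} or the full list of invariant violations,
#' each with its field path.
#'
#' @param path YAML/JSON file. Recognised keys: constituents, seed, max_comp,
#'   cv_iterations, outlier: \{iterations, ratio, k_sd\}, methods, grid_shape,
#'   canvas_side, spacing, n_train_locations, measured_cells, output_dir,
#'   configs (list of preprocessing mappings with keys ranges, scatter, sg),
#'   phantom: \{gain_sd, offset_sd, slope_sd, noise_sd, replicates\}.
#' @return a \code{PipelineConfig}, or an error listing every violation.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("unparseable config: ",
                                           conditionMessage(e)))
  args <- list()
  if (!is.null(raw$constituents)) args$constituents <- unlist(raw$constituents)
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$max_comp)) args$maxComp <- raw$max_comp
  if (!is.null(raw$cv_iterations)) args$cvIterations <- raw$cv_iterations
  if (!is.null(raw$outlier)) {
    if (!is.null(raw$outlier$iterations))
      args$outlierIterations <- raw$outlier$iterations
    if (!is.null(raw$outlier$ratio)) args$outlierRatio <- raw$outlier$ratio
    if (!is.null(raw$outlier$k_sd)) args$outlierKSd <- raw$outlier$k_sd
  }
  if (!is.null(raw$methods)) args$methods <- unlist(raw$methods)
  if (!is.null(raw$grid_shape)) args$gridShape <- unlist(raw$grid_shape)
  if (!is.null(raw$canvas_side)) args$canvasSide <- raw$canvas_side
  if (!is.null(raw$spacing)) args$spacing <- raw$spacing
  if (!is.null(raw$n_train_locations))
    args$nTrainLocations <- raw$n_train_locations
  if (!is.null(raw$measured_cells)) args$measuredCells <- raw$measured_cells
  if (!is.null(raw$output_dir)) args$outputDir <- raw$output_dir
  if (!is.null(raw$configs)) {
    configs <- list(); errs <- character(0)
    for (i in seq_along(raw$configs)) {
      c_i <- tryCatch(configFromList(raw$configs[[i]]),
                      error = function(e) conditionMessage(e))
      if (is.character(c_i))
        errs <- c(errs, sprintf("configs[[%d]]: %s", i, c_i))
      else configs[[length(configs) + 1L]] <- c_i
    }
    if (length(errs)) stop("invalid pipeline config:\n  ",
                           paste(errs, collapse = "\n  "))
    args$configs <- configs
  }
  if (!is.null(raw$phantom)) {
    ph <- raw$phantom
    args$phantom <- phantomSpec(
      gainSd = if (is.null(ph$gain_sd)) 0.05 else ph$gain_sd,
      offsetSd = if (is.null(ph$offset_sd)) 0.02 else ph$offset_sd,
      slopeSd = if (is.null(ph$slope_sd)) 2e-5 else ph$slope_sd,
      noiseSd = if (is.null(ph$noise_sd)) 1e-3 else ph$noise_sd,
      replicates = if (is.null(ph$replicates)) 3L else ph$replicates)
  }
  do.call(pipelineConfig, args)
}

#' Run the full analysis pipeline
#'
#' End to end: generate (or load) the dataset, average replicates, search the
#' preprocessing grid per constituent, choose the component count by MCCV,
#' screen outliers, compare variable-selection methods, predict the held-out
#' grid, and assemble measured/predicted/error maps. All artifacts (winning
#' preprocessing per constituent, comparison tables, serialized models, map
#' CSVs, a JSON manifest with every seed) are written under
#' \code{config$outputDir}. Reruns with the same config and seed are
#' bit-identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with the output directory, the manifest, and the
#'   per-constituent results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(package = "menirmap",
                   version = as.character(utils::packageVersion("menirmap")),
                   seed = seed, stages = list(), files = character(0))

  # --- data ----------------------------------------------------------------
  if (is.null(config$paths)) {
    ds <- generateDataset(config$phantom, config$nTrainLocations,
                          config$gridShape, config$measuredCells,
                          seed = deriveSeed(seed, 1L))
    trainRef <- ds$trainRef
    testRef <- ds$testRef
    trainSet <- ds$train
    testSet <- ds$test
    manifest$stages$data <- list(source = "phantom",
                                 seed = deriveSeed(seed, 1L))
  } else {
    trainSet <- readSpectra(config$paths$train_spectra)
    trainRef <- readReferences(config$paths$train_references)
    testSet <- readSpectra(config$paths$test_spectra)
    testRef <- readReferences(config$paths$test_references)
    manifest$stages$data <- list(source = "files", paths = config$paths)
  }
  trainAvg <- averageReplicates(trainSet)
  testAvg <- averageReplicates(testSet)

  results <- list()
  for (con in config$constituents) {
    res <- tryCatch(
      runConstituent(con, trainAvg, trainRef, testAvg, testRef, config),
      error = function(e) list(error = conditionMessage(e)))
    results[[con]] <- res
    if (!is.null(res[["error"]])) {
      manifest$stages[[con]] <- list(status = "failed",
                                     error = res[["error"]])
      next
    }
    manifest$stages[[con]] <- res$stageInfo
    # Table 1 analog: winning preprocessing configuration
    f1 <- file.path(config$outputDir, sprintf("preprocessing_%s.csv", con))
    utils::write.csv(res$gridRanking, f1, row.names = FALSE)
    # Table 2 analog: method comparison
    f2 <- file.path(config$outputDir, sprintf("comparison_%s.csv", con))
    utils::write.csv(res$comparison, f2, row.names = FALSE)
    # serialized best model
    f3 <- file.path(config$outputDir, sprintf("model_%s.json", con))
    writePlsModel(res$model, f3)
    # maps
    f4 <- file.path(config$outputDir, sprintf("map_measured_%s.csv", con))
    f5 <- file.path(config$outputDir, sprintf("map_predicted_%s.csv", con))
    f6 <- file.path(config$outputDir, sprintf("map_error_%s.csv", con))
    utils::write.table(gridValues(res$measuredMap), f4, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(gridValues(res$predictedMap), f5, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(res$errors$map, f6, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    manifest$files <- c(manifest$files, f1, f2, f3, f4, f5, f6)
  }
  manifest$files <- basename(manifest$files)
  jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(outputDir = config$outputDir, manifest = manifest,
                 results = results))
}

# one constituent through preprocessing search, outlier screen, variable
# selection, test evaluation and mapping
runConstituent <- function(con, trainAvg, trainRef, testAvg, testRef, config) {
  seed <- config$seed
  conSeed <- deriveSeed(seed, 1000L + match(con, config$constituents))
  y <- trainRef[[con]][match(sampleIds(trainAvg), trainRef$location_id)]
  if (anyNA(y)) stop("missing training references for ", con)

  gs <- gridSearch(trainAvg, trainRef, config$configs, con,
                   maxComp = config$maxComp,
                   iterations = config$cvIterations,
                   seed = deriveSeed(conSeed, 1L))
  best <- gs$best
  ref <- pipelineReference(trainAvg, best)
  trainPp <- applyPipeline(trainAvg, best, reference = ref)
  testPp <- applyPipeline(testAvg, best, reference = ref)
  Xtr <- spectraValues(trainPp)

  out <- detectOutliers(Xtr, y, nComp = gs$curves[[1]]@nComp,
                        iterations = config$outlierIterations,
                        ratio = config$outlierRatio,
                        seed = deriveSeed(conSeed, 2L),
                        kSd = config$outlierKSd,
                        sampleIds = sampleIds(trainPp))
  keep <- !sampleIds(trainPp) %in% flaggedSamples(out)
  Xtr <- Xtr[keep, , drop = FALSE]
  yTr <- y[keep]

  testIds <- sampleIds(testPp)
  refRow <- match(testIds, testRef$location_id)
  yTe <- testRef[[con]][refRow]
  cmp <- compareMethods(Xtr, yTr, spectraValues(testPp), yTe,
                        methods = config$methods, maxComp = config$maxComp,
                        cvIterations = config$cvIterations,
                        seed = deriveSeed(conSeed, 3L),
                        methodArgs = config$methodArgs)
  bestRow <- which(cmp$best)
  bestMethod <- cmp$method[bestRow]
  sel <- if (bestMethod == "Base") seq_len(ncol(Xtr)) else
    selectedChannels(attr(cmp, "selections")[[tolower(bestMethod)]])
  model <- fitNipals(Xtr[, sel, drop = FALSE], yTr, cmp$n_comp[bestRow])
  preds <- predict(model, spectraValues(testPp)[, sel, drop = FALSE])

  coords <- cbind(testRef$row[refRow], testRef$col[refRow])
  measuredMap <- fillMissingNeighbors(
    assembleGrid(yTe, coords, shape = config$gridShape))
  predictedMap <- fillMissingNeighbors(
    assembleGrid(preds, coords, shape = config$gridShape))
  errs <- errorMap(assembleGrid(yTe, coords, shape = config$gridShape),
                   assembleGrid(preds, coords, shape = config$gridShape))
  canvas <- embedAndInterpolate(predictedMap, config$canvasSide,
                                config$spacing)

  list(gridRanking = utils::head(gs$ranking, 25),
       bestConfig = best, outliers = out, comparison = cmp,
       model = model, predictions = preds, yTest = yTe,
       rhoTest = spearmanRho(yTe, preds), rmsep = rmse(yTe, preds),
       measuredMap = measuredMap, predictedMap = predictedMap,
       errors = errs, canvas = canvas,
       stageInfo = list(status = "ok",
                        bestConfig = configLabel(best),
                        bestMethod = bestMethod,
                        nComp = cmp$n_comp[bestRow],
                        nOutliers = length(flaggedSamples(out)),
                        seeds = c(grid = deriveSeed(conSeed, 1L),
                                  outlier = deriveSeed(conSeed, 2L),
                                  compare = deriveSeed(conSeed, 3L))))
}

#' Serialize / load a PLS model as JSON
#'
#' Full double precision; a write/read round trip reproduces every slot.
#'
#' @param model a \linkS4class{PlsModel}.
#' @param path JSON file path.
#' @return \code{readPlsModel}: the restored \linkS4class{PlsModel}.
#' @export
writePlsModel <- function(model, path) {
  jsonlite::write_json(
    list(xMean = model@xMean, yMean = model@yMean,
         weights = model@weights, loadings = model@loadings,
         yLoadings = model@yLoadings, coefficients = model@coefficients,
         intercept = model@intercept, nComp = model@nComp),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writePlsModel
#' @export
readPlsModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PlsModel", xMean = x$xMean, yMean = x$yMean,
      weights = matrix(x$weights, ncol = x$nComp),
      loadings = matrix(x$loadings, ncol = x$nComp),
      yLoadings = x$yLoadings, coefficients = x$coefficients,
      intercept = x$intercept,
      scores = matrix(numeric(0), 0, x$nComp), nComp = as.integer(x$nComp))
}
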