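#' @import methods
NULL

#' SpectraSet: a set of spectra on a common wavelength axis
#'
#' Container for diffuse-reflectance NIR measurements: a samples x channels
#' intensity matrix, the wavelength axis in nm, per-row sample identifiers and
#' replicate-group labels, and a per-channel segment index marking contiguous
#' wavelength blocks (segments become non-trivial after range cropping and are
#' respected by segment-wise filters).
#'
#' @slot values numeric matrix, one row per measurement, one column per channel.
#' @slot wavelengths numeric vector of channel wavelengths in nm, strictly
#'   increasing.
#' @slot sampleIds character vector of per-row identifiers.
#' @slot groups character vector of replicate-group labels (rows sharing a
#'   label are replicate measurements of the same location).
#' @slot segments integer vector, one entry per channel, identifying the
#'   contiguous wavelength segment the channel belongs to.
#'
#' @exportClass SpectraSet
setClass("SpectraSet",
  representation(
    values = "matrix",
    wavelengths = "numeric",
    sampleIds = "character",
    groups = "character",
    segments = "integer"
  )
)

setValidity("SpectraSet", function(object) {
  msg <- character()
  v <- object@values
  wl <- object@wavelengths
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (ncol(v) != length(wl))
    msg <- c(msg, sprintf("column count (%d) != axis length (%d)", ncol(v), length(wl)))
  if (length(wl) < 2) msg <- c(msg, "wavelength axis needs at least 2 channels")
  if (any(!is.finite(wl))) msg <- c(msg, "wavelengths must be finite")
  if (length(wl) >= 2 && any(diff(wl) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (anyNA(v)) msg <- c(msg, "values contain missing entries")
  if (length(object@sampleIds) != nrow(v))
    msg <- c(msg, "one sample id per row required")
  if (length(object@groups) != nrow(v))
    msg <- c(msg, "one replicate-group label per row required")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (length(object@segments) != length(wl))
    msg <- c(msg, "one segment index per channel required")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' Columns are reordered so the wavelength axis is ascending; segment indices
#' default to a single contiguous segment.
#'
#' @param values samples x channels numeric matrix.
#' @param wavelengths channel wavelengths in nm.
#' @param sampleIds per-row identifiers; defaults to \code{s1, s2, ...}.
#' @param groups per-row replicate-group labels; defaults to the sample ids
#'   (every row its own group).
#' @param segments per-channel contiguous-segment index; defaults to all 1.
#' @return A \linkS4class{SpectraSet}.
#' @export
SpectraSet <- function(values, wavelengths,
                       sampleIds = paste0("s", seq_len(nrow(values))),
                       groups = sampleIds,
                       segments = rep(1L, length(wavelengths))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ord <- order(wavelengths)
  values <- values[, ord, drop = FALSE]
  wavelengths <- wavelengths[ord]
  segments <- as.integer(segments[ord])
  dimnames(values) <- NULL
  new("SpectraSet", values = values, wavelengths = as.numeric(wavelengths),
      sampleIds = as.character(sampleIds), groups = as.character(groups),
      segments = segments)
}

#' @describeIn SpectraSet intensity matrix accessor
#' @param object,x a \code{SpectraSet}
#' @export
spectraValues <- function(object) object@values

#' @describeIn SpectraSet wavelength axis accessor (nm)
#' @export
wavelengths <- function(object) object@wavelengths

#' @describeIn SpectraSet sample-id accessor
#' @export
sampleIds <- function(object) object@sampleIds

#' @describeIn SpectraSet replicate-group accessor
#' @export
replicateGroups <- function(object) object@groups

#' @describeIn SpectraSet per-channel segment index accessor
#' @export
segmentIds <- function(object) object@segments

#' @describeIn SpectraSet number of spectra
#' @export
nSpectra <- function(object) nrow(object@values)

#' @describeIn SpectraSet number of wavelength channels
#' @export
nChannels <- function(object) ncol(object@values)

setMethod("show", "SpectraSet", function(object) {
  wl <- object@wavelengths
  cat(sprintf("SpectraSet: %d spectra x %d channels (%.2f-%.2f nm, %d segment%s)\n",
              nrow(object@values), length(wl), min(wl), max(wl),
              max(object@segments), if (max(object@segments) == 1) "" else "s"))
  ng <- length(unique(object@groups))
  cat(sprintf("  replicate groups: %d\n", ng))
})

#' PreprocessConfig: one point in the preprocessing search space
#'
#' A preprocessing configuration: the wavelength intervals to retain, the
#' scatter-correction method, and the Savitzky-Golay smoothing/derivative
#' parameters. Stages are applied in the order crop, scatter correction,
#' Savitzky-Golay.
#'
#' @slot ranges numeric matrix with columns \code{low}, \code{high} (nm), one
#'   row per retained interval; intervals are closed and must not overlap.
#' @slot scatter one of \code{"none"}, \code{"snv"}, \code{"rnv"}, \code{"msc"}.
#' @slot sgWindow odd SG window size (channels), one of 5, 7, ..., 19.
#' @slot sgPolyOrder SG polynomial order, 2 or 3.
#' @slot sgDeriv SG derivative order, 0, 1 or 2 (must not exceed the
#'   polynomial order).
#' @slot rnvPercentile percentile used by RNV centering (default 25).
#'
#' @exportClass PreprocessConfig
setClass("PreprocessConfig",
  representation(
    ranges = "matrix",
    scatter = "character",
    sgWindow = "integer",
    sgPolyOrder = "integer",
    sgDeriv = "integer",
    rnvPercentile = "numeric"
  )
)

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  r <- object@ranges
  if (ncol(r) != 2) msg <- c(msg, "ranges must have two columns (low, high)")
  if (nrow(r) < 1) msg <- c(msg, "at least one range required")
  if (any(r[, 1] >= r[, 2])) msg <- c(msg, "each range needs low < high")
  if (nrow(r) > 1) {
    o <- order(r[, 1])
    rs <- r[o, , drop = FALSE]
    if (any(rs[-nrow(rs), 2] >= rs[-1, 1]))
      msg <- c(msg, "ranges must not overlap")
  }
  if (!object@scatter %in% c("none", "snv", "rnv", "msc"))
    msg <- c(msg, "scatter must be one of none, snv, rnv, msc")
  w <- object@sgWindow; p <- object@sgPolyOrder; d <- object@sgDeriv
  if (!w %in% seq(5L, 19L, 2L)) msg <- c(msg, "sg window must be odd, in 5..19")
  if (!p %in% c(2L, 3L)) msg <- c(msg, "sg polynomial order must be 2 or 3")
  if (!d %in% 0:2) msg <- c(msg, "sg derivative order must be 0, 1 or 2")
  if (p >= w) msg <- c(msg, "sg polynomial order must be < window")
  if (d > p) msg <- c(msg, "sg derivative order must be <= polynomial order")
  if (object@rnvPercentile <= 0 || object@rnvPercentile >= 100)
    msg <- c(msg, "rnv percentile must be in (0, 100)")
  if (length(msg)) msg else TRUE
})

#' Construct a PreprocessConfig
#'
#' @param ranges list of two-element numeric vectors \code{c(low, high)} in nm,
#'   or a two-column matrix.
#' @param scatter scatter-correction method: \code{"none"}, \code{"snv"},
#'   \code{"rnv"} or \code{"msc"}.
#' @param sgWindow,sgPolyOrder,sgDeriv Savitzky-Golay window size, polynomial
#'   order and derivative order.
#' @param rnvPercentile percentile used by RNV (default 25).
#' @return A \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(ranges, scatter = "none", sgWindow = 5L,
                             sgPolyOrder = 2L, sgDeriv = 0L,
                             rnvPercentile = 25) {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.numeric(ranges), ncol = 2,
                   dimnames = list(NULL, c("low", "high")))
  ranges <- ranges[order(ranges[, 1]), , drop = FALSE]
  new("PreprocessConfig", ranges = ranges, scatter = tolower(scatter),
      sgWindow = as.integer(sgWindow), sgPolyOrder = as.integer(sgPolyOrder),
      sgDeriv = as.integer(sgDeriv), rnvPercentile = rnvPercentile)
}

setMethod("show", "PreprocessConfig", function(object) {
  rtxt <- paste(apply(object@ranges, 1, function(r)
    sprintf("%g-%g", r[1], r[2])), collapse = ", ")
  cat(sprintf("PreprocessConfig: ranges [%s] nm | scatter %s | SG %d/%d/%d\n",
              rtxt, object@scatter, object@sgWindow, object@sgPolyOrder,
              object@sgDeriv))
})

#' PlsModel: a fitted NIPALS PLS1 regression model
#'
#' Single-response partial least squares model as produced by
#' \code{\link{fitNipals}}. Predictors are mean-centered (not variance-scaled)
#' internally; predictions are available both through the latent-variable route
#' and through the collapsed regression coefficients, and the two agree to
#' numerical precision.
#'
#' @slot xMean per-channel predictor means used for centering.
#' @slot yMean response mean.
#' @slot weights channels x components NIPALS weight matrix W.
#' @slot loadings channels x components predictor loading matrix P.
#' @slot yLoadings per-component response loadings q.
#' @slot coefficients per-channel collapsed regression coefficients b.
#' @slot intercept scalar intercept so that yhat = X b + intercept.
#' @slot scores training score matrix T (kept for diagnostics).
#' @slot nComp number of latent components.
#'
#' @exportClass PlsModel
setClass("PlsModel",
  representation(
    xMean = "numeric",
    yMean = "numeric",
    weights = "matrix",
    loadings = "matrix",
    yLoadings = "numeric",
    coefficients = "numeric",
    intercept = "numeric",
    scores = "matrix",
    nComp = "integer"
  )
)

setValidity("PlsModel", function(object) {
  msg <- character()
  k <- object@nComp
  p <- length(object@xMean)
  if (k < 1) msg <- c(msg, "nComp must be >= 1")
  if (!all(dim(object@weights) == c(p, k))) msg <- c(msg, "weights must be channels x components")
  if (!all(dim(object@loadings) == c(p, k))) msg <- c(msg, "loadings must be channels x components")
  if (length(object@yLoadings) != k) msg <- c(msg, "one y loading per component required")
  if (length(object@coefficients) != p) msg <- c(msg, "one coefficient per channel required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlsModel", function(object) {
  cat(sprintf("PlsModel (NIPALS PLS1): %d channels, %d components\n",
              length(object@xMean), object@nComp))
})

#' GridMap: a sparse constituent grid over measurement locations
#'
#' Per-cell constituent content over the measurement lattice, with a
#' measured-cell mask and per-cell provenance (\code{"measured"},
#' \code{"imputed"} or \code{"background"}).
#'
#' @slot values numeric matrix of per-cell contents (% of wet weight); NA on
#'   background cells.
#' @slot measured logical matrix, TRUE where a direct measurement exists.
#' @slot provenance character matrix with entries measured / imputed /
#'   background.
#'
#' @exportClass GridMap
setClass("GridMap",
  representation(values = "matrix", measured = "matrix", provenance = "matrix")
)

setValidity("GridMap", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (!all(dim(object@measured) == d) || !all(dim(object@provenance) == d))
    msg <- c(msg, "values, measured and provenance must share dimensions")
  if (!is.logical(object@measured)) msg <- c(msg, "measured must be logical")
  if (!all(object@provenance %in% c("measured", "imputed", "background")))
    msg <- c(msg, "provenance entries must be measured/imputed/background")
  if (any(object@measured & object@provenance != "measured"))
    msg <- c(msg, "measured cells must have provenance 'measured'")
  filled <- object@provenance %in% c("measured", "imputed")
  if (any(!is.finite(object@values[filled])))
    msg <- c(msg, "measured/imputed cells must hold finite values")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GridMap", function(object) {
  p <- object@provenance
  cat(sprintf("GridMap %dx%d: %d measured, %d imputed, %d background\n",
              nrow(object@values), ncol(object@values),
              sum(p == "measured"), sum(p == "imputed"), sum(p == "background")))
})

#' @describeIn GridMap per-cell value matrix
#' @param object a \code{GridMap}
#' @export
gridValues <- function(object) object@values

#' @describeIn GridMap measured-cell mask
#' @export
measuredMask <- function(object) object@measured

#' @describeIn GridMap provenance matrix
#' @export
gridProvenance <- function(object) object@provenance

#' CanvasMap: an embedded, interpolated constituent map
#'
#' The result of embedding a \linkS4class{GridMap} in a square background
#' canvas and bilinearly interpolating the node lattice at a fixed spacing.
#'
#' @slot canvas square matrix after embedding.
#' @slot interpolated high-resolution interpolated matrix.
#' @slot spacing interpolation step in grid units.
#' @slot background background fill value.
#' @slot offset integer (row, col) offset of the grid inside the canvas
#'   (0-based).
#'
#' @exportClass CanvasMap
setClass("CanvasMap",
  representation(canvas = "matrix", interpolated = "matrix",
                 spacing = "numeric", background = "numeric",
                 offset = "integer")
)

setValidity("CanvasMap", function(object) {
  msg <- character()
  side <- nrow(object@canvas)
  if (side != ncol(object@canvas)) msg <- c(msg, "canvas must be square")
  expect <- round((side - 1) / object@spacing) + 1
  if (nrow(object@interpolated) != expect || ncol(object@interpolated) != expect)
    msg <- c(msg, sprintf("interpolated side must be (canvas-1)/spacing + 1 = %d", expect))
  if (length(msg)) msg else TRUE
})

setMethod("show", "CanvasMap", function(object) {
  cat(sprintf("CanvasMap: canvas %dx%d -> interpolated %dx%d (spacing %g)\n",
              nrow(object@canvas), ncol(object@canvas),
              nrow(object@interpolated), ncol(object@interpolated),
              object@spacing))
})

#' CvCurve: a Monte Carlo cross-validation curve
#'
#' Per-component-count mean and standard deviation of validation RMSE from
#' repeated random train/validation splits, and the chosen component count.
#'
#' @slot components integer grid of component counts evaluated.
#' @slot meanRmsecv mean validation RMSE per component count.
#' @slot sdRmsecv standard deviation of validation RMSE per component count.
#' @slot nComp chosen number of components.
#' @slot iterations number of Monte Carlo splits.
#' @slot trainRatio fraction of samples used for training in each split.
#' @slot seed RNG seed used.
#'
#' @exportClass CvCurve
setClass("CvCurve",
  representation(components = "integer", meanRmsecv = "numeric",
                 sdRmsecv = "numeric", nComp = "integer",
                 iterations = "integer", trainRatio = "numeric",
                 seed = "integer")
)

setMethod("show", "CvCurve", function(object) {
  cat(sprintf("CvCurve: %d components evaluated, chosen n_comp = %d (RMSECV %.4g), %d iterations @ %.0f%% train\n",
              length(object@components), object@nComp,
              object@meanRmsecv[match(object@nComp, object@components)],
              object@iterations, 100 * object@trainRatio))
})

#' @describeIn CvCurve chosen component count
#' @param object a \code{CvCurve}
#' @export
chosenComponents <- function(object) object@nComp

#' @describeIn CvCurve mean RMSECV per component count
#' @export
rmsecvCurve <- function(object) {
  data.frame(n_comp = object@components, rmsecv = object@meanRmsecv,
             sd = object@sdRmsecv)
}

#' OutlierReport: Monte Carlo outlier screening result
#'
#' Per-sample mean and standard deviation of held-out absolute prediction
#' errors collected over repeated random subsampling fits, plus the flagged
#' sample ids.
#'
#' @slot table data.frame with columns sample_id, mean_residual, sd_residual,
#'   n_heldout, flagged.
#' @slot flagged character vector of flagged sample ids.
#' @slot iterations,ratio,kSd screening parameters.
#' @slot seed RNG seed used.
#'
#' @exportClass OutlierReport
setClass("OutlierReport",
  representation(table = "data.frame", flagged = "character",
                 iterations = "integer", ratio = "numeric",
                 kSd = "numeric", seed = "integer")
)

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf("OutlierReport: %d samples screened (%d iterations @ %.0f%%), %d flagged\n",
              nrow(object@table), object@iterations, 100 * object@ratio,
              length(object@flagged)))
  if (length(object@flagged))
    cat("  flagged:", paste(object@flagged, collapse = ", "), "\n")
})

#' @describeIn OutlierReport flagged sample ids
#' @param object an \code{OutlierReport}
#' @export
flaggedSamples <- function(object) object@flagged

#' @describeIn OutlierReport per-sample residual statistics
#' @export
outlierTable <- function(object) object@table

#' SelectionResult: output of a wavelength-selection algorithm
#'
#' @slot method method name (uve, cars, frog, mwpls, iriv).
#' @slot selected sorted unique channel indices into the preprocessed axis.
#' @slot score per-channel diagnostic score (reliability, selection
#'   probability, or window RMSECV profile depending on the method).
#' @slot hyperparameters named list of the hyperparameters used.
#' @slot seed RNG seed used.
#'
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(method = "character", selected = "integer",
                 score = "numeric", hyperparameters = "list",
                 seed = "integer")
)

setValidity("SelectionResult", function(object) {
  s <- object@selected
  if (anyDuplicated(s)) return("selected indices must be unique")
  if (is.unsorted(s)) return("selected indices must be sorted")
  if (length(s) && (min(s) < 1)) return("selected indices must be >= 1")
  TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult [%s]: %d channels selected\n",
              object@method, length(object@selected)))
})

#' @describeIn SelectionResult selected channel indices
#' @param object a \code{SelectionResult}
#' @export
selectedChannels <- function(object) object@selected

#' @describeIn SelectionResult per-channel diagnostic score
#' @export
selectionScore <- function(object) object@score
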