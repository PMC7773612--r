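#' Crop a spectra set to wavelength intervals
#'
#' Retains exactly the channels whose wavelength lies inside one of the closed
#' intervals, preserving channel order. Contiguity is re-derived after
#' cropping: channels that were adjacent on the original axis stay in one
#' segment, and a new segment starts at every gap, so segment-wise filters
#' never smooth across excluded regions.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @param ranges list of \code{c(low, high)} nm intervals or a two-column
#'   matrix.
#' @return the cropped \linkS4class{SpectraSet}.
#' @export
cropRanges <- function(set, ranges) {
  if (is.list(ranges)) ranges <- do.call(rbind, ranges)
  ranges <- matrix(as.numeric(ranges), ncol = 2)
  wl <- wavelengths(set)
  keep <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(ranges)))
    keep <- keep | (wl >= ranges[i, 1] & wl <= ranges[i, 2])
  if (!any(keep)) stop("cropping removed every channel")
  idx <- which(keep)
  seg <- cumsum(c(1L, diff(idx) != 1L))
  SpectraSet(spectraValues(set)[, idx, drop = FALSE], wl[idx],
             sampleIds = sampleIds(set), groups = replicateGroups(set),
             segments = as.integer(seg))
}

#' Standard normal variate correction of one spectrum
#'
#' Centers the spectrum to zero mean and scales to unit sample standard
#' deviation across its channels; invariant to affine distortions
#' \code{a*x + b} with \code{a > 0}.
#'
#' @param x numeric spectrum (>= 2 channels).
#' @return corrected spectrum.
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("snv needs at least 2 channels")
  s <- stats::sd(x)
  if (s < .Machine$double.eps) stop("constant spectrum: zero spread")
  (x - mean(x)) / s
}

#' Robust normal variate correction of one spectrum
#'
#' Centers on the \code{percentile}-th percentile and scales by the standard
#' deviation of the channels at or below that percentile, so large positive
#' spikes barely influence the correction (unlike SNV).
#'
#' @param x numeric spectrum (>= 4 channels).
#' @param percentile centering percentile in (0, 100); default 25.
#' @return corrected spectrum.
#' @export
rnv <- function(x, percentile = 25) {
  if (length(x) < 4) stop("rnv needs at least 4 channels")
  q <- stats::quantile(x, percentile / 100, names = FALSE, type = 7)
  low <- x[x <= q]
  s <- stats::sd(low)
  if (!is.finite(s) || s < .Machine$double.eps)
    stop("zero spread below the centering percentile")
  (x - q) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum is least-squares fit to \code{x = a + b * reference} and
#' replaced by \code{(x - a) / b}. The reference defaults to the channel-wise
#' mean of the set; pass the stored training-set reference when correcting
#' test spectra so no information leaks from the test set.
#'
#' @param set a \linkS4class{SpectraSet} (>= 2 spectra when \code{reference}
#'   is omitted).
#' @param reference optional reference spectrum on the same axis.
#' @return the corrected \linkS4class{SpectraSet}; the reference used is
#'   attached as attribute \code{"mscReference"}.
#' @export
msc <- function(set, reference = NULL) {
  v <- spectraValues(set)
  if (is.null(reference)) {
    if (nrow(v) < 2) stop("msc needs >= 2 spectra when no reference is given")
    reference <- colMeans(v)
  }
  if (length(reference) != ncol(v)) stop("reference length must match axis")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- v
  for (i in seq_len(nrow(v))) {
    b <- sum(rc * (v[i, ] - mean(v[i, ]))) / denom
    if (abs(b) < 1e-12)
      stop(sprintf("flat fit (b ~ 0) for spectrum '%s'", sampleIds(set)[i]))
    a <- mean(v[i, ]) - b * mean(reference)
    out[i, ] <- (v[i, ] - a) / b
  }
  res <- SpectraSet(out, wavelengths(set), sampleIds = sampleIds(set),
                    groups = replicateGroups(set), segments = segmentIds(set))
  attr(res, "mscReference") <- reference
  res
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Applies an SG filter of the given window, polynomial order and derivative
#' order to every spectrum, independently within each contiguous wavelength
#' segment (no smoothing across crop gaps). Derivatives are scaled by the
#' channel spacing so output units are intensity per nm^deriv. Edge channels
#' are evaluated from the local polynomial fit, keeping the channel count
#' constant.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @param window odd window length in channels; every segment must be at
#'   least this long.
#' @param polyorder polynomial order (< window).
#' @param deriv derivative order (<= polyorder).
#' @return the filtered \linkS4class{SpectraSet}.
#' @export
savitzkyGolay <- function(set, window, polyorder, deriv = 0) {
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  wl <- wavelengths(set)
  seg <- segmentIds(set)
  v <- spectraValues(set)
  out <- v
  for (s in unique(seg)) {
    idx <- which(seg == s)
    if (length(idx) < window)
      stop(sprintf("segment %d (%g-%g nm) shorter than window %d",
                   s, min(wl[idx]), max(wl[idx]), window))
    ts <- mean(diff(wl[idx]))
    A <- sgFilterMatrix(length(idx), window, polyorder, deriv, ts)
    out[, idx] <- v[, idx, drop = FALSE] %*% t(A)
  }
  SpectraSet(out, wl, sampleIds = sampleIds(set),
             groups = replicateGroups(set), segments = seg)
}

# Dense L x L Savitzky-Golay filtering matrix reproducing
# signal::sgolayfilt semantics (polynomial-fit edge rows, convolution with
# the central projection row in the interior) so a whole spectra matrix is
# filtered with one matrix product.
sgFilterMatrix <- function(L, window, polyorder, deriv, ts) {
  F <- unclass(signal::sgolay(p = polyorder, n = window, m = deriv, ts = ts))
  k <- floor(window / 2)
  A <- matrix(0, L, L)
  for (i in seq_len(k)) A[i, seq_len(window)] <- F[i, ]
  mid <- F[k + 1, ]
  for (i in seq.int(k + 1, L - k)) A[i, (i - k):(i + k)] <- mid
  for (i in seq.int(L - k + 1, L)) A[i, (L - window + 1):L] <- F[i - L + window, ]
  A
}

#' Apply a scatter-correction method to a spectra set
#'
#' Dispatches to \code{\link{snv}}, \code{\link{rnv}} or \code{\link{msc}}
#' per spectrum over the concatenated (cropped) channels; \code{"none"} is the
#' identity.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @param method one of none, snv, rnv, msc.
#' @param reference optional MSC reference (training-set mean) for
#'   \code{method = "msc"}.
#' @param percentile RNV centering percentile.
#' @return the corrected \linkS4class{SpectraSet}.
#' @export
scatterCorrect <- function(set, method = c("none", "snv", "rnv", "msc"),
                           reference = NULL, percentile = 25) {
  method <- match.arg(method)
  if (method == "none") return(set)
  if (method == "msc") return(msc(set, reference))
  v <- spectraValues(set)
  f <- if (method == "snv") snv else function(x) rnv(x, percentile)
  out <- t(apply(v, 1, f))
  SpectraSet(out, wavelengths(set), sampleIds = sampleIds(set),
             groups = replicateGroups(set), segments = segmentIds(set))
}

#' Enumerate preprocessing configurations
#'
#' Builds the Cartesian product of all non-empty combinations of the candidate
#' wavelength intervals, the scatter-correction options, and the valid
#' Savitzky-Golay (window, polyorder, deriv) triples (triples with
#' \code{polyorder >= window} or \code{deriv > polyorder} are excluded).
#' Ordering is deterministic: range subsets in binary-counter order over the
#' interval list, then scatter, then window, polyorder, deriv.
#'
#' @param ranges list of candidate \code{c(low, high)} nm intervals.
#' @param scatter character vector of scatter options.
#' @param windows,polyorders,derivs SG parameter candidates.
#' @return list of \linkS4class{PreprocessConfig} objects.
#' @export
enumerateConfigs <- function(ranges = list(c(1060, 1172), c(1211, 1366),
                                           c(1560, 1840)),
                             scatter = c("none", "snv", "rnv", "msc"),
                             windows = seq(5, 19, 2), polyorders = c(2, 3),
                             derivs = 0:2) {
  n <- length(ranges)
  subsets <- lapply(seq_len(2^n - 1), function(m) {
    ranges[which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)]
  })
  configs <- list()
  for (rs in subsets) for (sc in scatter) for (w in windows)
    for (p in polyorders) for (d in derivs) {
      if (p >= w || d > p) next
      configs[[length(configs) + 1L]] <-
        preprocessConfig(rs, scatter = sc, sgWindow = w, sgPolyOrder = p,
                         sgDeriv = d)
    }
  configs
}

#' Apply a full preprocessing configuration
#'
#' Stages run in the order crop, scatter correction, Savitzky-Golay. For MSC
#' the reference should be the training-set mean on the cropped axis (see
#' \code{\link{pipelineReference}}); when omitted it is computed from
#' \code{set} itself.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @param reference optional MSC reference on the cropped axis.
#' @return the preprocessed \linkS4class{SpectraSet}.
#' @export
applyPipeline <- function(set, config, reference = NULL) {
  validObject(config)
  out <- cropRanges(set, config@ranges)
  out <- scatterCorrect(out, config@scatter, reference = reference,
                        percentile = config@rnvPercentile)
  savitzkyGolay(out, config@sgWindow, config@sgPolyOrder, config@sgDeriv)
}

#' Training-set MSC reference for a configuration
#'
#' The channel-wise mean of the training spectra after cropping to the
#' configuration's ranges; stored and reused when preprocessing test spectra
#' so the correction never sees test data.
#'
#' @param trainSet training \linkS4class{SpectraSet}.
#' @param config a \linkS4class{PreprocessConfig}.
#' @return numeric reference spectrum on the cropped axis.
#' @export
pipelineReference <- function(trainSet, config) {
  colMeans(spectraValues(cropRanges(trainSet, config@ranges)))
}

#' Serialize / deserialize a PreprocessConfig
#'
#' @param config a \linkS4class{PreprocessConfig}.
#' @return \code{configToList}: a plain list with keys \code{ranges},
#'   \code{scatter}, \code{sg} (window, polyorder, deriv) and
#'   \code{rnv_percentile}; round-trips bit-exactly through
#'   \code{configFromList} and JSON/YAML.
#' @export
configToList <- function(config) {
  list(ranges = unname(lapply(seq_len(nrow(config@ranges)),
                              function(i) as.numeric(config@ranges[i, ]))),
       scatter = config@scatter,
       sg = list(window = as.integer(config@sgWindow),
                 polyorder = as.integer(config@sgPolyOrder),
                 deriv = as.integer(config@sgDeriv)),
       rnv_percentile = config@rnvPercentile)
}

#' @rdname configToList
#' @param x a list as produced by \code{configToList} (or parsed from
#'   JSON/YAML).
#' @export
configFromList <- function(x) {
  preprocessConfig(x$ranges, scatter = x$scatter, sgWindow = x$sg$window,
                   sgPolyOrder = x$sg$polyorder, sgDeriv = x$sg$deriv,
                   rnvPercentile = if (is.null(x$rnv_percentile)) 25
                                   else x$rnv_percentile)
}

# one-line deterministic serialization used for tie-breaking and reports
configLabel <- function(config) {
  rtxt <- paste(apply(config@ranges, 1, function(r) sprintf("%g-%g", r[1], r[2])),
                collapse = "+")
  sprintf("%s|%s|sg%d/%d/%d", rtxt, config@scatter, config@sgWindow,
          config@sgPolyOrder, config@sgDeriv)
}
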