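#' Monte Carlo cross-validation for PLS component selection
#'
#' Repeatedly draws a random training subset (without replacement, size
#' \code{round(trainRatio * n)}, half-up rounding), fits a NIPALS model at the
#' maximum component count, scores the held-out samples at every component
#' count from one fit, and averages the validation RMSE per count over
#' iterations. The chosen component count minimises the mean RMSECV (smallest
#' count on ties); with \code{oneSe = TRUE} the smallest count within one
#' standard error of the minimum is chosen instead.
#'
#' @param X samples x channels matrix.
#' @param y numeric response.
#' @param maxComp largest component count to evaluate.
#' @param iterations number of random splits (default 1000).
#' @param trainRatio training fraction per split (default 0.9).
#' @param seed RNG seed.
#' @param oneSe use the one-standard-error rule instead of the global
#'   minimum.
#' @return a \linkS4class{CvCurve}.
#' @export
mccv <- function(X, y, maxComp, iterations = 1000L, trainRatio = 0.9,
                 seed = 1L, oneSe = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  nTrain <- roundHalfUp(trainRatio * n)
  if (nTrain < maxComp + 1)
    stop("training subset too small for the requested component count")
  if (nTrain >= n) stop("validation set is empty at this train ratio")
  errs <- matrix(NA_real_, iterations, maxComp)
  withSeed(seed, {
    for (it in seq_len(iterations)) {
      tr <- sample.int(n, nTrain)
      va <- setdiff(seq_len(n), tr)
      path <- nipalsPath(X[tr, , drop = FALSE], y[tr], maxComp)
      for (a in seq_len(maxComp))
        errs[it, a] <- rmse(y[va], path$predictAt(a, X[va, , drop = FALSE]))
    }
  })
  m <- colMeans(errs)
  s <- apply(errs, 2, stats::sd)
  best <- which.min(m)  # smallest index on ties
  chosen <- if (oneSe) {
    thr <- m[best] + s[best] / sqrt(iterations)
    min(which(m <= thr))
  } else best
  new("CvCurve", components = seq_len(maxComp), meanRmsecv = m,
      sdRmsecv = s, nComp = as.integer(chosen),
      iterations = as.integer(iterations), trainRatio = trainRatio,
      seed = as.integer(seed))
}

#' Monte Carlo outlier screening
#'
#' Repeatedly fits a PLS model on a random subset (default 75% of the data)
#' and records the absolute prediction error of every held-out sample. A
#' sample is flagged when its mean held-out residual exceeds the cohort mean
#' plus \code{kSd} cohort standard deviations of the mean residuals (with
#' \code{axes = "both"}, samples extreme on the residual-spread axis are
#' flagged analogously). The full per-sample table is always returned.
#'
#' @param X samples x channels matrix.
#' @param y numeric response.
#' @param nComp components for the screening fits.
#' @param iterations number of random subsets (default 2500).
#' @param ratio training fraction per subset (default 0.75).
#' @param seed RNG seed.
#' @param kSd flagging threshold in cohort standard deviations (default 3;
#'   \code{Inf} disables flagging).
#' @param axes \code{"mean"} (default) flags on the mean-residual axis;
#'   \code{"both"} also flags samples extreme on the residual-spread axis.
#' @param sampleIds optional ids for reporting (default row numbers).
#' @return an \linkS4class{OutlierReport}.
#' @export
detectOutliers <- function(X, y, nComp, iterations = 2500L, ratio = 0.75,
                           seed = 1L, kSd = 3, axes = c("mean", "both"),
                           sampleIds = as.character(seq_len(nrow(X)))) {
  axes <- match.arg(axes)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  nTrain <- roundHalfUp(ratio * n)
  if (nTrain < nComp + 1) stop("subset too small for nComp")
  if (nTrain >= n) stop("no held-out samples at this ratio")
  resSum <- numeric(n); resSumSq <- numeric(n); resN <- integer(n)
  withSeed(seed, {
    for (it in seq_len(iterations)) {
      tr <- sample.int(n, nTrain)
      va <- setdiff(seq_len(n), tr)
      path <- nipalsPath(X[tr, , drop = FALSE], y[tr], nComp)
      r <- abs(y[va] - path$predictAt(nComp, X[va, , drop = FALSE]))
      resSum[va] <- resSum[va] + r
      resSumSq[va] <- resSumSq[va] + r^2
      resN[va] <- resN[va] + 1L
    }
  })
  never <- resN == 0
  if (any(never))
    warning("samples never held out: ",
            paste(sampleIds[never], collapse = ", "))
  mr <- ifelse(resN > 0, resSum / resN, NA_real_)
  sr <- ifelse(resN > 1,
               sqrt(pmax(0, (resSumSq - resN * mr^2) / (resN - 1))),
               NA_real_)
  ok <- !is.na(mr)
  flag <- rep(FALSE, n)
  if (is.finite(kSd) && sum(ok) > 2) {
    # primary rule: mean held-out residual above cohort mean + kSd * sd.
    # The residual-spread axis is reported always but only contributes to
    # flagging when axes = "both": on well-behaved data its distribution is
    # heavy-tailed and would dominate the false-flag rate.
    mThr <- mean(mr[ok]) + kSd * stats::sd(mr[ok])
    flag[ok] <- mr[ok] > mThr
    if (axes == "both") {
      sThr <- mean(sr[ok], na.rm = TRUE) +
        kSd * stats::sd(sr[ok], na.rm = TRUE)
      flag[ok] <- flag[ok] | (!is.na(sr[ok]) & sr[ok] > sThr)
    }
  }
  tab <- data.frame(sample_id = sampleIds, mean_residual = mr,
                    sd_residual = sr, n_heldout = resN, flagged = flag,
                    stringsAsFactors = FALSE)
  new("OutlierReport", table = tab, flagged = sampleIds[flag],
      iterations = as.integer(iterations), ratio = ratio, kSd = kSd,
      seed = as.integer(seed))
}

#' Preprocessing grid search
#'
#' Applies every candidate \linkS4class{PreprocessConfig} to the (replicate-
#' averaged) training spectra, runs Monte Carlo cross-validation on each, and
#' ranks configurations by the minimum mean RMSECV attained at their chosen
#' component count. Ties are broken by position in \code{configs}
#' (serialization order). Configurations whose preprocessing fails (e.g. a
#' segment shorter than the SG window) are recorded as failed and excluded
#' from the ranking; the search never aborts.
#'
#' @param spectra training \linkS4class{SpectraSet} (one row per location).
#' @param references reference data.frame with a \code{location_id} column.
#' @param configs list of \linkS4class{PreprocessConfig} objects.
#' @param constituent reference column to model.
#' @param maxComp largest component count for MCCV.
#' @param iterations,trainRatio MCCV settings.
#' @param seed RNG seed; every configuration is evaluated on the same random
#'   splits so RMSECV comparisons are paired.
#' @return list with \code{ranking} (data.frame: rank, config label, chosen
#'   n_comp, rmsecv, status), \code{curves} (CvCurve per successful config, in
#'   ranking order) and \code{best} (the winning config).
#' @export
gridSearch <- function(spectra, references, configs, constituent,
                       maxComp = 10L, iterations = 50L, trainRatio = 0.9,
                       seed = 1L) {
  if (!length(configs)) stop("configs must be non-empty")
  ids <- sampleIds(spectra)
  y <- references[[constituent]][match(ids, references$location_id)]
  if (anyNA(y)) stop("missing reference values for some spectra")
  rows <- vector("list", length(configs))
  curves <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    res <- tryCatch({
      pp <- applyPipeline(spectra, cfg)
      mc <- min(maxComp, nrow(spectraValues(pp)) - 2L, nChannels(pp))
      # identical splits for every configuration: RMSECV comparisons are
      # paired, and identical configs tie exactly (broken by list order)
      cv <- mccv(spectraValues(pp), y, mc, iterations = iterations,
                 trainRatio = trainRatio, seed = seed)
      list(cv = cv, err = NULL)
    }, error = function(e) list(cv = NULL, err = conditionMessage(e)))
    if (is.null(res$err)) {
      cv <- res$cv
      rows[[i]] <- data.frame(config = configLabel(cfg), index = i,
                              n_comp = cv@nComp,
                              rmsecv = min(cv@meanRmsecv),
                              status = "ok", stringsAsFactors = FALSE)
      curves[[i]] <- cv
    } else {
      rows[[i]] <- data.frame(config = configLabel(cfg), index = i,
                              n_comp = NA_integer_, rmsecv = NA_real_,
                              status = paste("failed:", res$err),
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  okIdx <- which(tab$status == "ok")
  ord <- okIdx[order(tab$rmsecv[okIdx], tab$index[okIdx])]
  ranking <- rbind(tab[ord, ], tab[setdiff(seq_len(nrow(tab)), ord), ])
  ranking$rank <- c(seq_along(ord),
                    rep(NA_integer_, nrow(tab) - length(ord)))
  rownames(ranking) <- NULL
  if (!length(ord)) stop("every configuration failed preprocessing")
  list(ranking = ranking, curves = curves[ord], best = configs[[ranking$index[1]]])
}
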