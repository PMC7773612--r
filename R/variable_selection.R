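# Wavelength-selection algorithms for PLS calibration: UVE, CARS, random
# frog, MWPLS and IRIV over a common SelectionResult interface. Fidelity
# target is the algorithmic skeleton of each method, validated by
# planted-signal recovery; hyperparameters are exposed and logged.

# cheap Monte Carlo RMSECV used inside selection loops: identical splits for
# identical seeds, so subset comparisons are paired
quickRmsecv <- function(X, y, nComp, iterations = 10L, ratio = 0.8,
                        seed = 1L, details = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  nTrain <- roundHalfUp(ratio * n)
  nComp <- max(1L, min(nComp, nTrain - 1L, ncol(X)))
  e <- numeric(iterations)
  withSeed(seed, {
    for (it in seq_len(iterations)) {
      tr <- sample.int(n, nTrain)
      va <- setdiff(seq_len(n), tr)
      path <- nipalsPath(X[tr, , drop = FALSE], y[tr], nComp)
      e[it] <- rmse(y[va], path$predictAt(nComp, X[va, , drop = FALSE]))
    }
  })
  if (details) list(mean = mean(e), se = stats::sd(e) / sqrt(iterations))
  else mean(e)
}

#' Uninformative variable elimination (UVE)
#'
#' Augments the predictors with \code{nNoise} tiny-amplitude uniform noise
#' channels, refits the PLS model on Monte Carlo subsets, and computes a
#' reliability score \code{c_j = mean(b_j) / sd(b_j)} per channel from the
#' collected regression coefficients. Real channels whose |reliability|
#' exceeds the largest |reliability| among the noise channels are selected.
#'
#' @param X samples x channels matrix.
#' @param y response.
#' @param nComp PLS components for the resampled fits.
#' @param nNoise number of artificial noise channels (default
#'   \code{ncol(X)}).
#' @param iterations Monte Carlo resampling count (default 100).
#' @param ratio subset fraction per fit (default 0.8).
#' @param noiseAmplitude amplitude of the noise channels (default 1e-10, small
#'   enough not to perturb the model).
#' @param seed RNG seed.
#' @return a \linkS4class{SelectionResult} with the reliability scores.
#' @export
uve <- function(X, y, nComp, nNoise = ncol(X), iterations = 100L,
                ratio = 0.8, noiseAmplitude = 1e-10, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  nTrain <- roundHalfUp(ratio * n)
  B <- matrix(NA_real_, iterations, p + nNoise)
  # noise drawn under a derived seed so it cannot collide with any stream the
  # caller used to build X or y
  noise <- withSeed(deriveSeed(seed, 77731L),
                    matrix(stats::runif(n * nNoise, 0, noiseAmplitude),
                           n, nNoise))
  withSeed(seed, {
    Xa <- cbind(X, noise)
    k <- max(1L, min(nComp, nTrain - 1L, ncol(Xa)))
    for (it in seq_len(iterations)) {
      tr <- sample.int(n, nTrain)
      B[it, ] <- fitNipals(Xa[tr, , drop = FALSE], y[tr], k)@coefficients
    }
  })
  mB <- colMeans(B)
  sB <- apply(B, 2, stats::sd)
  rel <- ifelse(sB > 0, mB / sB, NA_real_)
  cutoff <- max(abs(rel[(p + 1):(p + nNoise)]), na.rm = TRUE)
  sel <- which(!is.na(rel[1:p]) & abs(rel[1:p]) > cutoff)
  new("SelectionResult", method = "uve", selected = as.integer(sort(sel)),
      score = rel[1:p],
      hyperparameters = list(nComp = nComp, nNoise = nNoise,
                             iterations = iterations, ratio = ratio,
                             noiseAmplitude = noiseAmplitude,
                             cutoff = cutoff),
      seed = as.integer(seed))
}

#' CARS retained-channel schedule
#'
#' The exponentially decreasing function fixing the fraction of channels kept
#' at each CARS iteration: \code{r_i = a * exp(-k * i)} with \code{a} and
#' \code{k} solved so that \code{r_1 = 1} (all channels) and
#' \code{r_N = 2 / p} (two channels).
#'
#' @param iterations number of CARS iterations N.
#' @param p number of channels.
#' @return numeric vector of retained fractions, length \code{iterations}.
#' @export
carsSchedule <- function(iterations, p) {
  k <- log(p / 2) / (iterations - 1)
  a <- exp(k)
  a * exp(-k * seq_len(iterations))
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' At each iteration a PLS model is fit on a Monte Carlo sample of the data
#' restricted to the surviving channels; channels are then reduced by forced
#' selection (keeping the top fraction of the schedule by |coefficient|)
#' followed by adaptive reweighted sampling proportional to |coefficient|.
#' Every iteration's subset is scored by Monte Carlo RMSECV and the best
#' subset over all iterations is returned.
#'
#' @param X samples x channels matrix.
#' @param y response.
#' @param nComp PLS components (reduced automatically when a subset becomes
#'   smaller than the component count; reductions are logged in the
#'   hyperparameters).
#' @param iterations number of CARS iterations (default 50).
#' @param ratio Monte Carlo sample fraction per fit (default 0.8).
#' @param cvIterations splits used to score each subset (default 10).
#' @param seed RNG seed.
#' @return a \linkS4class{SelectionResult}; the score is each channel's
#'   survival frequency across iterations.
#' @export
cars <- function(X, y, nComp, iterations = 50L, ratio = 0.8,
                 cvIterations = 10L, seed = 1L) {
  if (iterations < 2) stop("cars needs at least 2 iterations")
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  sched <- carsSchedule(iterations, p)
  nTrain <- roundHalfUp(ratio * n)
  subsets <- vector("list", iterations)
  errs <- numeric(iterations)
  errSes <- numeric(iterations)
  counts <- integer(p)
  reductions <- 0L
  withSeed(seed, {
    current <- seq_len(p)
    for (i in seq_len(iterations)) {
      keepN <- max(2L, round(sched[i] * p))
      tr <- sample.int(n, nTrain)
      k <- min(nComp, length(current), nTrain - 1L)
      if (k < nComp) reductions <- reductions + 1L
      fit <- fitNipals(X[tr, current, drop = FALSE], y[tr], max(1L, k))
      w <- abs(fit@coefficients)
      # forced selection: top keepN by |b|
      if (length(current) > keepN) {
        ord <- order(w, decreasing = TRUE)
        current <- current[ord[seq_len(keepN)]]
        w <- w[ord[seq_len(keepN)]]
      }
      # adaptive reweighted sampling: keepN weighted draws with replacement
      if (sum(w) > 0) {
        pick <- unique(sample.int(length(current), keepN, replace = TRUE,
                                  prob = w / sum(w)))
        current <- sort(current[pick])
      } else current <- sort(current)
      subsets[[i]] <- current
      counts[current] <- counts[current] + 1L
      # identical CV splits for every iteration so subset scores are paired
      ei <- quickRmsecv(X[, current, drop = FALSE], y,
                        min(nComp, length(current)),
                        iterations = cvIterations,
                        seed = deriveSeed(seed, 10000L), details = TRUE)
      errs[i] <- ei$mean
      errSes[i] <- ei$se
    }
  })
  # parsimony rule: among subsets within one standard error of the minimum
  # RMSECV, return the smallest
  minIdx <- which.min(errs)
  tol <- errs[minIdx] + errSes[minIdx]
  cand <- which(errs <= tol)
  best <- cand[which.min(lengths(subsets[cand]))]
  new("SelectionResult", method = "cars",
      selected = as.integer(subsets[[best]]),
      score = counts / iterations,
      hyperparameters = list(nComp = nComp, iterations = iterations,
                             ratio = ratio, cvIterations = cvIterations,
                             bestIteration = best, bestRmsecv = errs[best],
                             nCompReductions = reductions),
      seed = as.integer(seed))
}

#' Random frog wavelength selection
#'
#' A reversible-jump-style chain over channel subsets. From the current
#' subset a candidate is proposed by perturbing the subset size with a
#' normally distributed step (adding random channels from the complement or
#' dropping random members); the candidate is accepted when its
#' cross-validated RMSE improves, and otherwise with probability
#' current error / candidate error (capped at 1). The per-channel selection
#' probability is the visit frequency over the chain; the selected set is the
#' top \code{initSize} channels by probability.
#'
#' @param X samples x channels matrix.
#' @param y response.
#' @param nComp PLS components.
#' @param iterations chain length (default 1000).
#' @param initSize initial subset size (default: a tenth of the channels, at
#'   least \code{nComp + 2}).
#' @param varSd standard deviation of the size perturbation (default 2).
#' @param cvIterations splits per subset evaluation (default 3).
#' @param ratio training fraction per split.
#' @param seed RNG seed.
#' @return a \linkS4class{SelectionResult} with selection probabilities as
#'   the score.
#' @export
randomFrog <- function(X, y, nComp, iterations = 1000L,
                       initSize = max(nComp + 2L, round(ncol(X) / 10)),
                       varSd = 2, cvIterations = 3L, ratio = 0.8, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (initSize > p) stop("initSize exceeds the number of channels")
  minSize <- 2L
  visits <- numeric(p)
  sizeSum <- 0
  withSeed(seed, {
    current <- sort(sample.int(p, initSize))
    curErr <- quickRmsecv(X[, current, drop = FALSE], y,
                          min(nComp, length(current)),
                          iterations = cvIterations,
                          seed = deriveSeed(seed, 1L))
    for (i in seq_len(iterations)) {
      # candidate dimension drawn around the anchor size so the chain cannot
      # drift to very large subsets where the error surface is flat
      newSize <- as.integer(round(stats::rnorm(1, initSize, varSd)))
      newSize <- max(minSize, min(p, newSize))
      if (newSize > length(current)) {
        extra <- sampleInt(setdiff(seq_len(p), current),
                           newSize - length(current))
        cand <- sort(c(current, extra))
      } else if (newSize < length(current)) {
        # shrink guided by the fitted model: keep the channels with the
        # largest |coefficient| so removals target uninformative members
        k <- min(nComp, length(current), nrow(X) - 1L)
        fitc <- fitNipals(X[, current, drop = FALSE], y, max(1L, k))
        ord <- order(abs(fitc@coefficients), decreasing = TRUE)
        cand <- sort(current[ord[seq_len(newSize)]])
      } else {
        # same size: swap one member for a non-member
        drop1 <- sampleInt(current, 1)
        add1 <- sampleInt(setdiff(seq_len(p), current), 1)
        cand <- sort(c(setdiff(current, drop1), add1))
      }
      candErr <- quickRmsecv(X[, cand, drop = FALSE], y,
                             min(nComp, length(cand)),
                             iterations = cvIterations,
                             seed = deriveSeed(seed, 1L))
      accept <- candErr < curErr ||
        stats::runif(1) < min(1, curErr / candErr)
      if (accept) { current <- cand; curErr <- candErr }
      visits[current] <- visits[current] + 1
      sizeSum <- sizeSum + length(current)
    }
  })
  prob <- visits / iterations
  thr <- sort(prob, decreasing = TRUE)[initSize]
  sel <- which(prob >= thr)
  if (length(sel) > initSize)  # trim ties deterministically by index
    sel <- sel[seq_len(initSize)]
  new("SelectionResult", method = "frog", selected = as.integer(sort(sel)),
      score = prob,
      hyperparameters = list(nComp = nComp, iterations = iterations,
                             initSize = initSize, varSd = varSd,
                             cvIterations = cvIterations, ratio = ratio,
                             meanSubsetSize = sizeSum / iterations),
      seed = as.integer(seed))
}

#' Moving window PLS (MWPLS)
#'
#' Fits a PLS model on every contiguous channel window and records its Monte
#' Carlo RMSECV (identical splits across windows so the comparison is
#' paired); the window with the minimum RMSECV is selected. The diagnostic
#' score is the per-start-position RMSECV profile.
#'
#' @param X samples x channels matrix.
#' @param y response.
#' @param nComp PLS components (window must be at least \code{nComp + 1}).
#' @param window window width in channels (default 15).
#' @param cvIterations splits per window (default 10).
#' @param ratio training fraction per split.
#' @param seed CV seed (the method itself is deterministic given it).
#' @return a \linkS4class{SelectionResult}; \code{selectionScore} holds the
#'   RMSECV profile (length \code{n_channels - window + 1}).
#' @export
mwpls <- function(X, y, nComp, window = 15L, cvIterations = 10L,
                  ratio = 0.9, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (window > p) stop("window exceeds the number of channels")
  if (window < nComp + 1) stop("window must be at least nComp + 1")
  starts <- seq_len(p - window + 1L)
  profile <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    quickRmsecv(X[, idx, drop = FALSE], y, nComp,
                iterations = cvIterations, ratio = ratio, seed = seed)
  }, numeric(1))
  best <- which.min(profile)
  sel <- best:(best + window - 1L)
  new("SelectionResult", method = "mwpls", selected = as.integer(sel),
      score = profile,
      hyperparameters = list(nComp = nComp, window = window,
                             cvIterations = cvIterations, ratio = ratio,
                             bestStart = best, bestRmsecv = profile[best]),
      seed = as.integer(seed))
}

#' Iteratively retaining informative variables (IRIV)
#'
#' Rounds of balanced binary-matrix sampling: each round draws an inclusion
#' matrix in which every surviving channel appears in half the rows, fits a
#' PLS model per row on the included channels and records its cross-validated
#' RMSE. Channels whose inclusion lowers the error (rows-with mean below
#' rows-without mean) are retained - strongly informative when a Wilcoxon
#' rank-sum test is significant at \code{alpha}, weakly otherwise - while
#' channels whose inclusion raises the error (uninformative or interfering)
#' are removed. Rounds repeat on the retained set until nothing is removed,
#' then weakly informative channels are backward-eliminated one at a time,
#' keeping a removal only when it improves the RMSECV.
#'
#' @param X samples x channels matrix (>= 4 channels).
#' @param y response.
#' @param nComp PLS components.
#' @param alpha significance level of the rank test (default 0.05).
#' @param nRows rows of the binary sampling matrix per round (default 50,
#'   forced even).
#' @param maxRounds safety cap on rounds (default 10).
#' @param cvIterations splits per row evaluation (default 5).
#' @param ratio training fraction per split.
#' @param seed RNG seed.
#' @return a \linkS4class{SelectionResult}; the score is each channel's last
#'   observed error decrease (mean without minus mean with, NA once removed).
#' @export
iriv <- function(X, y, nComp, alpha = 0.05, nRows = 50L, maxRounds = 10L,
                 cvIterations = 5L, ratio = 0.8, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 4) stop("iriv needs at least 4 channels")
  nRows <- as.integer(nRows); if (nRows %% 2L == 1L) nRows <- nRows + 1L
  retained <- seq_len(p)
  weak <- integer(0)
  score <- rep(NA_real_, p)
  rounds <- 0L
  withSeed(seed, {
    repeat {
      rounds <- rounds + 1L
      pr <- length(retained)
      if (pr < 4 || rounds > maxRounds) break
      # balanced inclusion matrix: each column has nRows/2 ones
      M <- vapply(seq_len(pr), function(j) {
        v <- logical(nRows); v[sample.int(nRows, nRows %/% 2L)] <- TRUE; v
      }, logical(nRows))
      err <- rep(NA_real_, nRows)
      for (r in seq_len(nRows)) {
        sub <- retained[M[r, ]]
        if (length(sub) < 2) next
        # one split seed per round: row errors are paired, so differences
        # between rows reflect subset composition, not split luck
        err[r] <- quickRmsecv(X[, sub, drop = FALSE], y,
                              min(nComp, length(sub)),
                              iterations = cvIterations, ratio = ratio,
                              seed = deriveSeed(seed, 1000L * rounds))
      }
      dm <- numeric(pr); pv <- numeric(pr)
      for (j in seq_len(pr)) {
        ein <- err[M[, j]]; eout <- err[!M[, j]]
        dm[j] <- mean(eout, na.rm = TRUE) - mean(ein, na.rm = TRUE)
        pv[j] <- tryCatch(
          suppressWarnings(stats::wilcox.test(ein, eout)$p.value),
          error = function(e) 1)
      }
      score[retained] <- dm
      keep <- dm > 0
      weak <- retained[keep & pv >= alpha]
      newRetained <- retained[keep]
      if (length(newRetained) == length(retained)) { retained <- newRetained; break }
      retained <- newRetained
      if (!length(retained)) break
    }
    # backward elimination of weakly informative channels
    if (length(retained) >= 3 && length(weak)) {
      base <- quickRmsecv(X[, retained, drop = FALSE], y,
                          min(nComp, length(retained)),
                          iterations = cvIterations, ratio = ratio,
                          seed = deriveSeed(seed, 999983L))
      for (w in weak) {
        if (length(retained) <= 2) break
        cand <- setdiff(retained, w)
        e <- quickRmsecv(X[, cand, drop = FALSE], y,
                         min(nComp, length(cand)),
                         iterations = cvIterations, ratio = ratio,
                         seed = deriveSeed(seed, 999983L))
        if (e < base) { retained <- cand; base <- e; score[w] <- NA_real_ }
      }
    }
  })
  new("SelectionResult", method = "iriv",
      selected = as.integer(sort(retained)), score = score,
      hyperparameters = list(nComp = nComp, alpha = alpha, nRows = nRows,
                             rounds = rounds, cvIterations = cvIterations,
                             ratio = ratio),
      seed = as.integer(seed))
}

# registry used by compareMethods and the pipeline
runSelector <- function(method, X, y, nComp, seed, args = list()) {
  f <- switch(method,
              uve = uve, cars = cars, frog = randomFrog,
              mwpls = mwpls, iriv = iriv,
              stop("unknown selection method: ", method))
  do.call(f, c(list(X = X, y = y, nComp = nComp, seed = seed), args))
}

#' Compare PLS models with and without variable selection
#'
#' Builds the model-comparison table: a Base row (all channels) plus one row
#' per selection method. Each row refits PLS on the method's selected
#' channels with an MCCV-chosen component count and reports the training
#' Spearman rho, RMSEC, RMSECV, test Spearman rho, RMSEP and component count.
#' The best row is flagged by minimum RMSEP (ties broken by fewer
#' components). A failing method is recorded as failed and the comparison
#' continues.
#'
#' @param Xtrain,ytrain training predictors and response.
#' @param Xtest,ytest held-out test predictors and response (disjoint from
#'   training).
#' @param methods character vector among uve, cars, frog, mwpls, iriv (may be
#'   empty for a Base-only table).
#' @param maxComp largest component count for MCCV.
#' @param cvIterations MCCV iterations for component choice.
#' @param seed RNG seed (children derived per method).
#' @param methodArgs named list of per-method argument lists.
#' @return data.frame with columns method, rho_training, rmsec, rmsecv,
#'   rho_test, rmsep, n_comp, n_channels, best, status; the selection results
#'   are attached as attribute \code{"selections"}.
#' @export
compareMethods <- function(Xtrain, ytrain, Xtest, ytest,
                           methods = c("uve", "frog", "cars", "mwpls", "iriv"),
                           maxComp = 10L, cvIterations = 50L, seed = 1L,
                           methodArgs = list()) {
  Xtrain <- as.matrix(Xtrain); Xtest <- as.matrix(Xtest)
  evalModel <- function(cols, childSeed) {
    Xtr <- Xtrain[, cols, drop = FALSE]
    mc <- max(1L, min(maxComp, ncol(Xtr), nrow(Xtr) - 2L))
    cv <- mccv(Xtr, ytrain, mc, iterations = cvIterations,
               seed = childSeed)
    k <- cv@nComp
    fit <- fitNipals(Xtr, ytrain, k)
    yhatTr <- predict(fit, Xtr)
    yhatTe <- predict(fit, Xtest[, cols, drop = FALSE])
    data.frame(rho_training = spearmanRho(ytrain, yhatTr),
               rmsec = rmse(ytrain, yhatTr),
               rmsecv = cv@meanRmsecv[k],
               rho_test = spearmanRho(ytest, yhatTe),
               rmsep = rmse(ytest, yhatTe),
               n_comp = k, n_channels = length(cols))
  }
  rows <- list()
  selections <- list()
  base <- evalModel(seq_len(ncol(Xtrain)), deriveSeed(seed, 0L))
  rows[["Base"]] <- cbind(method = "Base", base, status = "ok")
  baseComp <- base$n_comp
  for (m in methods) {
    res <- tryCatch({
      selRes <- runSelector(m, Xtrain, ytrain, baseComp,
                            deriveSeed(seed, match(m, methods)),
                            args = if (!is.null(methodArgs[[m]]))
                              methodArgs[[m]] else list())
      sel <- selectedChannels(selRes)
      if (!length(sel)) stop("empty selection")
      selections[[m]] <- selRes
      cbind(method = toupper(m),
            evalModel(sel, deriveSeed(seed, 100L + match(m, methods))),
            status = "ok")
    }, error = function(e) {
      data.frame(method = toupper(m), rho_training = NA_real_,
                 rmsec = NA_real_, rmsecv = NA_real_, rho_test = NA_real_,
                 rmsep = NA_real_, n_comp = NA_integer_,
                 n_channels = NA_integer_,
                 status = paste("failed:", conditionMessage(e)))
    })
    rows[[m]] <- res
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab$status == "ok" & !is.na(tab$rmsep)
  tab$best <- FALSE
  if (any(ok)) {
    cand <- which(ok)
    cand <- cand[order(tab$rmsep[cand], tab$n_comp[cand])]
    tab$best[cand[1]] <- TRUE
  }
  attr(tab, "selections") <- selections
  tab
}
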