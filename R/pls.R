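#' Fit a PLS1 regression model by NIPALS
#'
#' Single-response partial least squares. Predictors and response are
#' mean-centered (never variance-scaled). Components are extracted by the
#' NIPALS recursion: the weight vector is the covariance direction
#' \code{t(Xres) \%*\% yres} normalised to unit length (for a single response
#' the inner loop converges in this one pass, so no iteration tolerance is
#' needed), scores are \code{Xres \%*\% w}, predictor and response loadings
#' come from least squares on the scores, and both residual matrices are
#' deflated. Collapsed regression coefficients are
#' \code{b = W (P'W)^{-1} q}.
#'
#' @param X samples x channels numeric matrix, no missing values.
#' @param y numeric response, one value per row of \code{X}.
#' @param nComp number of latent components, between 1 and
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @return a \linkS4class{PlsModel}.
#' @export
fitNipals <- function(X, y, nComp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  nComp <- as.integer(nComp)
  if (nComp < 1 || nComp > min(n - 1, p))
    stop(sprintf("nComp must be in [1, %d]", min(n - 1, p)))
  if (stats::sd(y) < .Machine$double.eps) stop("zero-variance response")

  xMean <- colMeans(X)
  yMean <- mean(y)
  Xr <- sweep(X, 2, xMean)
  yr <- y - yMean

  W <- matrix(0, p, nComp)
  P <- matrix(0, p, nComp)
  Tm <- matrix(0, n, nComp)
  q <- numeric(nComp)
  for (a in seq_len(nComp)) {
    w <- crossprod(Xr, yr)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      # residual covariance exhausted; stop early with the components found
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      nComp <- a - 1L
      break
    }
    w <- w / nw
    t_ <- Xr %*% w
    tt <- sum(t_^2)
    pvec <- crossprod(Xr, t_)[, 1] / tt
    qa <- sum(yr * t_) / tt
    Xr <- Xr - t_ %*% t(pvec)
    yr <- yr - qa * t_
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t_; q[a] <- qa
  }
  if (nComp < 1) stop("no extractable component (X'y vanishes)")
  # b = W (P'W)^{-1} q  (P'W is upper triangular with unit diagonal)
  b <- as.numeric(W %*% solve(crossprod(P, W), q))
  new("PlsModel", xMean = xMean, yMean = yMean, weights = W, loadings = P,
      yLoadings = q, coefficients = b,
      intercept = yMean - sum(xMean * b), scores = Tm, nComp = nComp)
}

#' Predict from a fitted PLS model
#'
#' \code{yhat = (X - xMean) b + yMean}; identical (to numerical precision) to
#' propagating latent scores through the y loadings.
#'
#' @param object a \linkS4class{PlsModel}.
#' @param newdata samples x channels matrix with the model's channel count.
#' @param via \code{"coefficients"} (default) or \code{"scores"} (latent
#'   route, mainly for verification).
#' @param ... unused.
#' @return numeric predictions, one per row.
#' @export
setMethod("predict", "PlsModel", function(object, newdata,
                                          via = c("coefficients", "scores"),
                                          ...) {
  via <- match.arg(via)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@xMean))
    stop(sprintf("channel mismatch: model has %d, data has %d",
                 length(object@xMean), ncol(X)))
  Xc <- sweep(X, 2, object@xMean)
  if (via == "coefficients")
    return(as.numeric(Xc %*% object@coefficients + object@yMean))
  # latent route: scores via R = W (P'W)^{-1}, then T q
  R <- object@weights %*% solve(crossprod(object@loadings, object@weights))
  Tn <- Xc %*% R
  as.numeric(Tn %*% object@yLoadings + object@yMean)
})

#' Root-mean-square error
#'
#' @param y,yhat equal-length numeric vectors (n >= 2).
#' @return \code{sqrt(mean((y - yhat)^2))}.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  sqrt(mean((y - yhat)^2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged); symmetric in its
#' arguments.
#'
#' @param y,yhat equal-length numeric vectors (n >= 3), neither constant.
#' @return rho in [-1, 1].
#' @export
spearmanRho <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(y) < .Machine$double.eps ||
      stats::sd(yhat) < .Machine$double.eps)
    stop("constant vector: rank correlation undefined")
  stats::cor(y, yhat, method = "spearman")
}

# --- internal: one NIPALS decomposition, predictions at every component count

# Returns a list with the decomposition and a function predictAt(k, X) used by
# cross-validation loops to score all component counts from a single fit.
nipalsPath <- function(X, y, maxComp) {
  fit <- fitNipals(X, y, maxComp)
  k <- fit@nComp
  # precompute collapsed coefficients at each component count
  PW <- crossprod(fit@loadings, fit@weights)
  coefs <- lapply(seq_len(k), function(a) {
    idx <- seq_len(a)
    as.numeric(fit@weights[, idx, drop = FALSE] %*%
                 solve(PW[idx, idx, drop = FALSE], fit@yLoadings[idx]))
  })
  list(fit = fit, nComp = k,
       predictAt = function(a, Xn) {
         a <- min(a, k)
         Xc <- sweep(as.matrix(Xn), 2, fit@xMean)
         as.numeric(Xc %*% coefs[[a]] + fit@yMean)
       })
}
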