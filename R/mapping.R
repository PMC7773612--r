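#' Assemble per-location predictions into a measurement grid
#'
#' Places each predicted (or measured) value at its (row, col) cell of the
#' measurement lattice; cells without a value stay background.
#'
#' @param predictions numeric values, one per location.
#' @param coordinates two-column matrix or data.frame of 0-based (row, col)
#'   cell coordinates, unique, inside \code{shape}.
#' @param shape integer \code{c(rows, cols)} (default the 9 x 14 meniscus
#'   lattice).
#' @return a \linkS4class{GridMap}.
#' @export
assembleGrid <- function(predictions, coordinates, shape = c(9L, 14L)) {
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != length(predictions))
    stop("one coordinate pair per prediction required")
  if (any(coordinates < 0) || any(coordinates[, 1] >= shape[1]) ||
      any(coordinates[, 2] >= shape[2]))
    stop("coordinates outside the grid")
  key <- coordinates[, 1] * shape[2] + coordinates[, 2]
  if (anyDuplicated(key)) stop("duplicate coordinates")
  vals <- matrix(NA_real_, shape[1], shape[2])
  meas <- matrix(FALSE, shape[1], shape[2])
  prov <- matrix("background", shape[1], shape[2])
  idx <- cbind(coordinates[, 1] + 1L, coordinates[, 2] + 1L)
  vals[idx] <- predictions
  meas[idx] <- TRUE
  prov[idx] <- "measured"
  new("GridMap", values = vals, measured = meas, provenance = prov)
}

#' Impute unmeasured grid cells from neighbour means
#'
#' Each unmeasured cell adjacent to at least one valued cell becomes the
#' arithmetic mean of its valued neighbours. Sweeps are repeated - each sweep
#' computed from the previous state only, so the result is order-independent -
#' until no unmeasured cell borders a valued cell; unreachable cells stay
#' background. Measured cells are never altered and imputed values always lie
#' within the range of the values they were computed from.
#'
#' @param grid a \linkS4class{GridMap} with at least one measured cell.
#' @param neighborhood 4 (default, edge-adjacent) or 8 (include diagonals).
#' @return the imputed \linkS4class{GridMap}.
#' @export
fillMissingNeighbors <- function(grid, neighborhood = 4) {
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  vals <- gridValues(grid)
  prov <- gridProvenance(grid)
  if (!any(prov == "measured")) stop("no measured cells to impute from")
  nr <- nrow(vals); nc <- ncol(vals)
  offs <- if (neighborhood == 4)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  repeat {
    valued <- prov %in% c("measured", "imputed")
    dim(valued) <- dim(prov)
    newVals <- vals; newProv <- prov
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (valued[i, j]) next
      acc <- numeric(0)
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && valued[ii, jj])
          acc <- c(acc, vals[ii, jj])
      }
      if (length(acc)) {
        newVals[i, j] <- mean(acc)
        newProv[i, j] <- "imputed"
        changed <- TRUE
      }
    }
    vals <- newVals; prov <- newProv
    if (!changed) break
  }
  new("GridMap", values = vals, measured = measuredMask(grid),
      provenance = prov)
}

#' Embed a grid in a square canvas and bilinearly interpolate
#'
#' Centers the grid inside a \code{canvasSide} x \code{canvasSide} matrix of
#' \code{background} values (offset \code{floor((canvas - grid)/2)} per axis),
#' then bilinearly interpolates the canvas node lattice (nodes 1 ..
#' canvasSide) at a step of \code{spacing} grid units per axis, producing an
#' interpolated matrix of side \code{(canvasSide - 1)/spacing + 1}; at the
#' default 20 / 0.01 this is 1901 x 1901. Interpolated values at node
#' positions equal the canvas entries exactly.
#'
#' @param grid a \linkS4class{GridMap} (background cells enter the canvas as
#'   \code{background}).
#' @param canvasSide side of the square canvas (default 20).
#' @param spacing interpolation step in grid units (default 0.01).
#' @param background background fill value (default 0).
#' @return a \linkS4class{CanvasMap}.
#' @export
embedAndInterpolate <- function(grid, canvasSide = 20L, spacing = 0.01,
                                background = 0) {
  vals <- gridValues(grid)
  nr <- nrow(vals); nc <- ncol(vals)
  if (nr > canvasSide || nc > canvasSide)
    stop("grid larger than the canvas")
  canvas <- matrix(background, canvasSide, canvasSide)
  offR <- floor((canvasSide - nr) / 2)
  offC <- floor((canvasSide - nc) / 2)
  block <- vals
  block[is.na(block)] <- background
  canvas[offR + seq_len(nr), offC + seq_len(nc)] <- block
  # bilinear interpolation on a regular node lattice is separable:
  # interp = R %*% canvas %*% t(R) with R the 1-D linear interpolation
  # operator from the nodes onto the fine grid
  R <- linearInterpMatrix(canvasSide, spacing)
  interp <- R %*% canvas %*% t(R)
  new("CanvasMap", canvas = canvas, interpolated = interp,
      spacing = spacing, background = background,
      offset = as.integer(c(offR, offC)))
}

# 1-D linear interpolation operator from node positions 1..side onto
# seq(1, side, by = spacing); each output point has at most two nonzero
# weights, and node positions map exactly onto the corresponding node
linearInterpMatrix <- function(side, spacing) {
  fine <- seq(1, side, by = spacing)
  lo <- pmin(floor(fine), side - 1L)
  frac <- fine - lo
  R <- matrix(0, length(fine), side)
  ix <- seq_along(fine)
  R[cbind(ix, lo)] <- 1 - frac
  R[cbind(ix, lo + 1L)] <- frac
  R
}

#' Per-cell relative error map between measured and predicted grids
#'
#' Percent error \code{100 * |pred - meas| / meas} on measured cells, with
#' summary statistics (min, max, mean, median) over the measured cells only.
#' Cells whose measured value is zero are excluded and reported.
#'
#' @param measured,predicted \linkS4class{GridMap}s of the same shape with
#'   identical measured masks.
#' @return list with \code{map} (matrix, NA off the measured cells),
#'   \code{summary} (named vector min/max/mean/median of percent errors) and
#'   \code{excluded} (count of zero-valued measured cells skipped).
#' @export
errorMap <- function(measured, predicted) {
  mv <- gridValues(measured); pv <- gridValues(predicted)
  if (!all(dim(mv) == dim(pv))) stop("grids differ in shape")
  mm <- measuredMask(measured)
  if (!identical(mm, measuredMask(predicted)))
    stop("measured masks differ")
  err <- matrix(NA_real_, nrow(mv), ncol(mv))
  usable <- mm & mv != 0
  err[usable] <- 100 * abs(pv[usable] - mv[usable]) / mv[usable]
  e <- err[usable]
  list(map = err,
       summary = c(min = min(e), max = max(e), mean = mean(e),
                   median = stats::median(e)),
       excluded = sum(mm & mv == 0))
}
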