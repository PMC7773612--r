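#' Read spectra from a delimited text file
#'
#' Expects a header row with \code{sample_id}, optionally
#' \code{replicate_group}, then one column per wavelength channel whose header
#' is the wavelength in nm. The delimiter (comma or tab) is sniffed from the
#' header line; lines starting with \code{#} (unit comments) are skipped.
#' Columns are reordered so the axis is ascending.
#'
#' @param path file path.
#' @return a \linkS4class{SpectraSet}.
#' @export
readSpectra <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no data in ", path)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column")
  meta <- intersect(c("sample_id", "replicate_group"), names(df))
  wlCols <- setdiff(names(df), meta)
  wl <- suppressWarnings(as.numeric(wlCols))
  if (anyNA(wl))
    stop("non-numeric wavelength headers: ",
         paste(wlCols[is.na(wl)], collapse = ", "))
  if (anyDuplicated(wl)) stop("duplicate wavelength columns")
  vals <- as.matrix(df[, wlCols, drop = FALSE])
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)
    stop("missing values in rows: ", paste(bad, collapse = ", "))
  }
  groups <- if ("replicate_group" %in% meta) df$replicate_group else df$sample_id
  SpectraSet(vals, wl, sampleIds = df$sample_id, groups = groups)
}

#' Write spectra to CSV
#'
#' Writes a unit comment line, then \code{sample_id}, \code{replicate_group}
#' and one column per wavelength with the nm value as header. Full double
#' precision is kept so a write/read round trip reproduces the matrix exactly.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSpectra <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavelengths in nm", con)
  hdr <- c("sample_id", "replicate_group",
           formatC(wavelengths(set), format = "g", digits = 17))
  writeLines(paste(hdr, collapse = ","), con)
  v <- spectraValues(set)
  for (i in seq_len(nrow(v))) {
    writeLines(paste(c(sampleIds(set)[i], replicateGroups(set)[i],
                       formatC(v[i, ], format = "g", digits = 17)),
                     collapse = ","), con)
  }
  invisible(path)
}

#' Read a constituent reference table
#'
#' CSV/TSV with columns \code{location_id}, constituent contents in % of wet
#' weight, and optional 0-based \code{row}, \code{col} grid coordinates.
#'
#' @param path file path.
#' @return a validated data.frame.
#' @export
readReferences <- function(path) {
  l1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", l1)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  validateReferenceTable(df)
  df
}

# invariants: ids unique, contents >= 0, water <= 100
validateReferenceTable <- function(df) {
  if (!"location_id" %in% names(df)) stop("missing 'location_id' column")
  if (anyDuplicated(df$location_id)) stop("location ids must be unique")
  num <- setdiff(names(df), c("location_id", "row", "col", "measured"))
  for (nm in num) {
    if (any(df[[nm]] < 0, na.rm = TRUE))
      stop(sprintf("negative content in column '%s'", nm))
  }
  if ("water" %in% names(df) && any(df$water > 100, na.rm = TRUE))
    stop("water content exceeds 100% of wet weight")
  invisible(df)
}

#' Average replicate measurements into representative spectra
#'
#' Collapses each replicate group to the channel-wise arithmetic mean of its
#' rows, producing one representative spectrum per measurement location.
#' Groups of size one pass through unchanged. Output rows are ordered by the
#' first appearance of each group.
#'
#' @param set a \linkS4class{SpectraSet}.
#' @return a \linkS4class{SpectraSet} with one row per replicate group; sample
#'   ids become the group labels.
#' @export
averageReplicates <- function(set) {
  g <- replicateGroups(set)
  ug <- unique(g)
  v <- spectraValues(set)
  out <- matrix(0, length(ug), ncol(v))
  for (i in seq_along(ug)) {
    rows <- which(g == ug[i])
    out[i, ] <- colMeans(v[rows, , drop = FALSE])
  }
  SpectraSet(out, wavelengths(set), sampleIds = ug, groups = ug,
             segments = segmentIds(set))
}
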