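#' Read spectra from disk
#'
#' Reads a spectral dataset plus its sample-metadata table into a validated
#' [SpectraSet-class]. Two formats are supported:
#'
#' * `csv_wide`: column 1 is the wavenumber axis (header `wavenumber_cm-1`),
#'   each further column one spectrum, named `<sample_id>_r<replicate>`.
#'   Lines starting with `#` are ignored.
#' * `jcamp_dx`: a single-block JCAMP-DX file with an `##XYDATA=(X++(Y..Y))`
#'   table in plain (AFFN) form, yielding one spectrum.
#'
#' The metadata CSV has one row per spectrum (columns `sample_id`,
#' `replicate`, `prep_class`, `label`) in spectrum-column order.
#'
#' @param path spectra file.
#' @param format `"csv_wide"` (default) or `"jcamp_dx"`.
#' @param meta_path metadata CSV.
#' @return a [SpectraSet-class].
#' @export
readSpectra <- function(path, format = c("csv_wide", "jcamp_dx"), meta_path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!file.exists(meta_path)) stop("file not found: ", meta_path)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (format == "csv_wide") {
    tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("format error: need a wavenumber column plus at least one spectrum")
    num <- vapply(tab, is.numeric, logical(1))
    if (!all(num))
      stop("parse error: non-numeric cells in column(s) ",
           paste(names(tab)[!num], collapse = ", "))
    wn <- tab[[1L]]
    A <- t(as.matrix(tab[, -1L, drop = FALSE]))
  } else {
    xy <- .readJcampXY(path)
    wn <- xy$x
    A <- matrix(xy$y, nrow = 1L)
  }
  if (nrow(meta) != nrow(A))
    stop("format error: metadata rows (", nrow(meta),
         ") do not match spectrum count (", nrow(A), ")")
  SpectraSet(A, wn, meta)
}

## Minimal single-block JCAMP-DX reader for (X++(Y..Y)) tables in AFFN
## (plain-number) form. XFACTOR/YFACTOR are honored; compressed (SQZ/DIF/DUP)
## encodings are not supported.
.readJcampXY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getField <- function(key, default = NA_real_) {
    i <- grep(sprintf("^##%s=", key), lines, ignore.case = TRUE)
    if (!length(i)) return(default)
    as.numeric(sub(sprintf("^##%s=\\s*", key), "", lines[i[1L]],
                   ignore.case = TRUE))
  }
  xf <- getField("XFACTOR", 1); yf <- getField("YFACTOR", 1)
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("parse error: no ##XYDATA block")
  body <- lines[(start[1L] + 1L):length(lines)]
  endi <- grep("^##", body)
  if (length(endi)) body <- body[seq_len(endi[1L] - 1L)]
  x <- numeric(0); y <- numeric(0)
  for (ln in body) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:],]+")[[1L]]))
    if (any(is.na(vals)))
      stop("parse error: non-numeric JCAMP data line: ", ln)
    if (length(vals) < 2L)
      stop("parse error: JCAMP data line with no Y values")
    nY <- length(vals) - 1L
    ## X of the line anchors its first Y; subsequent Y step by the implied
    ## grid spacing, reconstructed when the next line arrives or from
    ## FIRSTX/LASTX/NPOINTS.
    x <- c(x, vals[1L], rep(NA_real_, nY - 1L))
    y <- c(y, vals[-1L])
  }
  ## Fill implicit X from the uniform spacing implied by the line anchors.
  known <- which(!is.na(x))
  if (length(known) >= 2L) {
    step <- (x[known[length(known)]] - x[known[1L]]) /
      (known[length(known)] - known[1L])
    x <- x[known[1L]] + (seq_along(x) - known[1L]) * step
  } else {
    np <- getField("NPOINTS"); fx <- getField("FIRSTX"); lx <- getField("LASTX")
    if (!is.na(fx) && !is.na(lx) && length(y) > 1L)
      x <- seq(fx, lx, length.out = length(y))
  }
  list(x = x * xf, y = y * yf)
}

#' Write spectra to the wide CSV pair
#'
#' Inverse of [readSpectra()] for the `csv_wide` format: writes the spectra
#' table and the per-spectrum metadata table. Round-trips bit-identically.
#'
#' @param set a [SpectraSet-class].
#' @param path,meta_path output files.
#' @param header optional character vector written as `# `-prefixed comment
#'   lines at the top of both files (provenance: config hash, seed).
#' @return invisibly, `c(path, meta_path)`.
#' @export
writeSpectra <- function(set, path, meta_path, header = NULL) {
  A <- absorbance(set)
  tab <- data.frame(wn = wavenumbers(set), t(A), check.names = FALSE)
  names(tab) <- c("wavenumber_cm-1", rownames(A))
  .writeCsvWithHeader(tab, path, header)
  .writeCsvWithHeader(spectraMeta(set), meta_path, header)
  invisible(c(path, meta_path))
}

.writeCsvWithHeader <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Subrange specification
#'
#' A list of closed `(high, low)` wavenumber intervals in cm^-1, listed
#' high-to-low and non-overlapping, e.g. the modeling subranges
#' `subrangeSpec(c(9000, 6800), c(6500, 4000))` that bracket the C-H and
#' O-H overtone/combination bands distinguishing the two tissue classes.
#'
#' @param ... numeric length-2 vectors `c(high, low)`.
#' @return an object of class `SubrangeSpec` (a validated list).
#' @export
subrangeSpec <- function(...) {
  intervals <- list(...)
  if (!length(intervals)) stop("at least one interval is required")
  for (iv in intervals) {
    if (length(iv) != 2L || !is.numeric(iv))
      stop("each interval must be a numeric c(high, low) pair")
    if (iv[1L] <= iv[2L]) stop("interval high must exceed low: ",
                               paste(iv, collapse = "-"))
  }
  highs <- vapply(intervals, `[[`, 0, 1L)
  lows <- vapply(intervals, `[[`, 0, 2L)
  if (is.unsorted(rev(highs), strictly = TRUE))
    stop("intervals must be listed high-to-low")
  if (any(highs[-1L] >= lows[-length(lows)]))
    stop("intervals must not overlap")
  structure(intervals, class = "SubrangeSpec")
}

#' Extract spectral subranges
#'
#' Restricts a [SpectraSet-class] to the grid points falling inside each
#' interval of a [subrangeSpec()] (boundaries inclusive), concatenated in the
#' original high-to-low order. Idempotent under repeated application of the
#' same spec.
#'
#' @param set a [SpectraSet-class].
#' @param spec a [subrangeSpec()] (or list of `c(high, low)` pairs).
#' @return the restricted [SpectraSet-class].
#' @export
extractSubranges <- function(set, spec) {
  if (!inherits(spec, "SubrangeSpec")) spec <- do.call(subrangeSpec, spec)
  wn <- wavenumbers(set)
  keep <- logical(length(wn))
  for (iv in spec) {
    inside <- wn <= iv[1L] & wn >= iv[2L]
    if (!any(inside))
      stop("empty-interval error: no grid points in ",
           iv[1L], "-", iv[2L], " cm^-1")
    keep <- keep | inside
  }
  set[keep, ]
}

#' Mean and difference spectra
#'
#' `meanSpectrum()` averages all spectra carrying a class label pointwise;
#' `differenceSpectrum()` subtracts two such means elementwise, the standard
#' view used to locate the wavenumber regions where two classes differ.
#'
#' @param set a [SpectraSet-class].
#' @param label class label (`"mutant"`, `"wild_type"`, `"unknown"`).
#' @return numeric vector on the set's grid.
#' @export
meanSpectrum <- function(set, label) {
  sel <- spectraMeta(set)$label == label
  if (!any(sel))
    stop("empty-selection error: no spectra with label '", label, "'")
  colMeans(absorbance(set)[sel, , drop = FALSE])
}

#' @rdname meanSpectrum
#' @param mean_a,mean_b equal-length numeric vectors.
#' @export
differenceSpectrum <- function(mean_a, mean_b) {
  if (length(mean_a) != length(mean_b))
    stop("shape error: spectra have lengths ", length(mean_a), " and ",
         length(mean_b))
  mean_a - mean_b
}
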