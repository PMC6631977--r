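#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' SpectraSet: a set of NIR spectra on a shared wavenumber grid
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with the
#' conventions of FT-NIR transflectance data: rows are wavenumber grid points
#' (stored high-to-low, the FTIR plotting convention), columns are individual
#' spectra, the single assay `"absorbance"` holds absorbance units, and the
#' column metadata carries `sample_id`, `replicate` (1-3; each tissue sample
#' is measured at three locations), `prep_class` (paraffin_embedded,
#' deparaffinized or stained section) and the reference mutation `label`
#' (mutant / wild_type / unknown).
#'
#' Validity requires a strictly decreasing grid within 4000-12000 cm^-1, no
#' missing absorbance values, replicate indices in 1-3, and a single
#' consistent non-unknown label per sample id.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [SpectraSet()] for construction, [readSpectra()] for file input.
#' @aliases SpectraSet-class
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
  msg <- character(0)
  wn <- rowData(object)$wavenumber
  if (is.null(wn))
    return("rowData must contain a 'wavenumber' column")
  if (length(wn) < 2L)
    msg <- c(msg, "grid must have at least 2 wavenumbers")
  if (any(!is.finite(wn)))
    msg <- c(msg, "wavenumbers must be finite")
  else {
    if (any(diff(wn) >= 0))
      msg <- c(msg, "wavenumber grid must be strictly decreasing")
    if (any(wn > 12000 + 1e-9) || any(wn < 4000 - 1e-9))
      msg <- c(msg, "wavenumbers must lie within [4000, 12000] cm^-1")
  }
  if (!"absorbance" %in% names(assays(object)))
    msg <- c(msg, "assay 'absorbance' is required")
  else if (any(!is.finite(assay(object, "absorbance"))))
    msg <- c(msg, "absorbance matrix must contain no missing values")
  cd <- colData(object)
  need <- c("sample_id", "replicate", "prep_class", "label")
  if (!all(need %in% names(cd)))
    msg <- c(msg, sprintf("colData must contain columns: %s",
                          paste(need, collapse = ", ")))
  else {
    if (!all(cd$replicate %in% 1:3))
      msg <- c(msg, "replicate must be in {1, 2, 3}")
    if (!all(cd$prep_class %in% prepClassLevels))
      msg <- c(msg, "prep_class must be one of paraffin_embedded, deparaffinized, stained")
    if (!all(cd$label %in% labelLevels))
      msg <- c(msg, "label must be one of mutant, wild_type, unknown")
    known <- cd$label != "unknown"
    if (any(known)) {
      perSample <- tapply(cd$label[known], cd$sample_id[known],
                          function(l) length(unique(l)))
      if (any(perSample > 1L))
        msg <- c(msg, "each sample_id must carry a single consistent label")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("SpectraSet", .validSpectraSet)

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix of spectra, one row per spectrum and one
#'   column per wavenumber (absorbance units).
#' @param wavenumber numeric vector of wavenumbers in cm^-1, one per column
#'   of `absorbance`. Any order is accepted; the object stores the grid
#'   strictly decreasing and reorders the columns accordingly. Duplicated
#'   wavenumbers are a grid error.
#' @param meta `data.frame` (or DataFrame) with one row per spectrum and
#'   columns `sample_id`, `replicate`, `prep_class`, `label`.
#' @return a [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(runif(8, 0.2, 0.8), nrow = 2), c(9000, 8000, 7000, 6000),
#'                 data.frame(sample_id = "A", replicate = 1:2,
#'                            prep_class = "paraffin_embedded", label = "mutant"))
#' nSpectra(s)
#' @export
SpectraSet <- function(absorbance, wavenumber, meta) {
  absorbance <- asSpectraMatrix(absorbance)
  wavenumber <- as.numeric(wavenumber)
  if (ncol(absorbance) != length(wavenumber))
    stop("format error: absorbance columns (", ncol(absorbance),
         ") do not match grid length (", length(wavenumber), ")")
  if (nrow(absorbance) != nrow(meta))
    stop("format error: metadata rows (", nrow(meta),
         ") do not match number of spectra (", nrow(absorbance), ")")
  if (anyDuplicated(wavenumber))
    stop("grid error: duplicated wavenumber values")
  ord <- order(wavenumber, decreasing = TRUE)
  wavenumber <- wavenumber[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  meta <- DataFrame(meta)
  meta$replicate <- as.integer(meta$replicate)
  sname <- sprintf("%s_r%d", meta$sample_id, meta$replicate)
  A <- t(absorbance)
  dimnames(A) <- list(NULL, sname)
  se <- SummarizedExperiment(
    assays = SimpleList(absorbance = A),
    rowData = DataFrame(wavenumber = wavenumber),
    colData = meta)
  new("SpectraSet", se)
}

#' Principal-component model of a spectral calibration set
#'
#' Fitted by [fitPCA()] on preprocessed calibration spectra: the column mean
#' vector, orthonormal loadings (right singular vectors, sign-fixed so each
#' column's largest-magnitude element is positive), and per-component
#' explained-variance percentages over the full rank. [selectNumPCs()] fills
#' `kSelected`/`valid` using the cumulative-variance threshold rule; a model
#' whose cumulative explained variance never reaches the threshold within the
#' component cap is flagged invalid (the "NA" models of an over-differentiated
#' preprocessing strategy).
#'
#' @slot center numeric, calibration column means.
#' @slot loadings matrix (n_points x kMax), orthonormal columns.
#' @slot explainedRatio numeric, per-PC explained variance in percent
#'   (full spectrum, sums to 100).
#' @slot kMax integer, number of loadings retained.
#' @slot kSelected integer, selected number of PCs (NA until selection).
#' @slot valid logical, FALSE when the threshold is unreachable within the cap.
#' @slot threshold numeric, cumulative-variance threshold in percent.
#' @aliases PCAModel-class
#' @exportClass PCAModel
setClass("PCAModel", representation(
  center = "numeric", loadings = "matrix", explainedRatio = "numeric",
  kMax = "integer", kSelected = "integer", valid = "logical",
  threshold = "numeric"))

setValidity("PCAModel", function(object) {
  msg <- character(0)
  if (length(object@center) != nrow(object@loadings))
    msg <- c(msg, "center length must equal loadings rows")
  if (any(object@explainedRatio < -1e-8))
    msg <- c(msg, "explained ratios must be non-negative")
  if (sum(object@explainedRatio) > 100 + 1e-6)
    msg <- c(msg, "explained ratios must sum to at most 100%")
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(ncol(G)))) > 1e-8)
    msg <- c(msg, "loadings must be orthonormal")
  if (!is.na(object@kSelected) && object@kSelected > object@kMax)
    msg <- c(msg, "kSelected must not exceed kMax")
  if (length(msg)) msg else TRUE
})

#' Counter-propagation artificial neural network model
#'
#' A square Kohonen map of `S x S` neurons whose input-layer weights live in
#' the PC-score space, coupled to an output layer holding per-neuron class
#' weights. Training ([trainCPANN()]) moves both layers of all neurons within
#' a linearly shrinking neighborhood toward each input and its one-hot class
#' label; prediction ([predict()]) returns the class weights of the winning
#' (nearest) neuron.
#'
#' @slot S integer, neurons per map side.
#' @slot d integer, input dimensionality (number of PC scores).
#' @slot nClasses integer, number of classes (2).
#' @slot kohonenW matrix (S*S x d): input-layer weights, row-major neuron
#'   order (row 1 col 1, row 1 col 2, ...).
#' @slot outputW matrix (S*S x C): output-layer class weights; rows sum to 1.
#' @slot classLevels character, class names in output-layer column order.
#' @slot epochs,lrStart,lrEnd training hyperparameters.
#' @slot seed integer RNG seed; initialization and the per-epoch shuffled
#'   presentation order are deterministic functions of it.
#' @slot trained logical.
#' @aliases CPANNModel-class
#' @exportClass CPANNModel
setClass("CPANNModel", representation(
  S = "integer", d = "integer", nClasses = "integer",
  kohonenW = "matrix", outputW = "matrix", classLevels = "character",
  epochs = "integer", lrStart = "numeric", lrEnd = "numeric",
  seed = "integer", trained = "logical"))

setValidity("CPANNModel", function(object) {
  msg <- character(0)
  if (object@S < 1L) msg <- c(msg, "S must be >= 1")
  if (nrow(object@kohonenW) != object@S^2 || ncol(object@kohonenW) != object@d)
    msg <- c(msg, "kohonenW must be S^2 x d")
  if (nrow(object@outputW) != object@S^2 || ncol(object@outputW) != object@nClasses)
    msg <- c(msg, "outputW must be S^2 x C")
  if (any(object@outputW < -1e-9) || any(object@outputW > 1 + 1e-9))
    msg <- c(msg, "output weights must lie in [0, 1]")
  if (max(abs(rowSums(object@outputW) - 1)) > 1e-6)
    msg <- c(msg, "output weights must sum to 1 per neuron")
  if (length(msg)) msg else TRUE
})

#' Fitted spectral preprocessing strategy
#'
#' An ordered composition of preprocessing operators in the standard
#' chemometric shorthand: MC (mean centering), MSC (multiplicative scatter
#' correction), SNV (standard normal variate), FD/SD (first/second
#' derivative), SGS (Savitzky-Golay smoothing), NDS (Norris derivative
#' smoothing). Operators apply left to right; MC, when present, is the final
#' step and each operator appears at most once. MC column means and the MSC
#' reference spectrum are fitted on the calibration set only and re-applied
#' unchanged to new spectra (no calibration leakage).
#'
#' @slot steps list of `list(op =, params =)` entries in application order.
#' @slot fitted list of fitted state per step (`NULL` before fitting):
#'   the MC mean vector and/or MSC reference spectrum.
#' @slot isFitted logical.
#' @aliases PreprocessStrategy-class
#' @exportClass PreprocessStrategy
setClass("PreprocessStrategy", representation(
  steps = "list", fitted = "list", isFitted = "logical"))

setValidity("PreprocessStrategy", function(object) {
  msg <- character(0)
  ops <- vapply(object@steps, `[[`, "", "op")
  known <- c("MC", "MSC", "SNV", "FD", "SD", "SGS", "NDS")
  if (!all(ops %in% known))
    msg <- c(msg, sprintf("unknown operator(s): %s",
                          paste(setdiff(ops, known), collapse = ", ")))
  if (anyDuplicated(ops))
    msg <- c(msg, "operators may appear at most once")
  if ("MC" %in% ops && ops[length(ops)] != "MC")
    msg <- c(msg, "MC, when present, must be the final step")
  if (length(msg)) msg else TRUE
})
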