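#' @rdname SpectraSet-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("spectraMeta", function(x) standardGeneric("spectraMeta"))

#' @rdname SpectraSet-accessors
#' @export
setGeneric("nSpectra", function(x) standardGeneric("nSpectra"))

#' SpectraSet accessors
#'
#' @param x a [SpectraSet-class].
#' @return `wavenumbers()` the decreasing grid in cm^-1; `absorbance()` the
#'   spectra as an `n_spectra x n_points` matrix (spectra in rows, the
#'   orientation all preprocessing operators use); `spectraMeta()` the
#'   per-spectrum metadata as a `data.frame`; `nSpectra()` the number of
#'   spectra.
#' @name SpectraSet-accessors
NULL

#' @rdname SpectraSet-accessors
setMethod("wavenumbers", "SpectraSet", function(x) rowData(x)$wavenumber)

#' @rdname SpectraSet-accessors
setMethod("absorbance", "SpectraSet", function(x) t(assay(x, "absorbance")))

#' @rdname SpectraSet-accessors
setMethod("spectraMeta", "SpectraSet",
          function(x) as.data.frame(colData(x)))

#' @rdname SpectraSet-accessors
setMethod("nSpectra", "SpectraSet", function(x) ncol(x))

setMethod("show", "SpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavenumbers (%.0f-%.0f cm^-1)\n",
              ncol(object), length(wn), max(wn), min(wn)))
  m <- spectraMeta(object)
  cat(sprintf("  samples: %d  labels: %s\n",
              length(unique(m$sample_id)),
              paste(sprintf("%s=%d", names(table(m$label)), table(m$label)),
                    collapse = " ")))
})

setMethod("show", "PCAModel", function(object) {
  cum <- cumsum(object@explainedRatio)
  sel <- if (is.na(object@kSelected)) "unselected"
         else if (object@valid)
           sprintf("k=%d (%.1f%% cumulative)", object@kSelected,
                   cum[object@kSelected])
         else sprintf("NA model: %.1f%% at cap %d < %.1f%%",
                      cum[object@kSelected], object@kSelected, object@threshold)
  cat(sprintf("PCAModel: %d variables, %d loadings retained; %s\n",
              nrow(object@loadings), object@kMax, sel))
})

setMethod("show", "CPANNModel", function(object) {
  cat(sprintf("CPANNModel: %dx%d map, %d-dim input, classes: %s; %s\n",
              object@S, object@S, object@d,
              paste(object@classLevels, collapse = "/"),
              if (object@trained) sprintf("trained (%d epochs, lr %.3g->%.3g, seed %d)",
                                          object@epochs, object@lrStart,
                                          object@lrEnd, object@seed)
              else "untrained"))
})

setMethod("show", "PreprocessStrategy", function(object) {
  cat(sprintf("PreprocessStrategy: %s (%s)\n", strategyId(object),
              if (object@isFitted) "fitted" else "unfitted"))
})
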