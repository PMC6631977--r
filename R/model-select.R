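#' Grid search over preprocessing strategy, subrange and map size
#'
#' Reproduces the model-screening table: for every combination of
#' preprocessing strategy, spectral-subrange option and map side, the
#' strategy is fitted on the calibration set and applied to both sets, a PCA
#' is fitted and its component count selected by the cumulative-variance
#' rule, and — unless the PCA is invalid (the "NA" rows) — a CP-ANN is
#' trained and scored: CAC on the calibration spectra, CACV by
#' sample-grouped cross-validation, CAV on the validation spectra. One
#' shared seed drives every row so rows differ only by configuration.
#'
#' @param cal,val calibration and validation [SpectraSet-class] on a shared
#'   grid.
#' @param strategies character vector of strategy strings (see
#'   [preprocessStrategy()]).
#' @param subranges list of [subrangeSpec()] objects.
#' @param sides integer vector of map sides.
#' @param seed shared RNG seed.
#' @param threshold,cap PC-selection rule (see [selectNumPCs()]).
#' @param folds cross-validation folds.
#' @param epochs,lrStart,lrEnd CP-ANN hyperparameters.
#' @return `data.frame` with one row per combination: `strategy`,
#'   `subrange`, `nPCs`, `cumvarPct`, `mapSide`, `cacPct`, `cacvPct`,
#'   `cavPct`, `valid`.
#' @export
runGrid <- function(cal, val, strategies,
                    subranges = list(subrangeSpec(c(9000, 6800), c(6500, 4000))),
                    sides = c(10L, 12L, 15L), seed = 1L,
                    threshold = 85.0, cap = 20L, folds = 5L,
                    epochs = 100L, lrStart = 0.5, lrEnd = 0.01) {
  if (!length(strategies)) stop("parameter error: empty strategy list")
  if (!isTRUE(all.equal(wavenumbers(cal), wavenumbers(val))))
    stop("grid error: calibration and validation sets must share a grid")
  calMeta <- spectraMeta(cal); valMeta <- spectraMeta(val)
  if (length(unique(calMeta$label[calMeta$label != "unknown"])) < 2L)
    stop("data error: calibration set must contain both classes")
  rows <- list()
  for (sr in subranges) {
    if (!inherits(sr, "SubrangeSpec")) sr <- do.call(subrangeSpec, sr)
    srId <- paste(vapply(sr, function(iv) paste0(iv[1L], "-", iv[2L]), ""),
                  collapse = ",")
    calSub <- extractSubranges(cal, sr)
    valSub <- extractSubranges(val, sr)
    grid <- wavenumbers(calSub)
    for (st in strategies) {
      fit <- fitApplyStrategy(st, absorbance(calSub), absorbance(valSub),
                              grid = grid)
      pca <- selectNumPCs(fitPCA(fit$cal, kMax = cap), threshold = threshold,
                          cap = cap)
      cum <- cumsum(pca@explainedRatio)
      base <- data.frame(
        strategy = st, subrange = srId, nPCs = pca@kSelected,
        cumvarPct = roundHalfUp(cum[min(pca@kSelected, length(cum))], 1),
        stringsAsFactors = FALSE)
      for (S in sides) {
        if (!pca@valid) {
          rows[[length(rows) + 1L]] <- cbind(
            base, mapSide = S, cacPct = NA_real_, cacvPct = NA_real_,
            cavPct = NA_real_, valid = FALSE)
          next
        }
        scCal <- projectScores(pca, fit$cal)
        scVal <- projectScores(pca, fit$new)
        m <- initMap(S, ncol(scCal), seed = seed, epochs = epochs,
                     lrStart = lrStart, lrEnd = lrEnd)
        m <- trainCPANN(m, scCal, calMeta$label)
        cac <- 100 * mean(predict(m, scCal)$class == calMeta$label)
        cav <- 100 * mean(predict(m, scVal)$class == valMeta$label)
        cacv <- crossValidate(scCal, calMeta$label, calMeta$sample_id,
                              folds = folds, S = S, seed = seed,
                              epochs = epochs, lrStart = lrStart,
                              lrEnd = lrEnd)$cacvPct
        rows[[length(rows) + 1L]] <- cbind(
          base, mapSide = S, cacPct = cac, cacvPct = cacv, cavPct = cav,
          valid = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Select the best grid row
#'
#' Ranks the non-NA rows by validation accuracy (CAV) first — the
#' generalization claim — then calibration accuracy (CAC), then CACV, with
#' remaining ties broken toward the smaller map and fewer components.
#'
#' @param rows the `data.frame` returned by [runGrid()].
#' @return the single winning row.
#' @export
selectBest <- function(rows) {
  ok <- rows[!is.na(rows$cavPct), , drop = FALSE]
  if (!nrow(ok)) stop("no-model error: all grid rows are NA")
  ord <- order(-ok$cavPct, -ok$cacPct, -ok$cacvPct, ok$mapSide, ok$nPCs)
  ok[ord[1L], , drop = FALSE]
}
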