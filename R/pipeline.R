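#' Run the full classification pipeline on one synthetic dataset
#'
#' Convenience wrapper tying the stages together for a single
#' configuration: generate synthetic calibration/validation sets, restrict
#' to the modeling subranges, fit and apply the preprocessing strategy,
#' reduce with PCA under the cumulative-variance rule, train the CP-ANN,
#' and score per-spectrum accuracies (CAC/CAV) and per-sample diagnostics
#' (replicate OR-voting) on both sets.
#'
#' @param seed RNG seed driving data generation and model training.
#' @param strategy preprocessing strategy string (default `"MC"`).
#' @param subranges list of `c(high, low)` intervals (default the two
#'   modeling subranges 9000-6800 and 6500-4000 cm^-1).
#' @param side CP-ANN map side (default 12).
#' @param threshold,cap PC-selection rule.
#' @param epochs,lrStart,lrEnd CP-ANN hyperparameters.
#' @param synthetic named list of [syntheticConfig()] overrides
#'   (e.g. `list(effect_size = 0)`).
#' @return list with `cacPct`, `cavPct`, the `diagnosticReport`s
#'   `calReport` and `valReport`, and the fitted `pca` and `cpann` objects.
#' @export
runPipeline <- function(seed = 1L, strategy = "MC",
                        subranges = list(c(9000, 6800), c(6500, 4000)),
                        side = 12L, threshold = 85.0, cap = 20L,
                        epochs = 100L, lrStart = 0.5, lrEnd = 0.01,
                        synthetic = list()) {
  syn <- do.call(syntheticConfig, c(synthetic, list(seed = seed)))
  sets <- generateSpectra(syn)
  sr <- do.call(subrangeSpec, subranges)
  cal <- extractSubranges(sets$calibration, sr)
  val <- extractSubranges(sets$validation, sr)
  calMeta <- spectraMeta(cal); valMeta <- spectraMeta(val)
  fit <- fitApplyStrategy(strategy, absorbance(cal), absorbance(val),
                          grid = wavenumbers(cal))
  pca <- selectNumPCs(fitPCA(fit$cal, kMax = cap), threshold = threshold,
                      cap = cap)
  if (!pca@valid)
    stop("NA-model error: PC-selection threshold unreachable at cap")
  scCal <- projectScores(pca, fit$cal)
  scVal <- projectScores(pca, fit$new)
  m <- initMap(side, ncol(scCal), seed = seed, epochs = epochs,
               lrStart = lrStart, lrEnd = lrEnd)
  m <- trainCPANN(m, scCal, calMeta$label)
  predCal <- predict(m, scCal)$class
  predVal <- predict(m, scVal)$class
  list(
    cacPct = 100 * mean(predCal == calMeta$label),
    cavPct = 100 * mean(predVal == valMeta$label),
    calReport = diagnoseReport(predCal, calMeta$sample_id, calMeta$label),
    valReport = diagnoseReport(predVal, valMeta$sample_id, valMeta$label),
    pca = pca, cpann = m)
}
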