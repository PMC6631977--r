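#' Aggregate replicate predictions into a sample diagnosis
#'
#' The replicate-voting (OR) rule: a sample is diagnosed wild type only when
#' every one of its replicate spectra is predicted wild type; a single
#' mutant prediction makes the diagnosis mutant. This deliberately trades
#' specificity for sensitivity — missing a mutant is the costly error.
#'
#' @param predictions character vector of per-replicate predicted classes
#'   (normally length 3).
#' @return `"mutant"` or `"wild_type"`.
#' @export
aggregateSample <- function(predictions) {
  if (!length(predictions)) stop("data error: no replicate predictions")
  if (all(predictions == "wild_type")) "wild_type" else "mutant"
}

#' Diagnose all samples of a prediction set
#'
#' Groups per-spectrum predictions by sample and applies the replicate
#' voting rule of [aggregateSample()]. Samples with fewer than 3 replicates
#' are diagnosed from the available ones, with a warning.
#'
#' @param predicted per-spectrum predicted classes.
#' @param sampleIds per-spectrum sample identifiers.
#' @param labels per-spectrum true labels.
#' @return `data.frame(sample_id, label, diagnosed, n_replicates)`, one row
#'   per sample.
#' @export
diagnoseSamples <- function(predicted, sampleIds, labels) {
  if (length(predicted) != length(sampleIds) ||
      length(predicted) != length(labels))
    stop("shape error: predicted, sampleIds and labels must have equal length")
  ids <- unique(sampleIds)
  n <- vapply(ids, function(s) sum(sampleIds == s), 0L)
  if (any(n < 3L))
    warning("sample(s) with fewer than 3 replicate spectra diagnosed from ",
            "available replicates: ", paste(ids[n < 3L], collapse = ", "))
  data.frame(
    sample_id = ids,
    label = vapply(ids, function(s) unique(labels[sampleIds == s])[1L], ""),
    diagnosed = vapply(ids, function(s)
      aggregateSample(predicted[sampleIds == s]), ""),
    n_replicates = n,
    stringsAsFactors = FALSE)
}

#' Confusion counts with mutant as the positive class
#'
#' @param truth,diagnosed equal-length vectors with values `"mutant"` /
#'   `"wild_type"`.
#' @return object of class `confusionCounts`: list with integer `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusionCounts <- function(truth, diagnosed) {
  if (length(truth) != length(diagnosed))
    stop("shape error: truth and diagnosed lengths differ")
  ok <- c("mutant", "wild_type")
  if (!all(truth %in% ok) || !all(diagnosed %in% ok))
    stop("label error: labels must be 'mutant' or 'wild_type'")
  structure(list(
    TP = sum(truth == "mutant" & diagnosed == "mutant"),
    FP = sum(truth == "wild_type" & diagnosed == "mutant"),
    TN = sum(truth == "wild_type" & diagnosed == "wild_type"),
    FN = sum(truth == "mutant" & diagnosed == "wild_type")),
    class = "confusionCounts")
}

#' Diagnostic performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, as percentages at full precision, with
#' one-decimal half-up rounding applied only for display (75/80 prints as
#' 93.8). A metric whose denominator is zero is reported as missing (`NA`),
#' never as 0, with a warning.
#'
#' @param counts a `confusionCounts` object (or list with TP/FP/TN/FN).
#' @return object of class `diagnosticReport`: list with
#'   `sensitivityPct`, `specificityPct`, `accuracyPct` (full precision),
#'   `counts`, and `display` (one-decimal rounded copies).
#' @export
diagnosticMetrics <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    if (total == 0L) stop("data error: no diagnosed samples")
    sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else {
      warning("undefined sensitivity: no mutant samples (TP + FN = 0)")
      NA_real_
    }
    spec <- if (TN + FP > 0) 100 * TN / (TN + FP) else {
      warning("undefined specificity: no wild-type samples (TN + FP = 0)")
      NA_real_
    }
    acc <- 100 * (TP + TN) / total
    structure(list(
      sensitivityPct = sens, specificityPct = spec, accuracyPct = acc,
      counts = counts,
      display = c(sensitivity = roundHalfUp(sens, 1),
                  specificity = roundHalfUp(spec, 1),
                  accuracy = roundHalfUp(acc, 1))),
      class = "diagnosticReport")
  })
}

#' @export
print.diagnosticReport <- function(x, ...) {
  d <- x$display
  cat(sprintf("Diagnostic report (mutant positive): sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              d["sensitivity"], d["specificity"], d["accuracy"]))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$counts$TP, x$counts$FP,
              x$counts$TN, x$counts$FN))
  invisible(x)
}

#' Full diagnostic report from per-spectrum predictions
#'
#' Convenience wrapper: [diagnoseSamples()] then [confusionCounts()] then
#' [diagnosticMetrics()].
#'
#' @inheritParams diagnoseSamples
#' @return a `diagnosticReport` with the per-sample table attached as
#'   `$samples`.
#' @export
diagnoseReport <- function(predicted, sampleIds, labels) {
  samples <- diagnoseSamples(predicted, sampleIds, labels)
  rep <- diagnosticMetrics(confusionCounts(samples$label, samples$diagnosed))
  rep$samples <- samples
  rep
}
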