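## Shared fixtures, all built in code.

## Tiny SpectraSet: nSpectra spectra on a small decreasing grid.
makeTinySet <- function(nSpectra = 4L, grid = c(9000, 8000, 7000, 6000, 5000),
                        labels = rep(c("mutant", "wild_type"),
                                     length.out = nSpectra),
                        seed = 42L) {
  set.seed(seed)
  A <- matrix(runif(nSpectra * length(grid), 0.2, 0.9), nrow = nSpectra)
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(nSpectra)),
    replicate = 1L, prep_class = "paraffin_embedded", label = labels,
    stringsAsFactors = FALSE)
  SpectraSet(A, grid, meta)
}

## Two well-separated 2-D clusters with labels; the oracle classifies by
## nearest class centroid.
makeClusters <- function(n = 20L, centers = list(mutant = c(0, 0),
                                                 wild_type = c(10, 10)),
                         sdev = 0.1, seed = 11L) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n, centers$mutant[1], sdev), rnorm(n, centers$mutant[2], sdev)),
    cbind(rnorm(n, centers$wild_type[1], sdev),
          rnorm(n, centers$wild_type[2], sdev)))
  labels <- rep(c("mutant", "wild_type"), each = n)
  list(scores = X, labels = labels,
       sampleIds = sprintf("%s%02d", rep(c("M", "W"), each = n),
                           rep(seq_len(n), 2L)))
}

nearestPrototypeOracle <- function(train, trainLabels, test) {
  centroids <- rbind(colMeans(train[trainLabels == "mutant", , drop = FALSE]),
                     colMeans(train[trainLabels == "wild_type", , drop = FALSE]))
  cls <- c("mutant", "wild_type")
  apply(test, 1L, function(x)
    cls[which.min(colSums((t(centroids) - x)^2))])
}

## Brute-force Savitzky-Golay oracle: smooth by explicit local polynomial
## least squares, evaluating the fit at the (possibly off-center) point.
sgOracle <- function(x, window, polyorder) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, min(i - half, n - window + 1L))
    idx <- lo:(lo + window - 1L)
    fit <- lm(y ~ poly(z, polyorder, raw = TRUE),
              data = data.frame(y = x[idx], z = idx - i))
    unname(predict(fit, newdata = data.frame(z = 0)))
  }, 0)
}
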