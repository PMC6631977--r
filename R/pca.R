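#' Fit a principal-component model
#'
#' Mean-centers the preprocessed calibration matrix and takes its singular
#' value decomposition: loadings are the right singular vectors, and the
#' per-component explained-variance percentage is `100 * sigma_i^2 /
#' sum(sigma^2)` over the full rank (so the ratios sum to 100 regardless of
#' how many loadings are retained). Each loading column's sign is fixed so
#' its largest-magnitude element is positive, making repeated fits
#' reproducible.
#'
#' @param X calibration spectra matrix (spectra in rows), already
#'   preprocessed.
#' @param kMax number of loading columns to retain (default: full rank).
#' @return an unselected [PCAModel-class]; pass to [selectNumPCs()].
#' @export
fitPCA <- function(X, kMax = NULL) {
  X <- asSpectraMatrix(X)
  if (nrow(X) < 2L) stop("data error: PCA needs >= 2 spectra")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (all(Xc == 0) && all(X == 0))
    stop("degenerate error: all-zero matrix")
  sv <- svd(Xc)
  ev <- sv$d^2
  tot <- sum(ev)
  if (tot == 0) stop("degenerate error: matrix has no variance")
  ratio <- 100 * ev / tot
  rank <- sum(sv$d > sv$d[1L] * 1e-12)
  if (is.null(kMax)) kMax <- rank
  kMax <- as.integer(min(kMax, rank))
  L <- sv$v[, seq_len(kMax), drop = FALSE]
  ## sign convention: largest-|.| element of each loading made positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  new("PCAModel", center = center, loadings = L,
      explainedRatio = ratio[seq_len(rank)], kMax = kMax,
      kSelected = NA_integer_, valid = NA, threshold = NA_real_)
}

#' Select the number of principal components
#'
#' Applies the cumulative-variance rule: the smallest k whose cumulative
#' explained-variance percentage reaches `threshold` (read inclusively,
#' `>= threshold`). If no k up to `cap` components reaches it, the model is
#' flagged invalid with `kSelected = cap` — the "NA" outcome seen when an
#' over-differentiated preprocessing strategy spreads variance across too
#' many components.
#'
#' @param model a fitted [PCAModel-class].
#' @param threshold cumulative explained-variance threshold in percent
#'   (default 85.0).
#' @param cap maximum number of components considered (default 20).
#' @return the model with `kSelected`, `valid` and `threshold` filled in.
#' @export
selectNumPCs <- function(model, threshold = 85.0, cap = 20L) {
  if (!is(model, "PCAModel")) stop("state error: need a fitted PCAModel")
  cum <- cumsum(model@explainedRatio)
  cap <- as.integer(cap)
  upto <- min(cap, length(cum))
  hit <- which(cum[seq_len(upto)] >= threshold)
  if (length(hit)) {
    model@kSelected <- hit[1L]
    model@valid <- TRUE
  } else {
    model@kSelected <- cap
    model@valid <- FALSE
  }
  model@threshold <- threshold
  model
}

#' Project spectra onto the selected principal components
#'
#' Scores are `(X - center) %*% loadings[, 1:kSelected]` with the
#' calibration center and loadings — validation spectra are projected, never
#' re-fitted.
#'
#' @param model a selected, valid [PCAModel-class].
#' @param X spectra matrix (spectra in rows) on the same variable grid.
#' @return scores matrix (`n_spectra x kSelected`).
#' @export
projectScores <- function(model, X) {
  if (!is(model, "PCAModel") || is.na(model@kSelected))
    stop("state error: run selectNumPCs() first")
  if (!isTRUE(model@valid))
    stop("NA-model error: cumulative variance below threshold at cap")
  X <- asSpectraMatrix(X)
  if (ncol(X) != length(model@center))
    stop("shape error: ", ncol(X), " variables vs model's ",
         length(model@center))
  k <- min(model@kSelected, model@kMax)
  sweep(X, 2L, model@center) %*% model@loadings[, seq_len(k), drop = FALSE]
}
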