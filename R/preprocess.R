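#' Mean centering
#'
#' Subtracts the calibration column mean of each spectral variable. When
#' `fittedMean` is `NULL`, `X` is taken as the calibration set and the means
#' are computed from it; otherwise the stored means are re-applied (so
#' validation spectra never contribute to the centering).
#'
#' @param X spectra matrix (spectra in rows) or a single spectrum vector.
#' @param fittedMean optional calibration column means.
#' @return `list(X = centered matrix, mean = means used)`.
#' @export
meanCenter <- function(X, fittedMean = NULL) {
  X <- asSpectraMatrix(X)
  if (is.null(fittedMean)) fittedMean <- colMeans(X)
  if (length(fittedMean) != ncol(X))
    stop("shape error: fitted mean length ", length(fittedMean),
         " does not match ", ncol(X), " variables")
  list(X = sweep(X, 2L, fittedMean), mean = fittedMean)
}

#' Standard normal variate
#'
#' Standardizes each spectrum (row) to mean 0 and sample (n-1) standard
#' deviation 1, removing multiplicative and additive scatter per spectrum.
#' Idempotent.
#'
#' @param X spectra matrix or single spectrum vector.
#' @return transformed matrix of the same shape.
#' @export
snvTransform <- function(X) {
  X <- asSpectraMatrix(X)
  if (ncol(X) < 2L) stop("degenerate-spectrum error: need >= 2 points")
  m <- rowMeans(X)
  s <- apply(X, 1L, stats::sd)
  if (any(s == 0))
    stop("degenerate-spectrum error: constant spectrum has zero sd")
  (X - m) / s
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * reference`
#' by least squares, and returns `(x - a) / b`. The reference is the
#' calibration-set mean spectrum (supplied, never recomputed from new data).
#'
#' @param X spectra matrix or single spectrum vector.
#' @param reference reference spectrum, same length as the grid.
#' @return corrected matrix of the same shape.
#' @export
mscTransform <- function(X, reference) {
  X <- asSpectraMatrix(X)
  if (length(reference) != ncol(X))
    stop("shape error: reference length ", length(reference),
         " does not match ", ncol(X), " variables")
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss == 0) stop("degenerate-fit error: constant reference spectrum")
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    b <- sum(rc * (x - mean(x))) / ss
    if (abs(b) < 1e-12)
      stop("degenerate-fit error: slope numerically zero for spectrum ", i)
    a <- mean(x) - b * mean(reference)
    out[i, ] <- (x - a) / b
  }
  out
}

#' Finite-difference spectral derivatives
#'
#' First (FD) or second (SD) derivative with respect to the point index:
#' central differences at interior points, one-sided differences at the two
#' endpoints, so the output keeps the input length.
#'
#' @param X spectra matrix or single spectrum vector.
#' @param order 1 (FD) or 2 (SD).
#' @param grid optional wavenumber grid; spacing must be uniform within 1%.
#' @return derivative matrix of the same shape.
#' @export
spectralDerivative <- function(X, order = 1L, grid = NULL) {
  X <- asSpectraMatrix(X)
  n <- ncol(X)
  if (n < 3L) stop("length error: derivative needs >= 3 points")
  if (!order %in% c(1L, 2L)) stop("parameter error: order must be 1 or 2")
  if (!is.null(grid)) {
    d <- abs(diff(grid))
    if ((max(d) - min(d)) > 0.01 * mean(d))
      stop("parameter error: grid spacing must be uniform within 1%")
  }
  t(apply(X, 1L, function(x) {
    if (order == 1L) {
      c(x[2L] - x[1L],
        (x[3:n] - x[1:(n - 2L)]) / 2,
        x[n] - x[n - 1L])
    } else {
      mid <- x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]
      c(mid[1L], mid, mid[n - 2L])
    }
  }))
}

#' Savitzky-Golay coefficients and smoothing
#'
#' `sgCoefficients()` returns the central convolution weights of the
#' least-squares polynomial filter; `savitzkyGolay()` smooths each spectrum,
#' handling the edges by evaluating the terminal-window polynomial fits
#' (via [signal::sgolayfilt()]).
#'
#' @param X spectra matrix or single spectrum vector.
#' @param window odd filter length, greater than `polyorder`.
#' @param polyorder polynomial degree.
#' @return smoothed matrix of the same shape; for `sgCoefficients()` the
#'   length-`window` central weight vector.
#' @export
savitzkyGolay <- function(X, window = 11L, polyorder = 3L) {
  .checkSgParams(window, polyorder)
  X <- asSpectraMatrix(X)
  if (window > ncol(X))
    stop("parameter error: window exceeds number of points")
  t(apply(X, 1L, signal::sgolayfilt, p = polyorder, n = window))
}

#' @rdname savitzkyGolay
#' @export
sgCoefficients <- function(window, polyorder) {
  .checkSgParams(window, polyorder)
  F <- signal::sgolay(p = polyorder, n = window)
  as.numeric(F[(window + 1L) %/% 2L, ])
}

.checkSgParams <- function(window, polyorder) {
  if (window %% 2L == 0L)
    stop("parameter error: window must be odd")
  if (window <= polyorder)
    stop("parameter error: window must exceed polyorder")
  invisible(TRUE)
}

#' Norris derivative smoothing
#'
#' Segment-average smoothing followed by a gap difference: each point is
#' replaced by the mean over a centered segment (clipped at the edges), then
#' differenced across `gap` points. Order 1 uses the forward gap difference
#' `(s[i+g] - s[i]) / g` (so segment 1, gap 1 reduces to the plain first
#' difference); order 2 the central second gap difference
#' `(s[i+g] - 2 s[i] + s[i-g]) / g^2`. Edges are replicated to preserve
#' length.
#'
#' @param X spectra matrix or single spectrum vector.
#' @param segment odd smoothing-segment length (>= 1).
#' @param gap difference gap in points (>= 1).
#' @param order 1 or 2.
#' @return derivative matrix of the same shape.
#' @export
norrisDerivative <- function(X, segment = 5L, gap = 5L, order = 1L) {
  if (segment < 1L || segment %% 2L == 0L)
    stop("parameter error: segment must be odd and >= 1")
  if (gap < 1L) stop("parameter error: gap must be >= 1")
  if (!order %in% c(1L, 2L)) stop("parameter error: order must be 1 or 2")
  X <- asSpectraMatrix(X)
  n <- ncol(X)
  if (segment + gap > n)
    stop("parameter error: segment + gap exceeds number of points")
  half <- (segment - 1L) %/% 2L
  t(apply(X, 1L, function(x) {
    s <- vapply(seq_len(n), function(i)
      mean(x[max(1L, i - half):min(n, i + half)]), 0)
    d <- numeric(n)
    if (order == 1L) {
      idx <- seq_len(n - gap)
      d[idx] <- (s[idx + gap] - s[idx]) / gap
      d[(n - gap + 1L):n] <- d[n - gap]
    } else {
      idx <- (gap + 1L):(n - gap)
      d[idx] <- (s[idx + gap] - 2 * s[idx] + s[idx - gap]) / gap^2
      d[seq_len(gap)] <- d[gap + 1L]
      d[(n - gap + 1L):n] <- d[n - gap]
    }
    d
  }))
}

#' Parse a preprocessing-strategy string
#'
#' Strategies are written in the standard shorthand, operators joined by
#' `+` in application order, e.g. `"SNV+NDS+FD+MC"`. `SGS` and `NDS` accept
#' parameter suffixes: `"SGS(11,3)"` (window, polyorder) and `"NDS(5,5)"`
#' (segment, gap). Defaults are SGS(11,3) and NDS(5,5).
#'
#' @param strategy strategy string, or a [PreprocessStrategy-class] (returned
#'   unchanged).
#' @return an unfitted [PreprocessStrategy-class].
#' @export
preprocessStrategy <- function(strategy) {
  if (is(strategy, "PreprocessStrategy")) return(strategy)
  tokens <- trimws(strsplit(strategy, "+", fixed = TRUE)[[1L]])
  if (!length(tokens) || any(!nzchar(tokens)))
    stop("parameter error: empty strategy")
  steps <- lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Z]+)(\\(([0-9]+),\\s*([0-9]+)\\))?$", tok))[[1L]]
    if (!length(m)) stop("parameter error: cannot parse operator '", tok, "'")
    op <- m[2L]
    params <- switch(op,
      SGS = list(window = 11L, polyorder = 3L),
      NDS = list(segment = 5L, gap = 5L),
      list())
    if (nzchar(m[3L])) {
      if (!op %in% c("SGS", "NDS"))
        stop("parameter error: operator ", op, " takes no parameters")
      params[[1L]] <- as.integer(m[4L])
      params[[2L]] <- as.integer(m[5L])
    }
    list(op = op, params = params)
  })
  new("PreprocessStrategy", steps = steps,
      fitted = vector("list", length(steps)), isFitted = FALSE)
}

#' @rdname preprocessStrategy
#' @param x a [PreprocessStrategy-class].
#' @export
strategyId <- function(x) {
  paste(vapply(x@steps, function(s) {
    if (length(s$params) && s$op %in% c("SGS", "NDS"))
      sprintf("%s(%d,%d)", s$op, s$params[[1L]], s$params[[2L]])
    else s$op
  }, ""), collapse = "+")
}

.applyStep <- function(step, state, X, grid, calMatrix) {
  ## `state` is NULL when fitting (calMatrix provides the calibration data);
  ## otherwise the fitted state captured on the calibration set.
  switch(step$op,
    MC = {
      if (is.null(state)) state <- list(mean = colMeans(calMatrix))
      list(X = meanCenter(X, state$mean)$X, state = state)
    },
    MSC = {
      if (is.null(state)) state <- list(reference = colMeans(calMatrix))
      list(X = mscTransform(X, state$reference), state = state)
    },
    SNV = list(X = snvTransform(X), state = list()),
    FD = list(X = spectralDerivative(X, 1L, grid), state = list()),
    SD = list(X = spectralDerivative(X, 2L, grid), state = list()),
    SGS = list(X = savitzkyGolay(X, step$params$window, step$params$polyorder),
               state = list()),
    NDS = list(X = norrisDerivative(X, step$params$segment, step$params$gap,
                                    order = 1L),
               state = list()),
    stop("parameter error: unknown operator ", step$op))
}

#' Fit a preprocessing strategy on calibration spectra and apply it
#'
#' Operators are applied left to right as written. Stateful operators (the
#' MC column means, the MSC reference spectrum) are fitted on the
#' calibration matrix only — at its position in the composition — and the
#' identical state is re-applied to `X_new`, so no information flows from
#' validation spectra into the transform.
#'
#' @param strategy strategy string or [PreprocessStrategy-class].
#' @param X_cal calibration spectra matrix (spectra in rows).
#' @param X_new optional new/validation spectra matrix.
#' @param grid optional wavenumber grid (passed to the derivative filters).
#' @return `list(cal =, new =, strategy = fitted PreprocessStrategy)`;
#'   `new` is `NULL` when `X_new` is.
#' @seealso [applyStrategy()] to transform further sets with the same fit.
#' @export
fitApplyStrategy <- function(strategy, X_cal, X_new = NULL, grid = NULL) {
  strategy <- preprocessStrategy(strategy)
  validObject(strategy)
  cal <- asSpectraMatrix(X_cal)
  nw <- if (!is.null(X_new)) asSpectraMatrix(X_new)
  fitted <- vector("list", length(strategy@steps))
  for (i in seq_along(strategy@steps)) {
    step <- strategy@steps[[i]]
    resCal <- .applyStep(step, NULL, cal, grid, calMatrix = cal)
    fitted[[i]] <- resCal$state
    cal <- resCal$X
    if (!is.null(nw)) nw <- .applyStep(step, resCal$state, nw, grid, NULL)$X
  }
  strategy@fitted <- fitted
  strategy@isFitted <- TRUE
  list(cal = cal, new = nw, strategy = strategy)
}

#' @rdname fitApplyStrategy
#' @param X spectra matrix to transform with an already fitted strategy.
#' @export
applyStrategy <- function(strategy, X, grid = NULL) {
  if (!is(strategy, "PreprocessStrategy") || !strategy@isFitted)
    stop("state error: strategy must be fitted first (fitApplyStrategy)")
  X <- asSpectraMatrix(X)
  for (i in seq_along(strategy@steps))
    X <- .applyStep(strategy@steps[[i]], strategy@fitted[[i]], X, grid, NULL)$X
  X
}
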