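#' Round half away from zero
#'
#' Display rounding used throughout the package: 93.75 rounds to 93.8, the
#' convention of most chemometric reporting, unlike [base::round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so package randomness never perturbs
## the user's stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

## Coerce a vector or matrix of spectra (rows = spectra) to a matrix.
asSpectraMatrix <- function(X) {
  if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
}

labelLevels <- c("mutant", "wild_type", "unknown")
prepClassLevels <- c("paraffin_embedded", "deparaffinized", "stained")
classLevelsDefault <- c("mutant", "wild_type")
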