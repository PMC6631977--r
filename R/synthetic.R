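#' Default NIR band table for the synthetic generator
#'
#' Gaussian absorption bands at the C-H/O-H overtone and combination
#' positions that distinguish the valine side chain ((CH3)2CH-) of the wild
#' type from the glutamate side chain (-(CH2)2COOH) of the mutant. The
#' `classDelta` column is the signed absorbance shift applied to mutant
#' spectra: CH3-associated bands drop, CH2- and COOH-associated bands rise.
#' All class-bearing bands lie inside the two modeling subranges 9000-6800
#' and 6500-4000 cm^-1.
#'
#' @return `data.frame(center, width, amplitude, classDelta, assignment)`;
#'   centers and Gaussian sigma widths in cm^-1, amplitudes in absorbance.
#' @export
nirBands <- function() {
  data.frame(
    center     = c(8480, 8163, 7355, 7263, 7186, 7080, 6944,
                   5905, 5872, 5680, 5600, 4520, 4395, 4250),
    width      = 40,
    amplitude  = c(0.12, 0.10, 0.12, 0.12, 0.12, 0.12, 0.10,
                   0.20, 0.20, 0.20, 0.15, 0.15, 0.15, 0.18),
    classDelta = c(-0.06, -0.03, -0.08, -0.08, 0.08, 0.08, -0.03,
                   -0.10, -0.10, 0.10, 0.03, -0.06, -0.06, 0.10),
    assignment = c("CH3 2nd overtone", "CH 2nd overtone",
                   "CH3 combination", "CH3 combination",
                   "CH2 combination", "CH2 combination", "CH combination",
                   "CH3 1st overtone", "CH3 1st overtone",
                   "CH2 1st overtone", "CH 1st overtone",
                   "CH3 combination", "CH3 combination",
                   "O-H (COOH) combination"),
    stringsAsFactors = FALSE)
}

#' Synthetic-spectra configuration
#'
#' Frozen defaults emulate the clinical study design: 52 samples per class
#' (40 calibration + 12 validation), three replicate spectra per sample
#' (tissue measured at three locations), a 12000-4000 cm^-1 grid at 4 cm^-1
#' spacing (2001 points), Gaussian bands from [nirBands()], additive
#' preparation interference (paraffin by default), per-replicate
#' multiplicative/additive scatter, band-amplitude jitter (the mutation may
#' occur unevenly across a section) and white absorbance noise.
#'
#' @param n_samples_per_class samples per class (calibration + validation).
#' @param n_validation_per_class validation samples per class.
#' @param replicates replicate spectra per sample (fixed at 3).
#' @param gridStep grid spacing in cm^-1.
#' @param bands band table as from [nirBands()].
#' @param effect_size multiplier on every `classDelta` (0 = null data).
#' @param interference `"paraffin"`, `"he_stain"` or `"none"`; also sets the
#'   stored preparation class.
#' @param scatter_slope_sd,scatter_offset_sd per-replicate multiplicative
#'   slope (around 1) and additive offset (around 0) scatter SDs.
#' @param noise_sd additive white-noise SD in absorbance units.
#' @param replicate_jitter_sd relative SD of per-replicate band-amplitude
#'   jitter.
#' @param seed integer RNG seed; output is a pure function of the config.
#' @return a validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(n_samples_per_class = 52L,
                            n_validation_per_class = 12L,
                            replicates = 3L,
                            gridStep = 4,
                            bands = nirBands(),
                            effect_size = 1.0,
                            interference = c("paraffin", "he_stain", "none"),
                            scatter_slope_sd = 0.05,
                            scatter_offset_sd = 0.02,
                            noise_sd = 0.01,
                            replicate_jitter_sd = 0.1,
                            seed = 1L) {
  interference <- match.arg(interference)
  cfg <- list(
    n_samples_per_class = as.integer(n_samples_per_class),
    n_validation_per_class = as.integer(n_validation_per_class),
    replicates = as.integer(replicates),
    grid = seq(12000, 4000, by = -abs(gridStep)),
    bands = bands, effect_size = effect_size, interference = interference,
    scatter_slope_sd = scatter_slope_sd,
    scatter_offset_sd = scatter_offset_sd,
    noise_sd = noise_sd, replicate_jitter_sd = replicate_jitter_sd,
    seed = as.integer(seed))
  if (cfg$replicates != 3L)
    stop("parameter error: replicates is fixed at 3")
  if (cfg$n_validation_per_class >= cfg$n_samples_per_class)
    stop("parameter error: validation samples must be fewer than total")
  sds <- c(scatter_slope_sd, scatter_offset_sd, noise_sd, replicate_jitter_sd)
  if (any(sds < 0)) stop("parameter error: sd parameters must be >= 0")
  if (any(bands$width <= 0)) stop("parameter error: band widths must be > 0")
  if (any(bands$center > max(cfg$grid) | bands$center < min(cfg$grid)))
    stop("parameter error: band centers must lie within the grid")
  structure(cfg, class = "syntheticConfig")
}

.gaussianBands <- function(grid, centers, widths, amplitudes) {
  G <- vapply(seq_along(centers), function(i)
    amplitudes[i] * exp(-(grid - centers[i])^2 / (2 * widths[i]^2)),
    numeric(length(grid)))
  rowSums(G)
}

## Smooth low-order polynomial baseline rising toward low wavenumbers,
## mimicking the broad tissue/water background of transflectance spectra.
.baseline <- function(grid) {
  u <- (max(grid) - grid) / (max(grid) - min(grid))
  0.45 + 0.25 * u + 0.10 * u^2
}

#' Fixed preparation-interference profiles
#'
#' Additive absorbance contributed by the specimen preparation: paraffin
#' (aliphatic CH2 bands near 5680, 7080-7186 and 4250 cm^-1, moderate
#' amplitude) or hematoxylin-eosin stain (a broad absorbance offset plus
#' bands, stronger than paraffin). Profiles are fixed functions of the grid,
#' identical across calls.
#'
#' @param kind `"paraffin"` or `"he_stain"`.
#' @param grid wavenumber grid.
#' @return numeric vector on `grid`.
#' @export
interferenceProfile <- function(kind = c("paraffin", "he_stain"), grid) {
  kind <- match.arg(kind)
  if (kind == "paraffin") {
    .gaussianBands(grid, c(5680, 7080, 7186, 4250), rep(40, 4),
                   c(0.06, 0.03, 0.03, 0.04))
  } else {
    0.04 + .gaussianBands(grid, c(6900, 5200, 4600), c(120, 150, 120),
                          c(0.04, 0.06, 0.08))
  }
}

#' Noise-free class-difference signature
#'
#' The expected mutant-minus-wild-type mean difference spectrum implied by a
#' configuration: the band deltas scaled by `effect_size`. Linear in
#' `effect_size` and confined, by construction of [nirBands()], to the two
#' modeling subranges.
#'
#' @param config a [syntheticConfig()].
#' @return numeric vector on the config grid.
#' @export
differenceSignature <- function(config) {
  b <- config$bands
  config$effect_size *
    .gaussianBands(config$grid, b$center, b$width, b$classDelta)
}

#' Generate synthetic calibration and validation spectra
#'
#' Each sample draws its class in fixed alternating order (mutant, wild
#' type, mutant, ...; mirroring alternating measurement), with the first
#' `n_samples_per_class - n_validation_per_class` samples of each class
#' forming the calibration set. A sample's noise-free spectrum is the
#' baseline plus the Gaussian bands, with `classDelta * effect_size` added
#' to mutant band amplitudes. Each of the three replicates then receives
#' band-amplitude jitter, a multiplicative/additive scatter transform
#' `a * x + b`, the preparation-interference profile, and white noise. The
#' output is bit-reproducible from the config seed.
#'
#' @param config a [syntheticConfig()].
#' @return `list(calibration = SpectraSet, validation = SpectraSet)`.
#' @export
generateSpectra <- function(config) {
  if (!inherits(config, "syntheticConfig"))
    stop("parameter error: config must come from syntheticConfig()")
  grid <- config$grid
  b <- config$bands
  base <- .baseline(grid)
  interf <- if (config$interference == "none") 0
            else interferenceProfile(config$interference, grid)
  prep <- switch(config$interference,
                 paraffin = "paraffin_embedded",
                 he_stain = "stained",
                 none = "deparaffinized")
  nPer <- config$n_samples_per_class
  nRep <- config$replicates
  classes <- rep(c("mutant", "wild_type"), nPer)  # alternating storage order
  ids <- sprintf("%s%03d", ifelse(classes == "mutant", "M", "W"),
                 rep(seq_len(nPer), each = 2L))
  nSpec <- length(ids) * nRep
  A <- matrix(NA_real_, nSpec, length(grid))
  meta <- data.frame(
    sample_id = rep(ids, each = nRep),
    replicate = rep(seq_len(nRep), times = length(ids)),
    prep_class = prep,
    label = rep(classes, each = nRep),
    stringsAsFactors = FALSE)
  withSeed(config$seed, {
    row <- 0L
    for (s in seq_along(ids)) {
      amp <- b$amplitude +
        if (classes[s] == "mutant") config$effect_size * b$classDelta else 0
      for (r in seq_len(nRep)) {
        row <- row + 1L
        ampJ <- amp * (1 + rnorm(nrow(b), 0, config$replicate_jitter_sd))
        spec <- base + .gaussianBands(grid, b$center, b$width, ampJ)
        a <- 1 + rnorm(1L, 0, config$scatter_slope_sd)
        off <- rnorm(1L, 0, config$scatter_offset_sd)
        A[row, ] <- a * spec + off + interf +
          rnorm(length(grid), 0, config$noise_sd)
      }
    }
  })
  nCalPer <- nPer - config$n_validation_per_class
  calSamples <- ids[rep(seq_len(nPer), each = 2L) <= nCalPer]
  isCal <- meta$sample_id %in% calSamples
  list(
    calibration = SpectraSet(A[isCal, , drop = FALSE], grid,
                             meta[isCal, , drop = FALSE]),
    validation = SpectraSet(A[!isCal, , drop = FALSE], grid,
                            meta[!isCal, , drop = FALSE]))
}
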