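---
title: "Classifying NIR tissue spectra with a counter-propagation neural network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying NIR tissue spectra with a counter-propagation neural network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirCPANN)
```

## The problem

Near-infrared (NIR) spectroscopy measures overtone and combination
vibrations of X–H bonds (X = C, N, O, S) over 12,000–4,000 cm⁻¹. Because
those bands overlap heavily, NIR spectra of tissue are not interpretable
band-by-band; classification instead relies on chemometrics. The clinical
question this package addresses is whether transflectance NIR spectra of
colorectal-cancer tissue sections can discriminate BRAF V600E **mutant**
from **wild-type** tissue. The mutation substitutes valine
((CH₃)₂CH–, a branched dimethyl side chain) with glutamic acid
(–(CH₂)₂COOH), so the discriminating signal is expected where CH₃, CH₂,
CH and carboxylic O–H overtones and combinations absorb — concentrated in
the two subranges **9000–6800 cm⁻¹** and **6500–4000 cm⁻¹** that the
package uses as its default modeling ranges.

The pipeline is: spectral containers and subrange slicing → preprocessing
→ PCA feature reduction → a counter-propagation artificial neural network
(CP-ANN) classifier → per-sample diagnostics with replicate voting.

## Data model

`SpectraSet` extends `SummarizedExperiment`: rows are grid points of a
strictly decreasing wavenumber axis (the FTIR plotting convention),
columns are individual spectra, and the column metadata records the
sample id, the replicate index (each tissue section is measured at three
locations, because the mutation can be distributed unevenly), the
preparation class (paraffin-embedded, deparaffinized, or HE-stained) and
the reference label. Validity enforces a consistent label across a
sample's replicates, which the diagnostic voting relies on.

## Preprocessing

Strategies are ordered compositions written in the usual shorthand
(`"SNV+NDS+FD+MC"`), with mean centering (MC) always last when present:

* **MC** — subtract the calibration column means.
* **MSC** — regress each spectrum on the calibration mean spectrum and
  remove the fitted offset and slope.
* **SNV** — per-spectrum standardization, using the sample (n−1)
  standard deviation (the dominant chemometric convention; changing to
  n would be a one-line edit).
* **FD/SD** — finite differences on the point index, central in the
  interior and one-sided at the ends.
* **SGS** — Savitzky–Golay least-squares smoothing (default window 11,
  polynomial order 3), with terminal-window polynomial evaluation at the
  edges.
* **NDS** — Norris derivative smoothing: a centered segment average
  (default segment 5) followed by a gap difference (default gap 5).

The SGS and NDS defaults are explicit stand-ins: the commercial software
used for the original measurements does not document its kernels, and the
source study reports no window parameters. They are exposed as
`"SGS(window,polyorder)"` / `"NDS(segment,gap)"` suffixes and recorded in
every model archive.

The one rule the module enforces rigidly is **fit-on-calibration
semantics**: the MC means and the MSC reference are computed from the
calibration set only, at their position in the composition, and
re-applied unchanged to any later set. The tests assert that transforming
new spectra can never perturb the fitted state.

## PCA and the 85% rule

PCA is fitted on the preprocessed calibration spectra (SVD of the
centered matrix; loading signs fixed so each column's largest-magnitude
element is positive, making fits reproducible). The number of score
dimensions passed to the classifier is the smallest k whose cumulative
explained variance reaches **85.0%**, read inclusively (≥); the boundary
case is untestable from published one-decimal tables, so the inclusive
reading is simply documented. If no k up to a **cap of 20** components
reaches the threshold, the model is flagged invalid and the grid search
records an NA row rather than a classifier — the behavior seen with
aggressive second-derivative strategies, which spread variance across
many noise-dominated components.

A practical consequence worth knowing: because selection is
variance-based and unsupervised, a *weak* class signal that ranks below
the retained components is silently discarded. On the synthetic data this
produces a sharp transition — at half the default effect size the
selected components carry almost no class information and accuracy sits
near chance, while at the default effect size the class-difference
direction enters the retained set and accuracy is essentially perfect.

## The CP-ANN

The counter-propagation network is a supervised Kohonen map: an S×S grid
of neurons (S chosen from 10, 12, 15; default 12) with input-layer
weights in score space and an output layer of per-neuron class weights.
The original study gives no training equations, so the package implements
the standard variant and documents every choice:

* winner = neuron with minimal Euclidean distance to the input; distance
  ties break to the lowest (row, column), lexicographically.
* all neurons within the current radius update both layers:
  `w ← w + lr · h · (x − w)` and `o ← o + lr · h · (t − o)` with `t` the
  one-hot label and `h = 1 − d/(radius + 1)` a triangular factor in the
  Chebyshev map distance.
* learning rate decays linearly (default 0.5 → 0.01) and the radius
  shrinks linearly from S/2 to 0 over the epochs (default 100);
  the map is non-toroidal.
* presentation order is reshuffled each epoch, deterministically from the
  model seed; everything downstream of a seed is bit-reproducible.

Because the output update is a convex combination, each neuron's class
weights remain a probability vector throughout training; prediction is
the argmax of the winner's class weights (ties toward the lower class
index, i.e. mutant). `projectMap()` reproduces the projection-map view:
neurons colored by majority class, each spectrum placed at its winner
with a correctness flag.

Classification accuracies follow the usual calibration /
cross-validation / validation split (CAC / CACV / CAV, per spectrum).
Cross-validation is **grouped by sample** — all three replicates share a
fold — and stratified by class, since splitting replicates across folds
would leak near-duplicate spectra into training and inflate CACV. The
original study does not state its CV scheme; 5-fold grouped CV is this
package's default and a known deviation risk when comparing CACV values.

## Model selection

`runGrid()` evaluates every strategy × subrange × map-side combination
under one shared seed and `selectBest()` ranks rows by CAV, then CAC,
then CACV, then smaller maps and fewer components. The published
criterion ("highest CAC and CAV") is ambiguous when the two conflict;
CAV ranks first here because validation accuracy is the generalization
claim.

## Diagnostics

Mutant is the positive class throughout. A sample is diagnosed wild type
only when **all three** replicate predictions are wild type (the OR
rule), which provably cannot lower sensitivity and cannot raise
specificity relative to per-spectrum counting — missing a mutant is the
costly error. Sensitivity, specificity and accuracy are kept at full
precision internally and rounded half-up to one decimal for display
(75/80 prints as 93.8). A metric whose denominator is empty (e.g.
sensitivity with no mutant samples) is reported as missing with a
warning, never as zero.

## The synthetic generator

No clinical spectra are distributed with the study, so the package ships
a generator whose frozen defaults emulate the study design: 52 samples
per class (40 calibration + 12 validation), three replicates each,
12,000–4,000 cm⁻¹ at 4 cm⁻¹ spacing (a plausible digitization of the
8 cm⁻¹ instrument resolution). Each spectrum is

> baseline (low-order polynomial) + Gaussian bands (σ = 40 cm⁻¹, the
> breadth of NIR overtones) + preparation interference + per-replicate
> scatter (`a·x + b`, slope SD 0.05, offset SD 0.02) + band-amplitude
> jitter (10% relative) + white noise (SD 0.01 absorbance).

The band centers sit at the CH₃/CH₂/CH/O–H positions listed above; the
class effect lowers CH₃-associated amplitudes and raises CH₂- and
COOH-associated ones, as the valine→glutamate substitution suggests. The
published work quantifies no absorbance differences, so the effect
magnitudes (±0.03–0.10 absorbance at band peak) are free parameters of
this package. They were fixed once, by a variance budget: the
class-difference direction must carry variance comparable to the scatter
components so that it falls inside the ≥85% retained set, which is what
the published component counts (roughly 5–6 components at ~100%
cumulative variance) imply about the real data. Interference profiles
are fixed vectors: paraffin contributes moderate aliphatic CH₂ bands,
HE stain a broader and stronger profile, matching their reported
relative strength.

What the generator does **not** emulate: Beer–Lambert tissue optics,
instrument line shapes, water-band dominance, or absolute absorbance
levels. Passing tests on synthetic data therefore demonstrate that the
*pipeline machinery* behaves as specified (leakage guards, selection
rules, voting arithmetic, reproducibility) and that the method recovers a
class signal with the assumed structure — they do not validate clinical
performance.

## Numerical and design choices, in brief

* Subrange membership is boundary-inclusive on both ends (closed ranges).
* Grids are stored strictly decreasing; duplicate wavenumbers are errors.
* MSC slope below 1e−12 in magnitude is a degenerate-fit error.
* PCA on an all-zero matrix is a degenerate error; an invalid (NA) PCA
  model refuses to project.
* Map sizes other than 10/12/15 are allowed programmatically (tests use
  tiny maps); the canonical sizes are only a screening convention.
* Samples with fewer than three replicates are diagnosed from the
  replicates present, with a warning.

## Problem sizes used in the tests

The shipped test-suite and acceptance runs use the full frozen design
(240 calibration / 72 validation spectra, 1177 grid points after
subranging, 12×12 map, 100 epochs) for the end-to-end checks — about two
seconds per run — with five seeds for the headline medians and twenty
seeds for the null control (effect size 0, where validation accuracy
must sit inside the 99% binomial band around 50%). Unit tests use tiny
fixtures (two-cluster scores, 5×4 random matrices, 90-spectrum noise
sets) chosen so each oracle comparison is exact or near-exact.

## Known limitations

* CACV is scheme-dependent and the original scheme is unknown; only CAC
  and CAV are compared against published values as bounds.
* The commercial preprocessing kernels (derivatives possibly embedding
  smoothing) are not reproduced; strategies are compositional and
  documented instead.
* The synthetic effect sizes are stand-ins; absolute agreement with the
  published per-strategy table (row by row) is out of reach without the
  clinical spectra and is not claimed.
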