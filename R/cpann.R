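## Counter-propagation ANN: a square, non-toroidal Kohonen map whose
## input-layer weights compete for each PC-score vector, coupled to an
## output layer of per-neuron class weights updated toward the one-hot label
## of each input. Neurons are stored row-major: index n <-> (row, col) with
## n = (row - 1) * S + col, so which.min() tie-breaking is lexicographic in
## (row, col).

.neuronCoords <- function(S) {
  cbind(row = rep(seq_len(S), each = S), col = rep(seq_len(S), times = S))
}

#' Initialize a counter-propagation ANN
#'
#' Input-layer weights are drawn uniformly on \[0, 1\] per dimension
#' (rescaled to the per-dimension score range when training starts); output
#' class weights start uniform at `1/C`. Fully deterministic given `seed`.
#'
#' @param S neurons per map side (the map is `S x S`).
#' @param d input dimensionality (number of PC scores).
#' @param C number of classes (2).
#' @param seed integer RNG seed.
#' @param epochs,lrStart,lrEnd training hyperparameters stored with the
#'   model: number of passes over the data and the linearly decaying
#'   learning rate.
#' @param classLevels class names in output-column order; the first level is
#'   the positive (mutant) class.
#' @return an untrained [CPANNModel-class].
#' @export
initMap <- function(S, d, C = 2L, seed = 1L, epochs = 100L,
                    lrStart = 0.5, lrEnd = 0.01,
                    classLevels = classLevelsDefault) {
  S <- as.integer(S); d <- as.integer(d); C <- as.integer(C)
  if (S < 1L || d < 1L || C < 2L)
    stop("parameter error: S >= 1, d >= 1, C >= 2 required")
  if (length(classLevels) != C)
    stop("parameter error: classLevels length must equal C")
  W <- withSeed(seed, matrix(stats::runif(S * S * d), nrow = S * S, ncol = d))
  O <- matrix(1 / C, nrow = S * S, ncol = C,
              dimnames = list(NULL, classLevels))
  new("CPANNModel", S = S, d = d, nClasses = C, kohonenW = W, outputW = O,
      classLevels = classLevels, epochs = as.integer(epochs),
      lrStart = lrStart, lrEnd = lrEnd, seed = as.integer(seed),
      trained = FALSE)
}

.oneHot <- function(labels, classLevels) {
  if (is.matrix(labels)) {
    if (any(!labels %in% c(0, 1)) || any(abs(rowSums(labels) - 1) > 1e-12))
      stop("label error: rows must be one-hot")
    return(labels)
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), classLevels)
  if (length(bad))
    stop("label error: unknown class label(s): ", paste(bad, collapse = ", "))
  T <- matrix(0, length(labels), length(classLevels),
              dimnames = list(NULL, classLevels))
  T[cbind(seq_along(labels), match(labels, classLevels))] <- 1
  T
}

#' Train a counter-propagation ANN
#'
#' For each epoch, inputs are presented in a seed-controlled shuffled order.
#' The winner is the neuron whose input-layer weights are nearest the input
#' in Euclidean distance (ties to the lowest (row, col)). All neurons within
#' the current neighborhood radius move toward the input and — in the output
#' layer — toward its one-hot label, by `lr * h`, where
#' `h = 1 - dist / (radius + 1)` is a triangular factor in the Chebyshev
#' map distance. The learning rate decays linearly `lrStart -> lrEnd` and
#' the radius shrinks linearly from `S/2` to 0 over the epochs (non-toroidal
#' map). Output-weight updates are convex combinations, so each neuron's
#' class weights stay in \[0, 1\] and sum to 1 throughout.
#'
#' @param model an initialized [CPANNModel-class].
#' @param scores input matrix (`n x d`), typically PC scores.
#' @param labels class-label vector (values in `model@classLevels`) or a
#'   one-hot matrix in that column order.
#' @param epochs optional override of the stored epoch count.
#' @param shuffle present inputs in seed-controlled shuffled order (default)
#'   or in the given row order.
#' @return the trained model.
#' @export
trainCPANN <- function(model, scores, labels, epochs = NULL, shuffle = TRUE) {
  if (!is(model, "CPANNModel")) stop("state error: need a CPANNModel")
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop("data error: no training spectra")
  if (ncol(scores) != model@d)
    stop("shape error: scores have ", ncol(scores), " dims, model expects ",
         model@d)
  T <- .oneHot(labels, model@classLevels)
  if (nrow(T) != nrow(scores))
    stop("shape error: labels rows must match scores rows")
  n <- nrow(scores)
  epochs <- if (is.null(epochs)) model@epochs else as.integer(epochs)

  ## rescale the raw U[0,1] initial weights to the per-dimension score range
  lo <- apply(scores, 2L, min); hi <- apply(scores, 2L, max)
  W <- sweep(sweep(model@kohonenW, 2L, hi - lo, `*`), 2L, lo, `+`)
  O <- model@outputW
  coords <- .neuronCoords(model@S)

  orders <- withSeed(model@seed + 1L, lapply(seq_len(epochs), function(e)
    if (shuffle) sample.int(n) else seq_len(n)))

  for (e in seq_len(epochs)) {
    frac <- if (epochs > 1L) (e - 1) / (epochs - 1) else 1
    lr <- model@lrStart + (model@lrEnd - model@lrStart) * frac
    radius <- (model@S / 2) * (1 - frac)
    for (i in orders[[e]]) {
      x <- scores[i, ]
      d2 <- rowSums((W - rep(x, each = nrow(W)))^2)
      win <- which.min(d2)
      dt <- pmax(abs(coords[, 1L] - coords[win, 1L]),
                 abs(coords[, 2L] - coords[win, 2L]))
      nb <- which(dt <= radius)
      h <- lr * (1 - dt[nb] / (radius + 1))
      W[nb, ] <- W[nb, ] + h * (rep(x, each = length(nb)) - W[nb, , drop = FALSE])
      O[nb, ] <- O[nb, ] + h * (rep(T[i, ], each = length(nb)) - O[nb, , drop = FALSE])
    }
  }
  model@kohonenW <- W
  model@outputW <- O
  model@epochs <- epochs
  model@trained <- TRUE
  validObject(model)
  model
}

#' Predict classes with a trained CP-ANN
#'
#' Each input is assigned to its winning (nearest) neuron; the predicted
#' class is the argmax of that neuron's output-layer class weights, ties
#' broken toward the lower class index.
#'
#' @param object a trained [CPANNModel-class].
#' @param scores input matrix (`n x d`).
#' @return `list(class = character vector, coords = n x 2 matrix of winner
#'   (row, col))`.
#' @export
setMethod("predict", "CPANNModel", function(object, scores) {
  if (!object@trained) stop("state error: model is untrained")
  scores <- as.matrix(scores)
  if (ncol(scores) != object@d)
    stop("shape error: scores have ", ncol(scores), " dims, model expects ",
         object@d)
  coords <- .neuronCoords(object@S)
  n <- nrow(scores)
  cls <- character(n)
  win <- integer(n)
  for (i in seq_len(n)) {
    d2 <- rowSums((object@kohonenW - rep(scores[i, ], each = nrow(object@kohonenW)))^2)
    win[i] <- which.min(d2)
    cls[i] <- object@classLevels[which.max(object@outputW[win[i], ])]
  }
  list(class = cls, coords = coords[win, , drop = FALSE])
})

#' Map-projection report
#'
#' Summarizes a trained map the way the projection figures do: every neuron
#' is colored by its majority class (argmax of the output weights), and
#' every spectrum is placed at its winning neuron with its role (calibration
#' or validation), true and predicted class, and a correctness flag (the
#' circled markers being the incorrect ones).
#'
#' @param model a trained [CPANNModel-class].
#' @param scores input matrix.
#' @param meta per-spectrum metadata `data.frame` with `sample_id`,
#'   `replicate` and `label` columns.
#' @param role `"calibration"` or `"validation"`, recycled over spectra.
#' @return `list(regions = S x S character matrix of class regions,
#'   placements = data.frame)` of class `cpannMapReport`.
#' @export
projectMap <- function(model, scores, meta, role = "calibration") {
  pr <- predict(model, scores)
  regions <- matrix(model@classLevels[apply(model@outputW, 1L, which.max)],
                    nrow = model@S, ncol = model@S, byrow = TRUE)
  role <- rep_len(role, nrow(as.matrix(scores)))
  marker <- ifelse(meta$label == "mutant", "M", "W")
  marker[role == "validation"] <- tolower(marker[role == "validation"])
  placements <- data.frame(
    sample_id = meta$sample_id, replicate = meta$replicate,
    row = pr$coords[, 1L], col = pr$coords[, 2L],
    label = meta$label, predicted = pr$class,
    correct = pr$class == meta$label, role = role, marker = marker,
    stringsAsFactors = FALSE)
  structure(list(regions = regions, placements = placements),
            class = "cpannMapReport")
}

#' Render a map report as a text grid
#'
#' One cell per neuron: `#` marks a mutant-region neuron, `.` a wild-type
#' one; occupied neurons show their marker letter (`M`/`W` calibration,
#' `m`/`w` validation), with `o` appended if any spectrum there is
#' misclassified.
#'
#' @param report a `cpannMapReport` from [projectMap()].
#' @return character vector, one line per map row.
#' @export
mapToText <- function(report) {
  S <- nrow(report$regions)
  cells <- matrix(ifelse(report$regions == "mutant", "#", "."), S, S)
  p <- report$placements
  for (i in seq_len(nrow(p))) {
    cur <- cells[p$row[i], p$col[i]]
    base <- if (nchar(cur) > 1L) substr(cur, 1L, 2L) else paste0(cur, p$marker[i])
    if (!p$correct[i] && !grepl("o", cur, fixed = TRUE)) base <- paste0(base, "o")
    cells[p$row[i], p$col[i]] <- base
  }
  apply(cells, 1L, function(r) paste(formatC(r, width = -4), collapse = ""))
}

#' Sample-grouped cross-validated classification accuracy
#'
#' k-fold cross-validation in which all replicate spectra of a tissue sample
#' share a fold (no replicate leakage between training and held-out data),
#' stratified by class at the sample level. The reported accuracy (CACV)
#' pools the held-out per-spectrum predictions over all folds.
#'
#' @param scores input matrix (`n x d`).
#' @param labels per-spectrum class labels.
#' @param sampleIds per-spectrum sample identifiers (replicates share one).
#' @param folds number of folds (default 5).
#' @param S map side; other arguments as in [initMap()].
#' @param seed seed for map initialization, training order and fold
#'   assignment.
#' @return `list(cacvPct =, predictions = data.frame(sample_id, label,
#'   predicted, fold))`.
#' @export
crossValidate <- function(scores, labels, sampleIds, folds = 5L, S = 12L,
                          seed = 1L, epochs = 100L, lrStart = 0.5,
                          lrEnd = 0.01, classLevels = classLevelsDefault) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  if (folds < 2L) stop("parameter error: folds must be >= 2")
  samples <- unique(sampleIds)
  if (folds > length(samples))
    stop("parameter error: folds exceed number of samples")
  sampleClass <- vapply(samples, function(s)
    unique(labels[sampleIds == s])[1L], "")
  ## stratified fold assignment: shuffle samples within class, deal cyclically
  foldOf <- withSeed(seed + 2L, {
    f <- setNames(integer(length(samples)), samples)
    for (cl in unique(sampleClass)) {
      idx <- sample(which(sampleClass == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  pred <- character(length(labels))
  foldVec <- foldOf[match(sampleIds, samples)]
  for (k in seq_len(folds)) {
    hold <- foldVec == k
    if (!any(hold)) next
    m <- initMap(S, ncol(scores), C = length(classLevels), seed = seed,
                 epochs = epochs, lrStart = lrStart, lrEnd = lrEnd,
                 classLevels = classLevels)
    m <- trainCPANN(m, scores[!hold, , drop = FALSE], labels[!hold])
    pred[hold] <- predict(m, scores[hold, , drop = FALSE])$class
  }
  list(cacvPct = 100 * mean(pred == labels),
       predictions = data.frame(sample_id = sampleIds, label = labels,
                                predicted = pred, fold = foldVec,
                                stringsAsFactors = FALSE))
}
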