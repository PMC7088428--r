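#' @include feature-selection.R evaluation.R
NULL

#' Default hyperparameter grid
#'
#' The libsvm practitioner's grid: C over 2^-5 .. 2^15 and gamma over
#' 2^-15 .. 2^3, both in steps of 2^2.
#'
#' @return List with numeric vectors `C` and `gamma`.
#' @export
defaultGrid <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `folds` folds so that, within every
#' class, fold sizes differ by at most one. The assignment depends only on
#' `(labels, folds, seed)`; the caller's RNG state is untouched.
#'
#' @param labels Class label per sample.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..folds.
#' @export
stratifiedFolds <- function(labels, folds = 10L, seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_local_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

# Min-max scale columns to [0,1] with given training statistics;
# constant training columns map to 0.
.scale_minmax <- function(mat, mins, maxs) {
  rng <- maxs - mins
  rng[rng == 0] <- 1
  sweep(sweep(mat, 2, mins), 2, rng, "/")
}

#' Train a multi-class RBF-SVM
#'
#' Min-max scales the training features to [0,1] (statistics stored in the
#' model and re-applied at prediction), then fits a one-vs-one multi-class
#' support vector machine with a radial-basis kernel via libsvm (e1071).
#'
#' @param mat Numeric training matrix (samples x features, named
#'   columns).
#' @param labels Class label per row; at least two classes.
#' @param config An [SVMConfig-class].
#' @param featureIndex Optional integer indices selecting a feature subset
#'   (e.g. from [topFeatures()]); default all columns.
#' @return A [MitoSVMModel-class].
#' @export
trainSVM <- function(mat, labels, config = svmConfig(),
                     featureIndex = seq_len(ncol(mat))) {
  stopifnot(is.matrix(mat), nrow(mat) == length(labels))
  y <- factor(as.character(labels))
  if (nlevels(y) < 2L)
    stop("training needs at least two classes", call. = FALSE)
  featureIndex <- as.integer(featureIndex)
  sub <- mat[, featureIndex, drop = FALSE]
  mins <- apply(sub, 2, min)
  maxs <- apply(sub, 2, max)
  weights <- NULL
  if (config@classWeighting == "balanced") {
    tab <- table(y)
    weights <- as.numeric(sum(tab) / (nlevels(y) * tab))
    names(weights) <- names(tab)
  }
  fit <- e1071::svm(x = .scale_minmax(sub, mins, maxs), y = y,
                    kernel = "radial", cost = config@C,
                    gamma = config@gamma, scale = FALSE,
                    class.weights = weights)
  new("MitoSVMModel", fit = fit, featureIndex = featureIndex,
      featureNames = colnames(mat)[featureIndex],
      scaleMin = mins, scaleMax = maxs,
      config = config, levels = levels(y))
}

.model_newdata <- function(object, mat) {
  if (ncol(mat) == length(object@featureIndex) &&
      (is.null(colnames(mat)) ||
       identical(colnames(mat), object@featureNames))) {
    sub <- mat
  } else if (ncol(mat) >= max(object@featureIndex)) {
    sub <- mat[, object@featureIndex, drop = FALSE]
  } else {
    stop("input has ", ncol(mat), " features; model needs the ",
         length(object@featureIndex), " selected from a ",
         max(object@featureIndex), "+ column matrix", call. = FALSE)
  }
  .scale_minmax(sub, object@scaleMin, object@scaleMax)
}

#' Predict compartment labels
#'
#' @param object A [MitoSVMModel-class].
#' @param mat Feature matrix: either the full layout the model was
#'   selected from, or exactly the model's feature subset.
#' @param ... Ignored.
#' @return Character vector of predicted class labels.
#' @export
setMethod("predict", "MitoSVMModel", function(object, mat, ...) {
  pred <- stats::predict(object@fit, .model_newdata(object, mat))
  as.character(pred)
})

#' One-vs-rest decision scores
#'
#' Aggregates the one-vs-one libsvm decision values into a per-class
#' score (the signed sum of all pairwise decision values involving the
#' class), suitable for one-vs-rest ROC analysis.
#'
#' @param object A [MitoSVMModel-class].
#' @param mat Feature matrix as in [predict,MitoSVMModel-method].
#' @return Numeric matrix, samples x classes.
#' @export
decisionScores <- function(object, mat) {
  stopifnot(is(object, "MitoSVMModel"))
  pred <- stats::predict(object@fit, .model_newdata(object, mat),
                         decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  out <- matrix(0, nrow(dv), length(object@levels),
                dimnames = list(rownames(mat), object@levels))
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    out[, pair[1]] <- out[, pair[1]] + dv[, cn]
    out[, pair[2]] <- out[, pair[2]] - dv[, cn]
  }
  out
}

#' Grid search for C and gamma
#'
#' Evaluates every (C, gamma) pair by mean stratified k-fold
#' cross-validated accuracy and returns the best configuration; ties are
#' broken toward smaller C, then smaller gamma. Deterministic given the
#' seed (folds are fixed once for the whole grid).
#'
#' @param mat Feature matrix.
#' @param labels Class labels (>= `folds` samples per class).
#' @param grid List with numeric vectors `C` and `gamma`; default
#'   [defaultGrid()].
#' @param folds CV folds (default 10).
#' @param seed Integer seed (default 1).
#' @param classWeighting Passed to [svmConfig()].
#' @return The winning [SVMConfig-class].
#' @export
gridSearch <- function(mat, labels, grid = defaultGrid(), folds = 10L,
                       seed = 1L, classWeighting = "none") {
  if (!length(grid$C) || !length(grid$gamma))
    stop("grid must contain non-empty C and gamma vectors",
         call. = FALSE)
  if (min(table(labels)) < folds)
    stop("need at least `folds` samples per class", call. = FALSE)
  fold <- stratifiedFolds(labels, folds, seed)
  best <- NULL
  bestAcc <- -Inf
  for (C in sort(grid$C)) {
    for (g in sort(grid$gamma)) {
      cfg <- svmConfig(C = C, gamma = g,
                       classWeighting = classWeighting, seed = seed)
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        model <- trainSVM(mat[tr, , drop = FALSE], labels[tr], cfg)
        pred <- predict(model, mat[!tr, , drop = FALSE])
        correct <- correct + sum(pred == labels[!tr])
      }
      acc <- correct / length(labels)
      if (acc > bestAcc + 1e-12) {
        bestAcc <- acc
        best <- cfg
      }
    }
  }
  best
}

#' Stratified k-fold cross-validation
#'
#' Runs seeded stratified k-fold cross-validation of the RBF-SVM. Feature
#' scaling — and, when `topK` is given, information-gain ranking and
#' selection — are re-fit inside each training fold, so no statistic of a
#' test fold leaks into its model. Every sample is tested exactly once.
#'
#' @param mat Full feature matrix.
#' @param labels Class labels (>= `folds` per class).
#' @param config An [SVMConfig-class].
#' @param folds Number of folds (default 10).
#' @param seed Fold-shuffling seed (default `config@seed`).
#' @param topK Optional number of features to select per training fold by
#'   information gain; `NULL` (default) uses all features.
#' @param bins Discretization bins for the per-fold ranking.
#' @return List with elements `confusion` (aggregated
#'   [ConfusionCounts-class]), `perFold` (list of per-fold
#'   ConfusionCounts), `accuracy` (overall), `foldAccuracy`, `predicted`,
#'   `scores` (one-vs-rest decision scores, samples x classes) and
#'   `fold` (the fold assignment).
#' @export
crossValidate <- function(mat, labels, config = svmConfig(),
                          folds = 10L, seed = config@seed,
                          topK = NULL, bins = 10L) {
  stopifnot(is.matrix(mat), nrow(mat) == length(labels))
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (min(table(labels)) < folds)
    stop("need at least `folds` samples per class", call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  fold <- stratifiedFolds(labels, folds, seed)
  predicted <- character(length(labels))
  scores <- matrix(NA_real_, length(labels), length(lev),
                   dimnames = list(rownames(mat), lev))
  perFold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    sel <- seq_len(ncol(mat))
    if (!is.null(topK) && topK < ncol(mat)) {
      rfs <- rankFeatures(mat[tr, , drop = FALSE], labels[tr],
                          bins = bins)
      sel <- topFeatures(rfs, topK)
    }
    model <- trainSVM(mat[tr, , drop = FALSE], labels[tr], config,
                      featureIndex = sel)
    te <- which(!tr)
    predicted[te] <- predict(model, mat[te, , drop = FALSE])
    sc <- decisionScores(model, mat[te, , drop = FALSE])
    scores[te, colnames(sc)] <- sc
    perFold[[f]] <- confusionCounts(labels[te], predicted[te],
                                    levels = lev)
  }
  confusion <- confusionCounts(labels, predicted, levels = lev)
  foldAcc <- vapply(perFold, function(cc)
    sum(diag(cc@counts)) / sum(cc@counts), numeric(1))
  list(confusion = confusion, perFold = perFold,
       accuracy = sum(diag(confusion@counts)) / sum(confusion@counts),
       foldAccuracy = foldAcc, predicted = predicted,
       scores = scores, fold = fold)
}

#' Save / load a trained model
#'
#' The model is persisted as a single self-describing RDS file holding the
#' fitted parameters, the feature subset and names, the scaling statistics
#' and the configuration.
#'
#' @param object A [MitoSVMModel-class].
#' @param path File path.
#' @return `saveModel`: `path` invisibly; `loadModel`: the model.
#' @export
saveModel <- function(object, path) {
  stopifnot(is(object, "MitoSVMModel"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!is(obj, "MitoSVMModel")) stop("not a saved model", call. = FALSE)
  obj
}
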