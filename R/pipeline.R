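#' @include classifier.R features.R simulate.R
NULL

#' Reduced tuning grid for the end-to-end pipeline
#'
#' A 3 x 3 subset of [defaultGrid()] (C in 2^\{0,3,6\}, gamma in
#' 2^\{-7,-5,-3\}) used by the pipeline runner, where the full libsvm grid
#' would be spent re-tuning a well-conditioned problem.
#'
#' @return List with vectors `C` and `gamma`.
#' @export
pipelineGrid <- function() {
  list(C = 2^c(0, 3, 6), gamma = 2^c(-7, -5, -3))
}

#' End-to-end cross-validated pipeline
#'
#' Runs the complete predictor on a labelled [ProteinSet-class]: encode
#' all sequences as 239 features, tune (C, gamma) by grid search, then
#' estimate performance by stratified k-fold cross-validation with
#' per-fold information-gain selection of the `topK` features.
#'
#' @param proteins A labelled [ProteinSet-class] (no `NA` labels).
#' @param topK Features kept per training fold (`NULL` or "all" for all
#'   239).
#' @param folds CV folds (default 10).
#' @param seed Seed for fold assignment and tuning (default 1).
#' @param grid Tuning grid (default [pipelineGrid()]).
#' @param bins Information-gain discretization bins (default 10).
#' @param scheme,scales Encoder resources.
#' @param features Optional pre-computed feature matrix (skips encoding).
#' @return List with `features`, `config`, `cv` (see [crossValidate()])
#'   and `metrics` (a [MetricsReport-class] with per-class AUC).
#' @export
runPipelineCV <- function(proteins, topK = 200L, folds = 10L, seed = 1L,
                          grid = pipelineGrid(), bins = 10L,
                          scheme = defaultGroupingScheme(),
                          scales = defaultPhyschemScales(),
                          features = NULL) {
  labels <- unname(classLabels(proteins))
  if (anyNA(labels))
    stop("all sequences must be labelled", call. = FALSE)
  if (is.null(features))
    features <- encodeFeatures(proteins, scheme = scheme,
                               scales = scales)
  if (identical(topK, "all")) topK <- NULL
  config <- gridSearch(features, labels, grid = grid, folds = folds,
                       seed = seed)
  cv <- crossValidate(features, labels, config, folds = folds,
                      seed = seed, topK = topK, bins = bins)
  metrics <- metricsReport(cv$confusion, scores = cv$scores,
                           truth = labels)
  list(features = features, config = config, cv = cv,
       metrics = metrics)
}

#' Cross-validated accuracy per feature-subset size
#'
#' Reproduces the accuracy-versus-subset layout of the evaluation
#' protocol: one row per requested subset size (e.g. the nested top
#' 10/50/100/150/200 plus all features), with the stratified k-fold CV
#' accuracy of the tuned model on that subset.
#'
#' @param proteins A labelled [ProteinSet-class].
#' @param topKs Subset sizes; numbers or "all" (default
#'   `c(10, 50, 100, 150, 200, "all")`).
#' @param scheme,scales Encoder resources (sequences are encoded once,
#'   shared across subset sizes).
#' @param ... Passed to [runPipelineCV()] (folds, seed, grid, ...).
#' @return Data frame with columns `features` and `cv_accuracy`.
#' @export
featureSubsetTable <- function(proteins,
                               topKs = c(10, 50, 100, 150, 200, "all"),
                               scheme = defaultGroupingScheme(),
                               scales = defaultPhyschemScales(),
                               ...) {
  feats <- encodeFeatures(proteins, scheme = scheme, scales = scales)
  rows <- lapply(topKs, function(k) {
    res <- runPipelineCV(proteins, topK = if (identical(k, "all"))
      "all" else as.integer(k), features = feats, ...)
    data.frame(features = as.character(k),
               cv_accuracy = res$cv$accuracy)
  })
  do.call(rbind, rows)
}
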