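#' @include AllClasses.R
NULL

#' Extract the amino-acid sequences
#' @param x A [ProteinSet-class].
#' @return An `AAStringSet`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Extract the free-text annotations
#' @param x A [ProteinSet-class].
#' @return Character vector.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' Extract the compartment labels
#' @param x A [ProteinSet-class].
#' @return Character vector over [MITO_CLASSES] with `NA` for unlabelled
#'   records.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Replace the compartment labels
#' @param x A [ProteinSet-class].
#' @param value Character vector of labels.
#' @return The modified object.
#' @export
setGeneric("classLabels<-", function(x, value) standardGeneric("classLabels<-"))

#' Apply the dataset curation filters
#'
#' @param x A [ProteinSet-class].
#' @param ... Filter parameters, see the method.
#' @return A [CurationReport-class].
#' @export
setGeneric("curate", function(x, ...) standardGeneric("curate"))

#' Remove redundant sequences by greedy identity clustering
#'
#' @param x A [ProteinSet-class].
#' @param ... Parameters, see the method.
#' @return A [ProteinSet-class] of cluster representatives.
#' @export
setGeneric("reduceRedundancy", function(x, ...)
  standardGeneric("reduceRedundancy"))

#' Encode sequences as feature matrices
#'
#' @param x A [ProteinSet-class] or character vector of sequences.
#' @param ... Encoder parameters, see [encodeFeatures,ProteinSet-method].
#' @return Numeric matrix, one row per sequence, 239 named columns.
#' @export
setGeneric("encodeFeatures", function(x, ...)
  standardGeneric("encodeFeatures"))

#' Retained sequences of a curation report
#' @param x A [CurationReport-class].
#' @return A [ProteinSet-class].
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' Per-filter removal counts of a curation report
#' @param x A [CurationReport-class].
#' @return Named integer vector.
#' @export
setGeneric("removedCounts", function(x) standardGeneric("removedCounts"))

#' Secondary-structure state string
#' @param x An [SSEAssignment-class].
#' @return Single string over H/E/C.
#' @export
setGeneric("sseStates", function(x) standardGeneric("sseStates"))

#' Helix/sheet/coil content fractions
#' @param x An [SSEAssignment-class].
#' @return Named numeric of length 3.
#' @export
setGeneric("sseContent", function(x) standardGeneric("sseContent"))

#' Information-gain scores of a ranking
#' @param x A [RankedFeatureSet-class].
#' @return Named numeric vector (bits).
#' @export
setGeneric("igScores", function(x) standardGeneric("igScores"))

#' Indices of the top-k ranked features
#'
#' Subsets are nested: `topFeatures(x, k)` is a prefix of
#' `topFeatures(x, k')` for `k <= k'`.
#'
#' @param x A [RankedFeatureSet-class].
#' @param k Number of features, or `Inf`/"all" for every feature.
#' @return Integer vector of feature indices, best first.
#' @export
setGeneric("topFeatures", function(x, k) standardGeneric("topFeatures"))

#' Confusion matrix of counts
#' @param x A [ConfusionCounts-class].
#' @return Integer matrix (true classes in rows, predicted in columns).
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' One-vs-rest TP/FP/TN/FN per class
#' @param x A [ConfusionCounts-class].
#' @return Data frame with columns class, TP, FP, TN, FN.
#' @export
setGeneric("ovrCounts", function(x) standardGeneric("ovrCounts"))
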