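#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom e1071 svm
#' @importFrom stats predict sd
#' @importFrom utils read.delim write.table
NULL

#' Standard amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order. This fixed
#' ordering is used for every composition-type feature block.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' Mitochondrial compartment labels
#'
#' The four sub-mitochondrial localization classes recognised by the
#' predictor, in canonical order.
#'
#' @format Character vector of length 4.
#' @export
MITO_CLASSES <- c("inner_membrane", "intermembrane_space",
                  "matrix", "outer_membrane")

# ---------------------------------------------------------------------------
# ProteinSet
# ---------------------------------------------------------------------------

#' ProteinSet: labelled protein sequences
#'
#' A set of protein sequences with identifiers, optional free-text
#' localization annotation (used by the curation filters) and an optional
#' compartment label per sequence.
#'
#' @slot sequences An [Biostrings::AAStringSet] with unique, non-empty names.
#' @slot annotation Character vector, one free-text annotation per sequence
#'   (may be "").
#' @slot label Character vector, one of [MITO_CLASSES] or `NA` per sequence.
#'
#' @seealso [ProteinSet()], [readProteinSet()], [curate()],
#'   [reduceRedundancy()]
#' @export
setClass("ProteinSet",
  representation(sequences = "AAStringSet",
                 annotation = "character",
                 label = "character"))

setValidity("ProteinSet", function(object) {
  n <- length(object@sequences)
  ids <- names(object@sequences)
  msg <- character()
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all sequences must have non-empty ids")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (n > 0 && any(Biostrings::width(object@sequences) < 1))
    msg <- c(msg, "sequences must have length >= 1")
  if (length(object@annotation) != n)
    msg <- c(msg, "annotation length must match number of sequences")
  if (length(object@label) != n)
    msg <- c(msg, "label length must match number of sequences")
  bad <- !is.na(object@label) & !(object@label %in% MITO_CLASSES)
  if (any(bad))
    msg <- c(msg, paste0("unknown class label(s): ",
      paste(unique(object@label[bad]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences Character vector of amino-acid sequences or an
#'   `AAStringSet`.
#' @param ids Sequence identifiers; defaults to `names(sequences)`.
#' @param annotation Free-text localization annotation per sequence
#'   (recycled if scalar; default "").
#' @param label Compartment label per sequence, one of [MITO_CLASSES] or
#'   `NA` (recycled if scalar).
#' @return A [ProteinSet-class] object.
#' @examples
#' ps <- ProteinSet(c(P1 = "MKLVA", P2 = "GGSTR"),
#'                  label = c("matrix", NA))
#' ps
#' @export
ProteinSet <- function(sequences, ids = names(sequences),
                       annotation = "", label = NA_character_) {
  force(ids)
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(unname(as.character(sequences)))
  n <- length(sequences)
  if (!is.null(ids)) names(sequences) <- ids
  annotation <- rep_len(as.character(annotation), n)
  label <- rep_len(as.character(label), n)
  new("ProteinSet", sequences = sequences,
      annotation = annotation, label = label)
}

# ---------------------------------------------------------------------------
# CurationReport
# ---------------------------------------------------------------------------

#' CurationReport: outcome of the dataset curation filters
#'
#' Records how many input sequences each curation filter removed and which
#' sequences survived. Counts always conserve the input:
#' `inputCount == length(retained) + sum(removed)`.
#'
#' @slot inputCount Number of records before filtering.
#' @slot removed Named integer vector: records removed per filter, in the
#'   order the filters are applied.
#' @slot retained A [ProteinSet-class] of surviving records.
#' @seealso [curate()]
#' @export
setClass("CurationReport",
  representation(inputCount = "integer",
                 removed = "integer",
                 retained = "ProteinSet"))

setValidity("CurationReport", function(object) {
  if (object@inputCount != length(object@retained) + sum(object@removed))
    return("inputCount must equal retained + sum(removed)")
  TRUE
})

# ---------------------------------------------------------------------------
# SSEAssignment
# ---------------------------------------------------------------------------

#' SSEAssignment: three-state secondary structure of one sequence
#'
#' @slot states Single string over \{H, E, C\} (helix, sheet, coil), same
#'   length as the sequence it was computed from.
#' @slot content Named numeric of length 3 (`helix`, `sheet`, `coil`):
#'   state fractions, summing to 1.
#' @seealso [assignSSE()]
#' @export
setClass("SSEAssignment",
  representation(states = "character", content = "numeric"))

setValidity("SSEAssignment", function(object) {
  msg <- character()
  if (length(object@states) != 1L)
    msg <- c(msg, "states must be a single string")
  if (grepl("[^HEC]", object@states))
    msg <- c(msg, "states may only contain H, E, C")
  if (length(object@content) != 3L ||
      !identical(names(object@content), c("helix", "sheet", "coil")))
    msg <- c(msg, "content must be named (helix, sheet, coil)")
  else if (abs(sum(object@content) - 1) > 1e-9 ||
           any(object@content < -1e-12 | object@content > 1 + 1e-12))
    msg <- c(msg, "content fractions must lie in [0,1] and sum to 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GroupingScheme / PhyschemScales
# ---------------------------------------------------------------------------

#' GroupingScheme: coarse-grained amino-acid classes
#'
#' Holds the 10 functional groups, the 7 physico-chemical groups (both may
#' overlap and must jointly cover the alphabet) and the 5 disjoint
#' short-peptide residue classes used by the window classifier.
#'
#' @slot functionalGroups Named list of 10 character vectors of residues.
#' @slot physchemGroups Named list of 7 character vectors of residues.
#' @slot peptideClasses Named list of 5 character vectors forming a
#'   partition of the 20 amino acids, with names
#'   hydrophobic/hydrophilic/neutral/polar/nonpolar.
#' @seealso [defaultGroupingScheme()]
#' @export
setClass("GroupingScheme",
  representation(functionalGroups = "list",
                 physchemGroups = "list",
                 peptideClasses = "list"))

setValidity("GroupingScheme", function(object) {
  msg <- character()
  if (length(object@functionalGroups) != 10L)
    msg <- c(msg, "exactly 10 functional groups required")
  if (length(object@physchemGroups) != 7L)
    msg <- c(msg, "exactly 7 physico-chemical groups required")
  if (length(object@peptideClasses) != 5L)
    msg <- c(msg, "exactly 5 peptide classes required")
  cov1 <- unique(unlist(object@functionalGroups))
  cov2 <- unique(unlist(object@physchemGroups))
  if (!all(AA_ALPHABET20 %in% cov1))
    msg <- c(msg, "functional groups must cover the 20 standard amino acids")
  if (!all(AA_ALPHABET20 %in% cov2))
    msg <- c(msg, "physico-chemical groups must cover the 20 standard amino acids")
  pep <- unlist(object@peptideClasses)
  if (anyDuplicated(pep) || !setequal(pep, AA_ALPHABET20))
    msg <- c(msg, "peptide classes must partition the 20 standard amino acids")
  if (length(msg)) msg else TRUE
})

#' PhyschemScales: per-residue physicochemical property scales
#'
#' A 31 x 20 numeric matrix of AAindex-style scales: one row per named
#' property, one column per amino acid (alphabetical order), no missing
#' values.
#'
#' @slot values Numeric matrix, 31 rows (named scales) by 20 columns
#'   (amino acids in [AA_ALPHABET20] order).
#' @seealso [defaultPhyschemScales()], [readPhyschemScales()]
#' @export
setClass("PhyschemScales", representation(values = "matrix"))

setValidity("PhyschemScales", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != 31L) msg <- c(msg, "exactly 31 scales required")
  if (!identical(colnames(v), AA_ALPHABET20))
    msg <- c(msg, "columns must be the 20 amino acids in alphabetical order")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "scales must have unique names")
  if (anyNA(v)) msg <- c(msg, "scales must be defined for all residues")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RankedFeatureSet
# ---------------------------------------------------------------------------

#' RankedFeatureSet: information-gain feature ranking
#'
#' Per-feature information-gain scores (bits, non-negative) together with
#' the total order they induce (descending score, ties broken by ascending
#' feature index). Subsets taken with [topFeatures()] are nested by
#' construction.
#'
#' @slot scores Named numeric vector of information gain per feature.
#' @slot ranking Integer permutation of `seq_along(scores)` in descending
#'   score order.
#' @seealso [rankFeatures()], [topFeatures()]
#' @export
setClass("RankedFeatureSet",
  representation(scores = "numeric", ranking = "integer"))

setValidity("RankedFeatureSet", function(object) {
  msg <- character()
  if (any(object@scores < -1e-12))
    msg <- c(msg, "information gain scores must be non-negative")
  if (!identical(sort(object@ranking), seq_along(object@scores)))
    msg <- c(msg, "ranking must be a permutation of the feature indices")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# SVMConfig / MitoSVMModel
# ---------------------------------------------------------------------------

#' SVMConfig: RBF-SVM hyperparameters
#'
#' @slot C Positive penalty constant.
#' @slot gamma Positive RBF width parameter.
#' @slot classWeighting Either "none" or "balanced" (inverse class
#'   frequency weights).
#' @slot seed Integer seed controlling fold shuffling.
#' @seealso [svmConfig()], [gridSearch()], [trainSVM()]
#' @export
setClass("SVMConfig",
  representation(C = "numeric", gamma = "numeric",
                 classWeighting = "character", seed = "integer"))

setValidity("SVMConfig", function(object) {
  msg <- character()
  if (length(object@C) != 1L || !is.finite(object@C) || object@C <= 0)
    msg <- c(msg, "C must be a single positive number")
  if (length(object@gamma) != 1L || !is.finite(object@gamma) ||
      object@gamma <= 0)
    msg <- c(msg, "gamma must be a single positive number")
  if (!object@classWeighting %in% c("none", "balanced"))
    msg <- c(msg, "classWeighting must be 'none' or 'balanced'")
  if (length(msg)) msg else TRUE
})

#' Create an SVM configuration
#'
#' @param C Penalty constant (default 1).
#' @param gamma RBF width (default 1/239, the reciprocal of the feature
#'   count).
#' @param classWeighting "none" (default) or "balanced".
#' @param seed Integer seed (default 1).
#' @return An [SVMConfig-class].
#' @export
svmConfig <- function(C = 1, gamma = 1 / 239,
                      classWeighting = "none", seed = 1L) {
  # Class= must be named: a partially-matched `C` would be taken for it
  new(Class = "SVMConfig", C = as.numeric(C), gamma = as.numeric(gamma),
      classWeighting = classWeighting, seed = as.integer(seed))
}

#' MitoSVMModel: a trained multi-class RBF-SVM
#'
#' Wraps a fitted libsvm model (via e1071) together with everything needed
#' to apply it to new data: the selected feature index set, the per-feature
#' min/max training statistics used for [0,1] scaling, the hyperparameter
#' configuration and the class levels seen at training.
#'
#' @slot fit The fitted `e1071::svm` object (one-vs-one multi-class).
#' @slot featureIndex Integer indices (into the full feature layout) of the
#'   features the model uses.
#' @slot featureNames Names of those features.
#' @slot scaleMin,scaleMax Numeric vectors of training minima/maxima per
#'   used feature.
#' @slot config The [SVMConfig-class] used.
#' @slot levels Class labels seen at training.
#' @seealso [trainSVM()], [predict,MitoSVMModel-method],
#'   [decisionScores()]
#' @export
setClass("MitoSVMModel",
  representation(fit = "ANY", featureIndex = "integer",
                 featureNames = "character",
                 scaleMin = "numeric", scaleMax = "numeric",
                 config = "SVMConfig", levels = "character"))

# ---------------------------------------------------------------------------
# ConfusionCounts / MetricsReport
# ---------------------------------------------------------------------------

#' ConfusionCounts: multi-class confusion matrix
#'
#' A K x K matrix of counts with true classes in rows and predicted classes
#' in columns. One-vs-rest TP/FP/TN/FN per class are derived views (see
#' [ovrCounts()]).
#'
#' @slot counts Integer matrix with identical row/column dimnames.
#' @seealso [confusionCounts()], [ovrCounts()], [metricsReport()]
#' @export
setClass("ConfusionCounts", representation(counts = "matrix"))

setValidity("ConfusionCounts", function(object) {
  m <- object@counts
  msg <- character()
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "counts must be square with matching dimnames")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: per-class and overall performance metrics
#'
#' @slot perClass Data frame with one row per class: sensitivity,
#'   specificity, MCC and (when decision scores were supplied) AUC.
#'   Undefined metrics (zero denominators) are `NA`, never 0.
#' @slot overallAccuracy Overall accuracy, trace of the confusion matrix
#'   over its total.
#' @slot macro Named numeric of macro-averaged sensitivity, specificity,
#'   MCC and AUC (`NA`-aware means).
#' @seealso [metricsReport()]
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame",
                 overallAccuracy = "numeric",
                 macro = "numeric"))
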