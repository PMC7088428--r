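#' @include AllGenerics.R
NULL

#' @describeIn ProteinSet Number of sequences.
#' @param x A `ProteinSet`.
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @describeIn ProteinSet Sequence identifiers.
#' @export
setMethod("names", "ProteinSet", function(x) names(x@sequences))

#' @rdname sequences
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)

#' @rdname annotations
#' @export
setMethod("annotations", "ProteinSet", function(x) {
  stats::setNames(x@annotation, names(x@sequences))
})

#' @rdname classLabels
#' @export
setMethod("classLabels", "ProteinSet", function(x) {
  stats::setNames(x@label, names(x@sequences))
})

#' @rdname classLabels-set
#' @export
setMethod("classLabels<-", "ProteinSet", function(x, value) {
  x@label <- rep_len(as.character(value), length(x))
  validObject(x)
  x
})

#' @describeIn ProteinSet Subset by index, id or logical vector.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  if (is.logical(i)) i <- which(rep_len(i, length(x)))
  new("ProteinSet", sequences = x@sequences[i],
      annotation = x@annotation[i], label = x@label[i])
})

setMethod("show", "ProteinSet", function(object) {
  n <- length(object)
  cat("ProteinSet with", n, "sequence(s)\n")
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    cat("  length range: [", min(w), ", ", max(w), "]\n", sep = "")
    lab <- object@label[!is.na(object@label)]
    if (length(lab)) {
      tab <- table(factor(lab, levels = MITO_CLASSES))
      cat("  labelled:", length(lab), "of", n, "(",
          paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
    } else cat("  labelled: 0 of", n, "\n")
  }
})

#' @rdname retained
#' @export
setMethod("retained", "CurationReport", function(x) x@retained)

#' @rdname removedCounts
#' @export
setMethod("removedCounts", "CurationReport", function(x) x@removed)

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport:", object@inputCount, "input record(s),",
      length(object@retained), "retained\n")
  for (f in names(object@removed))
    cat(sprintf("  removed by %-22s %d\n", paste0(f, ":"),
                object@removed[[f]]))
})

#' Serialize a curation report to JSON
#'
#' @param x A [CurationReport-class].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
curationReportJSON <- function(x, path = NULL) {
  stopifnot(is(x, "CurationReport"))
  obj <- list(input_count = x@inputCount,
              removed_by_filter = as.list(x@removed),
              retained_ids = names(x@retained))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname sseStates
#' @export
setMethod("sseStates", "SSEAssignment", function(x) x@states)

#' @rdname sseContent
#' @export
setMethod("sseContent", "SSEAssignment", function(x) x@content)

setMethod("show", "SSEAssignment", function(object) {
  cat("SSEAssignment of length", nchar(object@states), "\n")
  cat(sprintf("  helix %.3f  sheet %.3f  coil %.3f\n",
      object@content[["helix"]], object@content[["sheet"]],
      object@content[["coil"]]))
})

setMethod("show", "GroupingScheme", function(object) {
  cat("GroupingScheme: 10 functional, 7 physico-chemical groups,",
      "5 peptide classes\n")
})

setMethod("show", "PhyschemScales", function(object) {
  cat("PhyschemScales:", nrow(object@values), "scales x 20 residues\n")
  cat("  ", paste(utils::head(rownames(object@values), 5), collapse = ", "),
      ", ...\n", sep = "")
})

setMethod("show", "SVMConfig", function(object) {
  cat(sprintf("SVMConfig: C = %g, gamma = %g, weighting = %s, seed = %d\n",
      object@C, object@gamma, object@classWeighting, object@seed))
})

setMethod("show", "MitoSVMModel", function(object) {
  cat("MitoSVMModel (RBF, one-vs-one) on", length(object@featureIndex),
      "features;", "classes:", paste(object@levels, collapse = ", "), "\n")
  show(object@config)
})
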