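#' @include ProteinSet-methods.R
NULL

#' Read protein sequences from FASTA, optionally attaching labels
#'
#' Reads a (wrapped or unwrapped) FASTA file into a [ProteinSet-class].
#' Class labels can be attached from a two-column TSV (`id<TAB>class`,
#' no header required, a header line `id\tclass` is tolerated) or from the
#' header convention `>id loc=<class>`; description text after the id
#' (minus any `loc=` token) is kept as the annotation field.
#'
#' @param path FASTA file path.
#' @param labels Optional path to a label TSV, or `"header"` to use the
#'   `loc=` header convention. Default `NULL`: no labels.
#' @return A [ProteinSet-class]; order of the FASTA file is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 loc=matrix", "MKLVAGHST", ">P2", "GGSTRWYPA"), fa)
#' readProteinSet(fa, labels = "header")
#' @export
readProteinSet <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !startsWith(first, ">"))
    stop("malformed FASTA (", path,
         "): line 1 does not start with '>'", call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  label <- rep(NA_character_, length(seqs))
  if (!is.null(labels)) {
    if (identical(labels, "header")) {
      has <- grepl("loc=\\S+", desc)
      label[has] <- sub("^loc=", "", regmatches(desc,
                        regexpr("loc=\\S+", desc)))
      desc <- trimws(sub("loc=\\S+", "", desc))
    } else {
      tab <- readLabelTable(labels)
      label <- unname(tab[ids])
    }
    bad <- !is.na(label) & !(label %in% MITO_CLASSES)
    if (any(bad))
      stop("unknown class label(s): ",
           paste(unique(label[bad]), collapse = ", "),
           "; expected one of ", paste(MITO_CLASSES, collapse = ", "),
           call. = FALSE)
  }
  names(seqs) <- ids
  new("ProteinSet", sequences = seqs, annotation = desc, label = label)
}

#' Read a two-column id/class label table
#'
#' @param path TSV path with columns id and class (header optional).
#' @return Named character vector mapping id to class.
#' @export
readLabelTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("label table must have two tab-separated columns", call. = FALSE)
  if (identical(tolower(tab[1, 1]), "id")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write a ProteinSet to FASTA (and optionally a label table)
#'
#' @param x A [ProteinSet-class].
#' @param path Output FASTA path.
#' @param labelPath Optional TSV path for the id/class table (labelled
#'   records only).
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path, labelPath = NULL) {
  stopifnot(is(x, "ProteinSet"))
  Biostrings::writeXStringSet(x@sequences, path, width = 60L)
  if (!is.null(labelPath)) {
    keep <- !is.na(x@label)
    utils::write.table(
      data.frame(id = names(x)[keep], class = x@label[keep]),
      labelPath, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Phrases whose co-occurrence marks a multi-location annotation.
.class_phrases <- list(
  inner_membrane = "inner membrane",
  intermembrane_space = "inter ?membrane space",
  matrix = "matrix",
  outer_membrane = "outer membrane")

#' @describeIn curate Apply the four in-scope curation filters, in order:
#'   (1) ambiguous annotation — the annotation contains any of the
#'   `annotationKeywords` as a case-insensitive substring; (2) multiple
#'   location — more than one distinct compartment phrase occurs in the
#'   annotation; (3) short sequence — length below `minLength`; (4)
#'   nonstandard residue — any residue outside `allowedAlphabet`. Each
#'   record is counted against the first filter it fails. Taxonomic
#'   restriction (eukaryotic, non-plant) is the caller's responsibility:
#'   FASTA records carry no taxonomy.
#' @param minLength Minimum retained sequence length (default 80).
#' @param annotationKeywords Ambiguity keywords triggering removal.
#' @param allowedAlphabet Permitted residues (default the 20 standard
#'   amino acids).
#' @export
setMethod("curate", "ProteinSet",
  function(x, minLength = 80L,
           annotationKeywords = c("possible", "probable",
                                  "by similarity", "potential"),
           allowedAlphabet = AA_ALPHABET20) {
  n <- length(x)
  removed <- stats::setNames(integer(4),
    c("ambiguous_annotation", "multi_location",
      "short_sequence", "nonstandard_residue"))
  keep <- logical(n)
  ann <- tolower(x@annotation)
  seqs <- as.character(x@sequences)
  pat <- paste0("[^", paste(allowedAlphabet, collapse = ""), "]")
  for (i in seq_len(n)) {
    if (any(vapply(tolower(annotationKeywords), grepl, logical(1),
                   x = ann[i], fixed = TRUE))) {
      removed[["ambiguous_annotation"]] <-
        removed[["ambiguous_annotation"]] + 1L
    } else if (sum(vapply(.class_phrases, grepl, logical(1),
                          x = ann[i])) > 1L) {
      removed[["multi_location"]] <- removed[["multi_location"]] + 1L
    } else if (nchar(seqs[i]) < minLength) {
      removed[["short_sequence"]] <- removed[["short_sequence"]] + 1L
    } else if (grepl(pat, seqs[i])) {
      removed[["nonstandard_residue"]] <-
        removed[["nonstandard_residue"]] + 1L
    } else keep[i] <- TRUE
  }
  new("CurationReport", inputCount = n, removed = removed,
      retained = x[keep])
})

# Global alignment identity between two sequences: matches over alignment
# columns, under match = 1, mismatch = 0, linear gap penalty 1.
.sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      mm <- diag(1, 20)
      dimnames(mm) <- list(AA_ALPHABET20, AA_ALPHABET20)
      m <<- mm
    }
    m
  }
})

alignmentIdentity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = .sub_matrix(),
    gapOpening = 0, gapExtension = 1, type = "global")
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

#' @describeIn reduceRedundancy Greedy longest-first identity clustering in
#'   the style of CD-HIT: sequences are visited in decreasing length (ties
#'   broken by id), each joins the first already-retained representative
#'   with which its global-alignment identity (matches / alignment columns,
#'   match 1 / mismatch 0 / linear gap -1) exceeds `identityThreshold`,
#'   otherwise it founds a new cluster. Representatives are returned in the
#'   order they were created.
#' @param identityThreshold Pairwise identity above which a sequence is
#'   absorbed (default 0.70). Must lie in (0, 1].
#' @export
setMethod("reduceRedundancy", "ProteinSet",
  function(x, identityThreshold = 0.70) {
  if (!is.numeric(identityThreshold) || length(identityThreshold) != 1L ||
      identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must lie in (0, 1]", call. = FALSE)
  if (length(x) <= 1L) return(x)
  w <- Biostrings::width(x@sequences)
  ord <- order(-w, names(x))
  seqs <- as.character(x@sequences)[ord]
  reps <- integer(0)                   # indices into ord-sorted view
  for (i in seq_along(ord)) {
    absorbed <- FALSE
    for (r in reps) {
      if (alignmentIdentity(seqs[i], seqs[r]) > identityThreshold) {
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) reps <- c(reps, i)
  }
  x[ord[reps]]
})
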