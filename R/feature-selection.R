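#' @include AllGenerics.R
NULL

.entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of a feature column about the class label
#'
#' Discretizes a numeric feature into `bins` equal-width bins over its
#' observed range (a constant column collapses to a single bin) and
#' returns the mutual information H(Y) - H(Y|X) between the binned feature
#' and the labels, in bits. Non-negative by construction (small negative
#' rounding residue is clipped).
#'
#' @param x Numeric vector over n >= 2 samples.
#' @param labels Class label per sample; at least two distinct classes.
#' @param bins Number of equal-width bins (default 10).
#' @return Information gain in bits.
#' @examples
#' informationGain(c(0, 0, 1, 1), c("a", "a", "b", "b"))  # 1 bit
#' @export
informationGain <- function(x, labels, bins = 10L) {
  stopifnot(is.numeric(x), length(x) == length(labels))
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("information gain needs at least two classes", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, length(x))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  hy <- .entropy_bits(table(labels))
  n <- length(x)
  hyx <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    hyx <- hyx + sum(sel) / n * .entropy_bits(table(labels[sel]))
  }
  max(0, hy - hyx)
}

#' Rank features by information gain
#'
#' Computes [informationGain()] column-wise and orders features by
#' descending score, ties broken by ascending column index; deterministic.
#'
#' @param mat Numeric feature matrix (samples x features).
#' @param labels Class label per row.
#' @param bins Discretization bins (default 10).
#' @return A [RankedFeatureSet-class].
#' @seealso [topFeatures()]
#' @export
rankFeatures <- function(mat, labels, bins = 10L) {
  stopifnot(is.matrix(mat), nrow(mat) == length(labels))
  scores <- apply(mat, 2, informationGain, labels = labels, bins = bins)
  if (is.null(names(scores)))
    names(scores) <- paste0("f", seq_along(scores))
  ranking <- order(-scores, seq_along(scores))
  new("RankedFeatureSet", scores = scores, ranking = as.integer(ranking))
}

#' @rdname igScores
#' @export
setMethod("igScores", "RankedFeatureSet", function(x) x@scores)

#' @rdname topFeatures
#' @export
setMethod("topFeatures", "RankedFeatureSet", function(x, k) {
  if (identical(k, "all") || is.infinite(k)) k <- length(x@scores)
  k <- as.integer(k)
  if (k < 1L || k > length(x@scores))
    stop("k must lie in [1, ", length(x@scores), "]", call. = FALSE)
  x@ranking[seq_len(k)]
})

setMethod("show", "RankedFeatureSet", function(object) {
  cat("RankedFeatureSet over", length(object@scores), "features\n")
  top <- object@ranking[seq_len(min(5L, length(object@ranking)))]
  cat("  top:", paste(sprintf("%s (%.3f)", names(object@scores)[top],
                              object@scores[top]), collapse = ", "), "\n")
})

#' Write a feature ranking to TSV
#'
#' @param x A [RankedFeatureSet-class].
#' @param path Output TSV path (columns feature, ig_bits, rank).
#' @return `path`, invisibly.
#' @export
writeRanking <- function(x, path) {
  stopifnot(is(x, "RankedFeatureSet"))
  ord <- x@ranking
  utils::write.table(
    data.frame(feature = names(x@scores)[ord],
               ig_bits = x@scores[ord],
               rank = seq_along(ord)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
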