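#' @include secondary-structure.R
NULL

# Block sizes of the 239-feature layout.
.block_sizes <- c(ccd = 60L, saac = 60L, fg_sse = 88L, physchem = 31L)

#' Feature layout of the 239-dimensional encoding
#'
#' @return Named integer vector of block sizes:
#'   `c(ccd = 60, saac = 60, fg_sse = 88, physchem = 31)`.
#' @export
featureLayout <- function() .block_sizes

#' Composition, centroid and distribution features (60)
#'
#' For each amino acid `a` in alphabetical order: composition
#' `n_a / L`; centroid, the mean 1-based position of `a` divided by `L`
#' (0 if absent); distribution, the population standard deviation of the
#' normalized positions of `a` (0 if `a` occurs at most once). Output
#' order: 20 compositions, 20 centroids, 20 distributions.
#'
#' @param sequence Standard-alphabet amino-acid string, length >= 1.
#' @return Named numeric vector of length 60.
#' @examples
#' encodeCCD("GAG")[["ccd.centroid.A"]]  # 2/3
#' @export
encodeCCD <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("empty sequence", call. = FALSE)
  assert_standard(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  comp <- centroid <- disp <- stats::setNames(numeric(20), AA_ALPHABET20)
  pos <- split(seq_len(L), factor(chars, levels = AA_ALPHABET20))
  for (a in AA_ALPHABET20) {
    p <- pos[[a]]
    if (length(p)) {
      comp[a] <- length(p) / L
      centroid[a] <- mean(p) / L
      if (length(p) > 1L) {
        z <- p / L
        disp[a] <- sqrt(mean((z - mean(z))^2))
      }
    }
  }
  c(stats::setNames(comp, paste0("ccd.comp.", AA_ALPHABET20)),
    stats::setNames(centroid, paste0("ccd.centroid.", AA_ALPHABET20)),
    stats::setNames(disp, paste0("ccd.dist.", AA_ALPHABET20)))
}

#' Split amino-acid composition features (60)
#'
#' The sequence is split into an N-terminal, middle and C-terminal part at
#' indices `floor(L/3)` and `floor(2L/3)`; the 20 amino-acid compositions
#' of each part are concatenated N to C.
#'
#' @param sequence Standard-alphabet amino-acid string, length >= 3.
#' @return Named numeric vector of length 60; each part's 20 values sum
#'   to 1.
#' @export
encodeSAAC <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (L < 3L) stop("sequence must have length >= 3", call. = FALSE)
  assert_standard(sequence)
  chars <- strsplit(sequence, "")[[1]]
  cut1 <- L %/% 3L
  cut2 <- (2L * L) %/% 3L
  parts <- list(chars[seq_len(cut1)],
                chars[(cut1 + 1L):cut2],
                chars[(cut2 + 1L):L])
  out <- unlist(lapply(seq_along(parts), function(k) {
    cmp <- table(factor(parts[[k]], levels = AA_ALPHABET20)) /
      length(parts[[k]])
    stats::setNames(as.numeric(cmp),
                    paste0("saac.p", k, ".", AA_ALPHABET20))
  }))
  out
}

# Fraction of `chars` belonging to each residue group in `groups`.
.group_freqs <- function(chars, groups) {
  if (!length(chars))
    return(stats::setNames(numeric(length(groups)), names(groups)))
  vapply(groups, function(g) mean(chars %in% g), numeric(1))
}

# Classify each length-w window by strict-majority peptide class; returns
# a factor with NA for windows without a majority class. Classes are a
# partition, so at most one class can exceed w/2.
.window_classes <- function(chars, classes, w) {
  n <- length(chars) - w + 1L
  memb <- vapply(classes, function(g) as.numeric(chars %in% g),
                 numeric(length(chars)))
  counts <- apply(memb, 2, function(col)
    cumsum(col)[w:length(col)] - c(0, cumsum(col))[seq_len(n)])
  if (n == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, names(classes)))
  hit <- counts > w / 2
  cls <- rep(NA_character_, n)
  has <- rowSums(hit) == 1L
  cls[has] <- names(classes)[apply(hit[has, , drop = FALSE], 1,
                                   which)]
  cls
}

#' Functional-group, short-peptide and secondary-structure features (88)
#'
#' Concatenates five sub-blocks: (a) 17 whole-sequence group frequencies
#' (10 functional + 7 physico-chemical groups; member residues / L); (b) 5
#' short-peptide class frequencies — a sliding window of `peptideWindow`
#' residues is assigned to the peptide class holding a strict majority
#' (> w/2) of its residues, classless windows count toward nothing; (c) 3
#' helix/sheet/coil content fractions; (d) 51 per-state group frequencies
#' (17 groups x 3 states; group residues in a state / residues in that
#' state, 0 when a state is absent); (e) 12 per-state short-peptide
#' frequencies (hydrophobic, hydrophilic, polar, non-polar x 3 states), a
#' window belonging to the state of its central residue.
#'
#' @param sequence Standard-alphabet string, length >= `peptideWindow`.
#' @param sse An [SSEAssignment-class] for the same sequence.
#' @param scheme A [GroupingScheme-class].
#' @param peptideWindow Sliding-window length (default 10).
#' @return Named numeric vector of length 88, all values in [0, 1].
#' @export
encodeFgSse <- function(sequence, sse = assignSSE(sequence),
                        scheme = defaultGroupingScheme(),
                        peptideWindow = 10L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is(sse, "SSEAssignment"), is(scheme, "GroupingScheme"))
  L <- nchar(sequence)
  if (L < peptideWindow)
    stop("sequence shorter than the peptide window (", peptideWindow,
         ")", call. = FALSE)
  if (nchar(sse@states) != L)
    stop("secondary-structure string length does not match the sequence",
         call. = FALSE)
  assert_standard(sequence)
  chars <- strsplit(sequence, "")[[1]]
  states <- strsplit(sse@states, "")[[1]]
  groups17 <- c(scheme@functionalGroups, scheme@physchemGroups)
  gnames <- c(paste0("fg.func.", names(scheme@functionalGroups)),
              paste0("fg.phys.", names(scheme@physchemGroups)))

  # (a) global group frequencies
  a <- stats::setNames(.group_freqs(chars, groups17), gnames)

  # (b) short-peptide class frequencies
  cls <- .window_classes(chars, scheme@peptideClasses, peptideWindow)
  b <- vapply(names(scheme@peptideClasses),
              function(k) mean(cls %in% k), numeric(1))
  names(b) <- paste0("pep.", names(scheme@peptideClasses))

  # (c) SSE content
  cc <- stats::setNames(sse@content,
                        paste0("sse.", names(sse@content)))

  # (d) per-state group frequencies
  d <- numeric(0)
  for (s in c("H", "E", "C")) {
    in_state <- chars[states == s]
    d <- c(d, stats::setNames(.group_freqs(in_state, groups17),
                              paste0("sse.", s, ".", gnames)))
  }

  # (e) per-state short-peptide frequencies (neutral class excluded)
  pepcl <- setdiff(names(scheme@peptideClasses), "neutral")
  centre <- seq_along(cls) + ceiling(peptideWindow / 2) - 1L
  cstate <- states[centre]
  e <- numeric(0)
  for (s in c("H", "E", "C")) {
    sel <- cstate == s
    if (any(sel)) {
      f <- vapply(pepcl, function(k) mean(cls[sel] %in% k), numeric(1))
    } else f <- stats::setNames(numeric(length(pepcl)), pepcl)
    e <- c(e, stats::setNames(f, paste0("sse.", s, ".pep.", pepcl)))
  }
  c(a, b, cc, d, e)
}

#' Mean physicochemical property features (31)
#'
#' Each feature is the mean over the sequence of one per-residue
#' physicochemical scale.
#'
#' @param sequence Standard-alphabet string, length >= 1.
#' @param scales A [PhyschemScales-class].
#' @return Named numeric vector of length 31.
#' @export
encodePhyschem <- function(sequence, scales = defaultPhyschemScales()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is(scales, "PhyschemScales"))
  if (nchar(sequence) < 1L) stop("empty sequence", call. = FALSE)
  assert_standard(sequence)
  chars <- strsplit(sequence, "")[[1]]
  out <- rowMeans(scales@values[, chars, drop = FALSE])
  stats::setNames(out, paste0("physchem.", rownames(scales@values)))
}

#' Encode one sequence as the full 239-feature vector
#'
#' Concatenates the four blocks ccd (60), saac (60), fg_sse (88) and
#' physchem (31); see the individual encoders for definitions. Encoding is
#' a pure function of the sequence and the supplied resources.
#'
#' @param sequence Standard-alphabet string with
#'   `nchar >= max(peptideWindow, 3)`.
#' @param scheme A [GroupingScheme-class].
#' @param scales A [PhyschemScales-class].
#' @param window SSE smoothing window (default 5).
#' @param peptideWindow Short-peptide window (default 10).
#' @param sse Optional pre-computed [SSEAssignment-class] (e.g. imported
#'   from an external predictor); default Chou-Fasman assignment.
#' @return Named numeric vector of length 239.
#' @export
encodeSequence <- function(sequence,
                           scheme = defaultGroupingScheme(),
                           scales = defaultPhyschemScales(),
                           window = 5L, peptideWindow = 10L,
                           sse = NULL) {
  if (is.null(sse)) sse <- assignSSE(sequence, window = window)
  c(encodeCCD(sequence),
    encodeSAAC(sequence),
    encodeFgSse(sequence, sse = sse, scheme = scheme,
                peptideWindow = peptideWindow),
    encodePhyschem(sequence, scales = scales))
}

#' @describeIn encodeFeatures Encode every sequence of a ProteinSet; rows
#'   are sequences (named by id), columns the 239 named features.
#' @param scheme,scales,window,peptideWindow See [encodeSequence()].
#' @export
setMethod("encodeFeatures", "ProteinSet",
  function(x, scheme = defaultGroupingScheme(),
           scales = defaultPhyschemScales(),
           window = 5L, peptideWindow = 10L) {
  seqs <- as.character(x@sequences)
  out <- t(vapply(seqs, encodeSequence, numeric(sum(.block_sizes)),
                  scheme = scheme, scales = scales, window = window,
                  peptideWindow = peptideWindow))
  rownames(out) <- names(x)
  out
})

#' @describeIn encodeFeatures Encode a character vector of sequences.
#' @export
setMethod("encodeFeatures", "character",
  function(x, scheme = defaultGroupingScheme(),
           scales = defaultPhyschemScales(),
           window = 5L, peptideWindow = 10L) {
  ids <- if (is.null(names(x))) paste0("seq", seq_along(x)) else names(x)
  encodeFeatures(ProteinSet(x, ids = ids), scheme = scheme,
                 scales = scales, window = window,
                 peptideWindow = peptideWindow)
})

#' Write a feature matrix as headered CSV
#'
#' @param mat Feature matrix from [encodeFeatures()].
#' @param path Output CSV path.
#' @param labels Optional class labels, written as a final `class` column.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(mat, path, labels = NULL) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  if (!is.null(labels)) df$class <- labels
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a feature matrix in libsvm sparse format
#'
#' @param mat Feature matrix.
#' @param labels Class labels; encoded as the integer index into
#'   `levels`.
#' @param path Output path.
#' @param levels Label levels (default [MITO_CLASSES]).
#' @return `path`, invisibly.
#' @export
writeLibsvm <- function(mat, labels, path, levels = MITO_CLASSES) {
  y <- as.integer(factor(labels, levels = levels))
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    nz <- which(v != 0)
    paste(y[i], paste0(nz, ":", format(v[nz], digits = 10,
                                       scientific = FALSE, trim = TRUE),
                       collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
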