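#' @include ProteinSet-methods.R
NULL

# Five signature residues per compartment (disjoint across classes); the
# boost applied to these rows of the emission profile carries the class
# signal.
.class_signatures <- list(
  inner_membrane = c("F", "I", "L", "V", "W"),
  intermembrane_space = c("C", "G", "H", "S", "T"),
  matrix = c("D", "E", "K", "N", "Q"),
  outer_membrane = c("A", "M", "P", "R", "Y"))

#' Class-dependent residue emission profiles
#'
#' Builds one 20-simplex per compartment: a uniform base in which the
#' class's five signature residues are up-weighted by a factor
#' `1 + effectSize` before renormalization. `effectSize = 0` gives the
#' uniform profile for every class (a permutation null); the default 4
#' boosts signature residues five-fold, a strong compositional effect.
#'
#' @param effectSize Non-negative profile divergence from uniform.
#' @return Numeric matrix, 4 classes x 20 residues, rows summing to 1.
#' @export
classProfiles <- function(effectSize = 4) {
  if (!is.numeric(effectSize) || effectSize < 0)
    stop("effectSize must be >= 0", call. = FALSE)
  prof <- matrix(1, length(MITO_CLASSES), 20,
                 dimnames = list(MITO_CLASSES, AA_ALPHABET20))
  for (cl in MITO_CLASSES)
    prof[cl, .class_signatures[[cl]]] <- 1 + effectSize
  prof / rowSums(prof)
}

#' Generate a labelled synthetic protein dataset
#'
#' Emits i.i.d. residues from per-class emission profiles, with sequence
#' lengths uniform over `lengthRange`. With `blockStructure = TRUE` only
#' the N-terminal third of each sequence is emitted from the class
#' profile and the remainder from the uniform profile, concentrating the
#' signal where split-composition and centroid features can see it.
#' Deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param nPerClass Integer count of sequences per compartment, recycled
#'   to length 4 (default 100 each).
#' @param lengthRange Integer (min, max) sequence length, min >= 10
#'   (default c(80, 200)).
#' @param effectSize Profile divergence passed to [classProfiles()]
#'   (default 4); ignored when `profiles` is given.
#' @param seed Integer seed (default 1).
#' @param profiles Optional 4 x 20 matrix of emission probabilities (rows
#'   = [MITO_CLASSES], columns = [AA_ALPHABET20], each row a simplex).
#' @param blockStructure Emit the class signal only in the N-terminal
#'   third (default FALSE).
#' @return List with `proteins` (a labelled [ProteinSet-class]) and
#'   `profiles` (the emission matrix used).
#' @examples
#' sim <- generateProteins(nPerClass = 5, seed = 7)
#' sim$proteins
#' @export
generateProteins <- function(nPerClass = 100L,
                             lengthRange = c(80L, 200L),
                             effectSize = 4, seed = 1L,
                             profiles = NULL,
                             blockStructure = FALSE) {
  nPerClass <- rep_len(as.integer(nPerClass), length(MITO_CLASSES))
  if (lengthRange[1] < 10L || lengthRange[2] < lengthRange[1])
    stop("lengthRange must satisfy 10 <= min <= max", call. = FALSE)
  if (is.null(profiles)) profiles <- classProfiles(effectSize)
  if (!identical(dim(profiles), c(4L, 20L)) ||
      any(profiles < 0) || any(abs(rowSums(profiles) - 1) > 1e-9))
    stop("profiles must be a 4 x 20 matrix of probability rows",
         call. = FALSE)
  uniform <- rep(1 / 20, 20)
  seqs <- character(0)
  ids <- character(0)
  labs <- character(0)
  with_local_seed(seed, {
    for (k in seq_along(MITO_CLASSES)) {
      cl <- MITO_CLASSES[k]
      for (i in seq_len(nPerClass[k])) {
        L <- sample(lengthRange[1]:lengthRange[2], 1L)
        if (blockStructure) {
          nblock <- L %/% 3L
          res <- c(sample(AA_ALPHABET20, nblock, replace = TRUE,
                          prob = profiles[k, ]),
                   sample(AA_ALPHABET20, L - nblock, replace = TRUE,
                          prob = uniform))
        } else {
          res <- sample(AA_ALPHABET20, L, replace = TRUE,
                        prob = profiles[k, ])
        }
        seqs <- c(seqs, paste(res, collapse = ""))
        ids <- c(ids, sprintf("%s_%04d", cl, i))
        labs <- c(labs, cl)
      }
    }
  })
  list(proteins = ProteinSet(seqs, ids = ids, label = labs),
       profiles = profiles)
}
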