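test_that("FASTA parsing preserves order, ids, and labels", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1 some matrix protein", "MKLVAGHST",
               ">P2", "GGSTRWYPAMKL"), fa)
  ps <- readProteinSet(fa)
  expect_equal(length(ps), 2L)
  expect_equal(names(ps), c("P1", "P2"))
  expect_equal(as.character(sequences(ps)),
               c(P1 = "MKLVAGHST", P2 = "GGSTRWYPAMKL"))
  expect_true(all(is.na(classLabels(ps))))
  expect_equal(unname(annotations(ps)[1]), "some matrix protein")

  # header convention
  fa2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1 loc=matrix", "MKLVA", ">P2 loc=outer_membrane x",
               "GGSTR"), fa2)
  ps2 <- readProteinSet(fa2, labels = "header")
  expect_equal(unname(classLabels(ps2)),
               c("matrix", "outer_membrane"))

  # label table
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P2\tinner_membrane"), tsv)
  ps3 <- readProteinSet(fa, labels = tsv)
  expect_equal(unname(classLabels(ps3)), c(NA, "inner_membrane"))
})

test_that("FASTA parsing rejects malformed input, duplicates and bad labels", {
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("MKLVA", ">P1"), bad)
  expect_error(readProteinSet(bad), "line 1")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1", "MKLVA", ">P1", "GGSTR"), dup)
  expect_error(readProteinSet(dup), "duplicate.*P1")

  lab <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">P1 loc=cytoplasm", "MKLVA"), lab)
  expect_error(readProteinSet(lab, labels = "header"), "cytoplasm")
})

test_that("FASTA round-trips through write and read", {
  ps <- ProteinSet(c(A1 = "MKLVAGHST", B2 = "WWYPAMKLGG"),
                   label = c("matrix", NA))
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeProteinFasta(ps, fa, labelPath = tsv)
  back <- readProteinSet(fa, labels = tsv)
  expect_equal(as.character(sequences(back)), as.character(sequences(ps)))
  expect_equal(unname(classLabels(back)), c("matrix", NA))
})

test_that("curation filters fire in order and on the stated boundaries", {
  ps <- ProteinSet(
    c(short = strrep("M", 79),                    # length filter
      ambig = strrep("M", 90),                    # keyword filter
      multi = strrep("M", 90),                    # multi-location filter
      nonstd = paste0(strrep("M", 85), "XKL"),    # alphabet filter
      clean80 = strrep("MK", 40),                 # boundary: retained
      both = strrep("X", 10)),                    # fails several: 1st wins
    annotation = c("matrix", "Probable matrix protein",
                   "matrix; also inner membrane", "matrix", "matrix",
                   "Potential matrix"))
  rep <- curate(ps)
  expect_s4_class(rep, "CurationReport")
  expect_equal(names(retained(rep)), "clean80")
  rm <- removedCounts(rep)
  expect_equal(unname(rm["short_sequence"]), 1L)
  expect_equal(unname(rm["ambiguous_annotation"]), 2L)  # ambig + both
  expect_equal(unname(rm["multi_location"]), 1L)
  expect_equal(unname(rm["nonstandard_residue"]), 1L)
  # count conservation
  expect_equal(rep@inputCount, length(retained(rep)) + sum(rm))
})

test_that("curation is idempotent and its report serializes", {
  set.seed(42)
  seqs <- vapply(1:8, function(i) random_sequence(80 + i), character(1))
  names(seqs) <- paste0("S", 1:8)
  ps <- ProteinSet(seqs, annotation = "matrix")
  r1 <- curate(ps)
  r2 <- curate(retained(r1))
  expect_equal(length(retained(r2)), length(retained(r1)))
  expect_equal(sum(removedCounts(r2)), 0L)
  js <- jsonlite::fromJSON(curationReportJSON(r1))
  expect_equal(js$input_count, 8L)
})

test_that("redundancy reduction keeps the expected representatives", {
  # identical pair collapses; dissimilar pair survives
  ps <- ProteinSet(c(a = strrep("ACDEF", 20), b = strrep("ACDEF", 20),
                     c = strrep("WYK", 30)))
  expect_equal(sort(names(reduceRedundancy(ps))), c("a", "c"))

  # B ~90% identical to A joins A's cluster; C ~20% identical stays
  base <- strsplit(strrep("ACDEFGHIKL", 5), "")[[1]]
  bmut <- base
  bmut[c(3, 13, 23, 33, 43)] <- c("W", "W", "W", "W", "W")
  cseq <- strrep("WY", 25)
  ps2 <- ProteinSet(c(A = paste(base, collapse = ""),
                      B = paste(bmut, collapse = ""),
                      C = cseq))
  expect_gt(nw_identity_oracle(paste(base, collapse = ""),
                               paste(bmut, collapse = "")), 0.7)
  expect_lt(nw_identity_oracle(paste(base, collapse = ""), cseq), 0.7)
  expect_equal(sort(names(reduceRedundancy(ps2))), c("A", "C"))

  expect_error(reduceRedundancy(ps, identityThreshold = 1.5), "0, 1")
  expect_error(reduceRedundancy(ps, identityThreshold = 0), "0, 1")
})

test_that("no retained pair exceeds the identity threshold (alignment oracle)", {
  set.seed(7)
  n <- 14
  seqs <- character(n)
  # mixture: some mutated copies of shared templates, some random
  t1 <- random_sequence(60)
  t2 <- random_sequence(45)
  for (i in seq_len(n)) {
    if (i <= 5) {
      ch <- strsplit(t1, "")[[1]]
      k <- sample(60, i)  # i mutations
      ch[k] <- sample(AA_ALPHABET20, length(k), replace = TRUE)
      seqs[i] <- paste(ch, collapse = "")
    } else if (i <= 9) {
      ch <- strsplit(t2, "")[[1]]
      k <- sample(45, 2 * i)
      ch[k] <- sample(AA_ALPHABET20, length(k), replace = TRUE)
      seqs[i] <- paste(ch, collapse = "")
    } else {
      seqs[i] <- random_sequence(sample(40:70, 1))
    }
  }
  names(seqs) <- sprintf("s%02d", seq_len(n))
  reps <- reduceRedundancy(ProteinSet(seqs), identityThreshold = 0.70)
  kept <- as.character(sequences(reps))
  if (length(kept) > 1) {
    pairs <- utils::combn(length(kept), 2)
    ids <- apply(pairs, 2, function(p)
      nw_identity_oracle(kept[p[1]], kept[p[2]]))
    expect_true(all(ids <= 0.70 + 1e-9))
  }
  expect_lt(length(reps), n)  # the mutated copies did collapse
})
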