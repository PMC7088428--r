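toy_scales <- function(value_A = 0, value_other = 1) {
  v <- matrix(value_other, 31, 20,
              dimnames = list(paste0("toy", 1:31), AA_ALPHABET20))
  v[, "A"] <- value_A
  new("PhyschemScales", values = v)
}

test_that("composition/centroid/distribution features match position statistics", {
  v <- encodeCCD("AAAA")
  expect_equal(unname(v["ccd.comp.A"]), 1)
  expect_equal(sum(v[paste0("ccd.comp.", setdiff(AA_ALPHABET20, "A"))]), 0)
  expect_equal(unname(v["ccd.centroid.A"]), mean(1:4) / 4)  # 0.625

  v2 <- encodeCCD("GAG")
  expect_equal(unname(v2["ccd.centroid.A"]), 2 / 3)
  expect_equal(unname(v2["ccd.dist.A"]), 0)  # single occurrence

  # brute-force position statistics oracle on ACACAC
  v3 <- encodeCCD("ACACAC")
  expect_equal(unname(v3["ccd.comp.A"]), 0.5)
  expect_equal(unname(v3["ccd.comp.C"]), 0.5)
  posA <- c(1, 3, 5) / 6
  expect_equal(unname(v3["ccd.centroid.A"]), mean(c(1, 3, 5)) / 6)
  expect_equal(unname(v3["ccd.dist.A"]),
               sqrt(mean((posA - mean(posA))^2)))

  expect_error(encodeCCD(""), "empty|length")
})

test_that("split amino-acid composition follows the floor-based split", {
  v <- encodeSAAC("AAACCCGGG")
  expect_equal(unname(v["saac.p1.A"]), 1)
  expect_equal(unname(v["saac.p2.C"]), 1)
  expect_equal(unname(v["saac.p3.G"]), 1)

  # L = 10 -> parts of sizes 3, 3, 4
  v10 <- encodeSAAC("AAAACCCCGG")  # parts AAA | ACC | CCGG
  expect_equal(unname(v10["saac.p1.A"]), 1)
  expect_equal(unname(v10["saac.p2.A"]), 1 / 3)
  expect_equal(unname(v10["saac.p2.C"]), 2 / 3)
  expect_equal(unname(v10["saac.p3.C"]), 2 / 4)
  expect_equal(unname(v10["saac.p3.G"]), 2 / 4)

  # each part's 20 values sum to 1 on a random 60-mer
  set.seed(9)
  vr <- encodeSAAC(random_sequence(60))
  for (p in 1:3)
    expect_equal(sum(vr[paste0("saac.p", p, ".", AA_ALPHABET20)]), 1)

  expect_error(encodeSAAC("AC"), ">= 3")
})

test_that("functional-group / peptide / SSE block has the stated structure", {
  scheme <- defaultGroupingScheme()

  # all-Leu sequence: one uniform window -> hydrophobic frequency 1
  v <- encodeFgSse(strrep("L", 10), scheme = scheme)
  expect_equal(length(v), 88L)
  expect_equal(unname(v["pep.hydrophobic"]), 1)
  expect_equal(unname(v[c("pep.hydrophilic", "pep.neutral",
                          "pep.polar", "pep.nonpolar")]),
               c(0, 0, 0, 0))

  # all-coil assignment zeroes every helix/sheet per-state feature
  s <- random_sequence(30, seed = 4)
  sse_c <- new("SSEAssignment", states = strrep("C", 30),
               content = c(helix = 0, sheet = 0, coil = 1))
  vc <- encodeFgSse(s, sse = sse_c, scheme = scheme)
  he <- grep("^sse\\.(H|E)\\.", names(vc), value = TRUE)
  expect_equal(length(he), 42L)  # (17 groups + 4 classes) x 2 states
  expect_true(all(vc[he] == 0))

  # hand-count oracle for the 17 global group frequencies
  chars <- strsplit(s, "")[[1]]
  groups <- c(scheme@functionalGroups, scheme@physchemGroups)
  hand <- vapply(groups, function(g) sum(chars %in% g) / 30, numeric(1))
  expect_equal(unname(vc[1:17]), unname(hand))

  # windows without a strict majority count toward no class
  alt <- strrep("LD", 10)  # 5 hydrophobic + 5 hydrophilic per window
  va <- encodeFgSse(alt, scheme = scheme)
  expect_true(all(va[paste0("pep.", names(scheme@peptideClasses))] == 0))

  expect_error(encodeFgSse("LLLL"), "peptide window")
  expect_error(encodeFgSse(strrep("L", 12), sse = sse_c), "length")
})

test_that("physicochemical features are per-scale means", {
  sc <- toy_scales()
  expect_equal(unname(encodePhyschem("A", sc)), rep(0, 31))
  expect_equal(unname(encodePhyschem("AC", sc)), rep(0.5, 31))

  set.seed(11)
  s <- random_sequence(40)
  chars <- strsplit(s, "")[[1]]
  real <- defaultPhyschemScales()
  v <- encodePhyschem(s, real)
  brute <- apply(real@values, 1, function(row) mean(row[chars]))
  expect_equal(unname(v), unname(brute), tolerance = 1e-12)
})

test_that("full encoding is 239-long, block-consistent and pure", {
  scheme <- defaultGroupingScheme()
  scales <- defaultPhyschemScales()
  set.seed(13)
  s <- random_sequence(100)
  v <- encodeSequence(s, scheme = scheme, scales = scales)
  expect_equal(length(v), 239L)
  expect_equal(unname(featureLayout()), c(60L, 60L, 88L, 31L))
  expect_equal(sum(startsWith(names(v), "ccd.")), 60L)
  expect_equal(sum(startsWith(names(v), "saac.")), 60L)
  expect_equal(sum(startsWith(names(v), "physchem.")), 31L)

  # block slices equal the individually computed sub-encodings
  expect_equal(v[1:60], encodeCCD(s))
  expect_equal(v[61:120], encodeSAAC(s))
  expect_equal(v[121:208], encodeFgSse(s, scheme = scheme))
  expect_equal(v[209:239], encodePhyschem(s, scales))

  # determinism
  expect_identical(v, encodeSequence(s, scheme = scheme,
                                     scales = scales))

  # frequency-type features lie in [0,1]; compositions sum to 1
  freq <- v[!startsWith(names(v), "physchem.") &
            !startsWith(names(v), "ccd.dist.")]
  expect_true(all(freq >= 0 & freq <= 1 + 1e-12))
  expect_equal(sum(v[paste0("ccd.comp.", AA_ALPHABET20)]), 1)

  # residue permutation leaves whole-sequence compositions unchanged
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  vp <- encodeSequence(perm, scheme = scheme, scales = scales)
  expect_equal(vp[paste0("ccd.comp.", AA_ALPHABET20)],
               v[paste0("ccd.comp.", AA_ALPHABET20)])
  expect_equal(vp[1:17 + 120], v[1:17 + 120])  # global group block
})

test_that("ProteinSet encoding yields one named row per sequence", {
  sim <- generateProteins(nPerClass = 3, lengthRange = c(60, 90),
                          seed = 21)
  m <- encodeFeatures(sim$proteins)
  expect_equal(dim(m), c(12L, 239L))
  expect_equal(rownames(m), names(sim$proteins))
  # matrix writers round-trip shape
  csv <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(m, csv, labels = unname(classLabels(sim$proteins)))
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(dim(back), c(12L, 241L))  # id + 239 + class
  lsv <- withr::local_tempfile(fileext = ".libsvm")
  writeLibsvm(m, unname(classLabels(sim$proteins)), lsv)
  expect_equal(length(readLines(lsv)), 12L)
})
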