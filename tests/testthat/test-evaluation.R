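test_that("closed-form metrics follow their defining ratios", {
  expect_equal(sensitivity(90, 10), 0.9)
  expect_equal(specificity(0, 10), 0)
  expect_equal(accuracyRatio(50, 0, 50, 0), 1)
  expect_equal(mcc(50, 0, 50, 0), 1)    # perfect prediction
  expect_equal(mcc(0, 50, 0, 50), -1)   # perfect anti-correlation
  expect_equal(mcc(25, 25, 25, 25), 0)  # random prediction
  # direct evaluation of the closed form
  expect_equal(mcc(10, 5, 20, 3),
               (10 * 20 - 5 * 3) / sqrt(13 * 15 * 25 * 23))

  # undefined metrics surface as NA, never 0
  expect_true(is.na(sensitivity(0, 0)))
  expect_true(is.na(specificity(0, 0)))
  expect_true(is.na(mcc(5, 0, 0, 5)))

  # mcc symmetric under simultaneous TP<->TN, FP<->FN swap
  expect_equal(mcc(10, 5, 20, 3), mcc(20, 3, 10, 5))
})

test_that("confusion counts and one-vs-rest views are consistent", {
  truth <- c("a", "a", "a", "b", "b", "c", "c", "c", "c")
  pred  <- c("a", "b", "a", "b", "c", "c", "c", "a", "c")
  cc <- confusionCounts(truth, pred)
  m <- countsMatrix(cc)
  expect_equal(sum(m), 9)
  expect_equal(unname(diag(m)), c(2L, 1L, 3L))
  ovr <- ovrCounts(cc)
  # every one-vs-rest quadruple partitions the sample
  expect_true(all(ovr$TP + ovr$FP + ovr$TN + ovr$FN == 9))
  expect_equal(ovr$TP, unname(diag(m)))
  # overall accuracy is the trace identity
  rep <- metricsReport(cc)
  expect_equal(rep@overallAccuracy, sum(diag(m)) / sum(m))
})

test_that("AUC agrees with O(n^2) concordance counting", {
  expect_equal(rocAuc(c(4, 3, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)  # all ties

  set.seed(31)
  for (i in 1:5) {
    sc <- round(rnorm(12), 1)  # rounding forces some ties
    tr <- sample(c(0, 1), 12, replace = TRUE)
    if (length(unique(tr)) < 2) tr[1:2] <- c(0, 1)
    expect_equal(rocAuc(sc, tr)$auc, auc_oracle(sc, tr))
  }

  # complement identity
  sc <- rnorm(20)
  tr <- rep(c(0, 1), 10)
  expect_equal(rocAuc(sc, tr)$auc + rocAuc(-sc, tr)$auc, 1)

  # curve ends at (1,1) and is monotone
  r <- rocAuc(sc, tr)
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))

  expect_error(rocAuc(1:4, rep(1, 4)), "two classes")
})

test_that("AUC matches the pROC reference implementation", {
  set.seed(37)
  sc <- rnorm(50)
  tr <- rbinom(50, 1, 0.4)
  ours <- rocAuc(sc, tr)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(tr, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("metrics report carries per-class AUC and serializes", {
  set.seed(41)
  truth <- rep(c("a", "b", "c"), each = 10)
  scores <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  scores[cbind(1:30, match(truth, c("a", "b", "c")))] <-
    scores[cbind(1:30, match(truth, c("a", "b", "c")))] + 3
  pred <- c("a", "b", "c")[apply(scores, 1, which.max)]
  rep <- metricsReport(confusionCounts(truth, pred),
                       scores = scores, truth = truth)
  expect_true(all(rep@perClass$auc > 0.9))
  expect_true(all(rep@macro[c("sensitivity", "specificity")] <= 1))
  js <- jsonlite::fromJSON(metricsReportJSON(rep))
  expect_equal(js$overall_accuracy, rep@overallAccuracy)
  expect_equal(nrow(js$per_class), 3)
  # ROC points writer
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeRocPoints(rocAuc(scores[, "a"], truth == "a",
                        positive = "TRUE"), tsv)
  expect_true(file.exists(tsv))
})
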