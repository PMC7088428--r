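# Seeded Gaussian blob data: k classes, d features, class means spread out.
make_blobs <- function(n_per_class, centers, sd = 0.5, seed = 1) {
  k <- nrow(centers)
  d <- ncol(centers)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per_class * d, mean = rep(centers[i, ],
      each = n_per_class), sd = sd), n_per_class, d)))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(paste0("c", seq_len(k)), each = n_per_class))
}

test_that("stratified folds balance every class and are reproducible", {
  labs <- rep(c("a", "b", "c", "d"), times = c(23, 11, 17, 40))
  f <- stratifiedFolds(labs, folds = 5, seed = 9)
  expect_equal(sort(unique(f)), 1:5)
  for (cl in unique(labs)) {
    sizes <- table(f[labs == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(f, stratifiedFolds(labs, folds = 5, seed = 9))
  expect_false(identical(f, stratifiedFolds(labs, folds = 5, seed = 10)))
  expect_error(stratifiedFolds(labs, folds = 1), ">= 2")
})

test_that("training learns separable data and guards its contract", {
  blobs <- make_blobs(25, centers = 4 * diag(4), seed = 2)
  model <- trainSVM(blobs$x, blobs$y, svmConfig(C = 8, gamma = 0.25))
  expect_s4_class(model, "MitoSVMModel")
  # near-perfect recovery of separable training data
  expect_gte(mean(predict(model, blobs$x) == blobs$y), 0.99)
  # predictions stay inside the training label set
  expect_true(all(predict(model, matrix(rnorm(40), 10, 4)) %in%
                  blobs$y))
  # decision scores rank the true class highest for separable data
  sc <- decisionScores(model, blobs$x)
  expect_equal(dim(sc), c(100L, 4L))
  expect_gte(mean(colnames(sc)[apply(sc, 1, which.max)] == blobs$y),
             0.99)
  expect_error(predict(model, matrix(0, 3, 2)), "features")
  expect_error(trainSVM(blobs$x, rep("one", 100)), "two classes")
  expect_error(svmConfig(C = -1), "positive")
})

test_that("grid search picks accurate configurations deterministically", {
  # a one-point grid returns that point
  blobs <- make_blobs(12, centers = 3 * diag(3), seed = 4)
  cfg <- gridSearch(blobs$x, blobs$y,
                    grid = list(C = 2, gamma = 0.125), folds = 3,
                    seed = 5)
  expect_equal(cfg@C, 2)
  expect_equal(cfg@gamma, 0.125)

  # separable two-class data: selected config cross-validates >= 0.95
  two <- make_blobs(20, centers = rbind(c(0, 0), c(4, 4)), seed = 6)
  cfg2 <- gridSearch(two$x, two$y,
                     grid = list(C = c(1, 10), gamma = c(0.1, 1)),
                     folds = 5, seed = 7)
  cv <- crossValidate(two$x, two$y, cfg2, folds = 5, seed = 7)
  expect_gte(cv$accuracy, 0.95)

  # determinism of the selection
  cfg3 <- gridSearch(two$x, two$y,
                     grid = list(C = c(1, 10), gamma = c(0.1, 1)),
                     folds = 5, seed = 7)
  expect_equal(c(cfg2@C, cfg2@gamma), c(cfg3@C, cfg3@gamma))

  expect_error(gridSearch(two$x, two$y, grid = list(C = numeric(0),
    gamma = 1)), "non-empty")
})

test_that("cross-validation tests each sample once and respects folds", {
  blobs <- make_blobs(15, centers = 3 * diag(4), seed = 8)
  cv <- crossValidate(blobs$x, blobs$y, svmConfig(C = 4, gamma = 0.25),
                      folds = 5, seed = 3)
  # per-fold confusions sum to one full pass
  total <- Reduce(`+`, lapply(cv$perFold, countsMatrix))
  expect_equal(total, countsMatrix(cv$confusion))
  expect_equal(sum(countsMatrix(cv$confusion)), 60)
  # separable data cross-validates accurately
  expect_gte(cv$accuracy, 0.90)
  # scores filled for every sample
  expect_false(anyNA(cv$scores))
  expect_error(crossValidate(blobs$x, blobs$y, folds = 20), "per class")
})

test_that("per-fold feature selection works inside cross-validation", {
  # only feature 3 carries signal; selection should keep accuracy high
  set.seed(12)
  labs <- rep(c("a", "b"), each = 20)
  x <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  x[, 3] <- x[, 3] + 3 * (labs == "a")
  cv <- crossValidate(x, labs, svmConfig(C = 4, gamma = 0.5),
                      folds = 5, seed = 2, topK = 2)
  expect_gte(cv$accuracy, 0.9)
})

test_that("models persist to disk and reload intact", {
  blobs <- make_blobs(10, centers = 3 * diag(3), seed = 14)
  model <- trainSVM(blobs$x, blobs$y, svmConfig(C = 2, gamma = 0.3))
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(predict(back, blobs$x), predict(model, blobs$x))
  expect_equal(back@config@C, 2)
})
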