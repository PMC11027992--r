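## small helper: an AbetaFeatureSet from plain matrices
makeFeatureSet <- function(X, y, prefix = "eeg:") {
  colnames(X) <- paste0(prefix, colnames(X))
  recs <- lapply(seq_along(y), function(i)
    new("SubjectRecord", subjectId = rownames(X)[i], abetaRatio = y[i]))
  names(recs) <- rownames(X)
  recs <- assignGroups(recs)
  extracted <- lapply(seq_len(nrow(X)), function(i) X[i, ])
  names(extracted) <- rownames(X)
  assembleFeatureMatrix(recs, extracted)
}

randomFeatureSet <- function(n = 42, p = 12, signal = TRUE, seed = 1) {
  set.seed(seed)
  y <- exp(runif(n, log(1e-3), log(0.22)))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("f%02d", 1:p)))
  if (signal) X[, 1] <- -log(y) + rnorm(n, 0, 0.3)
  makeFeatureSet(X, y)
}

test_that("correlation ranking puts an exact predictor first", {
  set.seed(71)
  y <- rnorm(50)
  X <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, sprintf("n%02d", 1:20)))
  X[, 7] <- y
  colnames(X)[7] <- "target_copy"
  sel <- rankSelectFeatures(X, y, topK = 5)
  expect_equal(sel[1], "target_copy")
  ## topK = all features returns the identity set
  expect_setequal(rankSelectFeatures(X, y, topK = 20), colnames(X))
  ## constant features rank last with a warning
  X[, 3] <- 1
  expect_warning(sel2 <- rankSelectFeatures(X, y, topK = 20), "constant")
  expect_equal(sel2[20], colnames(X)[3])
})

test_that("planted informative features are recovered by the ranking", {
  set.seed(72)
  hits <- replicate(10, {
    n <- 200
    y <- rnorm(n)
    X <- matrix(rnorm(n * 510), n, 510,
                dimnames = list(NULL, sprintf("f%03d", 1:510)))
    for (j in 1:10) X[, j] <- 0.5 * scale(y) + sqrt(0.75) * rnorm(n)
    sel <- rankSelectFeatures(X, y, topK = 50)
    sum(sprintf("f%03d", 1:10) %in% sel)
  })
  expect_gte(mean(hits >= 9), 0.9)
})

test_that("cross-validation covers every subject exactly once, deterministically", {
  fs <- randomFeatureSet(seed = 2)
  cfg <- regressorConfig(nTrees = 30, nFolds = 5, seed = 11)
  pr1 <- crossValidatePredict(fs, cfg)
  pr2 <- crossValidatePredict(fs, cfg)
  expect_identical(pr1$predictions, pr2$predictions)     # bit-identical
  tab <- table(pr1$predictions$subject)
  expect_true(all(tab == 1))
  expect_setequal(pr1$predictions$subject, rownames(featureMatrix(fs)))
  expect_true(all(tabulate(pr1$predictions$fold, 5) >= 1))
})

test_that("feature ranking never sees test-fold targets", {
  fs <- randomFeatureSet(seed = 3)
  cfg <- regressorConfig(nTrees = 10, nFolds = 4, seed = 5)
  n <- nrow(featureMatrix(fs))
  folds <- stats::setNames(rep_len(1:4, n), rownames(featureMatrix(fs)))
  pr <- crossValidatePredict(fs, cfg, folds = folds)
  ## permute the targets inside fold 1 only: fold 1's ranking is computed on
  ## the other folds, so its selected features must not change
  fs2 <- fs
  y <- SummarizedExperiment::colData(fs2)$abeta_ratio
  set.seed(99)
  idx <- which(folds[colnames(fs2)] == 1)
  y[idx] <- sample(y[idx])
  SummarizedExperiment::colData(fs2)$abeta_ratio <- y
  pr2 <- crossValidatePredict(fs2, cfg, folds = folds)
  expect_identical(pr$selectedFeatures[[1]], pr2$selectedFeatures[[1]])
  ## the shuffle must, however, reach the other folds' training data
  expect_false(identical(pr$selectedFeatures, pr2$selectedFeatures))
})

test_that("a perfectly predictable target is recovered almost exactly", {
  set.seed(73)
  n <- 60
  y <- seq(0.001, 0.2, length.out = n)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:5)))
  X[, 1] <- y
  fs <- makeFeatureSet(X, y)
  pr <- crossValidatePredict(fs, regressorConfig(nFolds = 5, seed = 1))
  ## leaf averaging (min 5 obs/leaf) bounds how exact the fit can be
  expect_lt(pr$metrics$normalizedError, 0.2)
  expect_gt(pr$metrics$accuracy, 0.8)
  expect_gt(pr$metrics$auc, 0.95)
  expect_lt(pr$metrics$normalizedError,
            pr$metrics$baselineNormalizedError)
})

test_that("prediction metrics match hand-computed values", {
  m <- evaluatePredictions(c(0, 0.01, 0.02), c(0.005, 0.01, 0.015))
  expect_equal(m$mae, 0.01 / 3)
  expect_equal(m$range, 0.02)
  expect_equal(m$normalizedError, 1 / 6)
  expect_equal(m$accuracy, 5 / 6)

  perfect <- evaluatePredictions(c(0.05, 0.2, 0.08), c(0.05, 0.2, 0.08))
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)

  flat <- evaluatePredictions(c(0.05, 0.2, 0.08, 0.3), rep(0.1, 4))
  expect_equal(flat$auc, 0.5)

  const <- evaluatePredictions(rep(0.1, 3), c(0.1, 0.2, 0.05))
  expect_true(const$degenerate)
})

test_that("the trapezoid AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(74)
  truth <- exp(runif(40, log(1e-3), log(0.25)))
  pred <- truth * exp(rnorm(40, 0, 0.8))
  m <- evaluatePredictions(truth, pred)
  ref <- suppressMessages(
    pROC::auc(pROC::roc(response = factor(truth <= 0.1), predictor = -pred,
                        direction = "<", quiet = TRUE)))
  expect_equal(m$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("pure-noise targets do no better than the mean baseline", {
  set.seed(75)
  worse <- replicate(12, {
    fs <- randomFeatureSet(n = 40, p = 10, signal = FALSE,
                           seed = sample.int(1e6, 1))
    pr <- crossValidatePredict(fs, regressorConfig(nTrees = 40, nFolds = 4,
                                                   seed = 3))
    pr$metrics$mae - pr$metrics$baselineMae
  })
  expect_gt(mean(worse > -0.002), 0.8)   # no systematic beat of the baseline
})

test_that("larger ensembles do not increase expected out-of-fold error", {
  set.seed(76)
  diffs <- replicate(6, {
    fs <- randomFeatureSet(n = 50, p = 8, seed = sample.int(1e6, 1))
    sweep <- maeVsTrees(fs, regressorConfig(nFolds = 5, seed = 2),
                        treeCounts = c(5, 100))
    sweep$mae[sweep$nTrees == 100] - sweep$mae[sweep$nTrees == 5]
  })
  expect_lt(mean(diffs), 0)
})

test_that("configuration validation rejects nonsense", {
  expect_error(regressorConfig(nTrees = 0), "nTrees")
  expect_error(regressorConfig(minLeaf = 0), "minLeaf")
  expect_error(regressorConfig(nFolds = 1), "nFolds")
  fs <- randomFeatureSet(n = 10, seed = 4)
  expect_error(crossValidatePredict(fs, regressorConfig(nFolds = 11)),
               "fewer subjects")
})
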