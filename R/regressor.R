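#' Random-forest regressor configuration
#'
#' Defaults follow the reference analysis: 100 trees with a minimum of five
#' observations per leaf, the top 500 features by absolute correlation
#' (capped at the number of available features), and sevenfold
#' cross-validation.
#'
#' @param nTrees number of trees.
#' @param minLeaf minimum observations per leaf (\code{nodesize}).
#' @param topK number of correlation-ranked features kept.
#' @param nFolds cross-validation folds.
#' @param seed integer seed; fold assignment and each fold's forest use
#'   seeds derived from it.
#' @return Validated list of class \code{"RegressorConfig"}.
#' @export
regressorConfig <- function(nTrees = 100L, minLeaf = 5L, topK = 500L,
                            nFolds = 7L, seed = 1L) {
  cfg <- list(nTrees = as.integer(nTrees), minLeaf = as.integer(minLeaf),
              topK = as.integer(topK), nFolds = as.integer(nFolds),
              seed = as.integer(seed))
  if (cfg$nTrees < 1L) stop("nTrees must be >= 1")
  if (cfg$minLeaf < 1L) stop("minLeaf must be >= 1")
  if (cfg$topK < 1L) stop("topK must be >= 1")
  if (cfg$nFolds < 2L) stop("nFolds must be >= 2")
  class(cfg) <- "RegressorConfig"
  cfg
}

#' Rank features by absolute correlation with the target
#'
#' Pearson-correlates every feature with the target on the supplied rows
#' only (call it with training rows to keep test folds unseen), ranks by
#' decreasing absolute correlation with ties broken by feature name, and
#' returns the top \code{topK} names. Constant features get |r| = 0 and rank
#' last, with a warning.
#'
#' @param X subjects x features numeric matrix.
#' @param y target values.
#' @param topK number of features to keep (capped at \code{ncol(X)}).
#' @return Character vector of selected feature names, best first.
#' @export
rankSelectFeatures <- function(X, y, topK = 500L) {
  if (nrow(X) != length(y)) stop("X rows must match y")
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  const <- is.na(r)
  if (any(const)) {
    warning(sum(const), " constant feature(s) ranked last")
    r[const] <- 0
  }
  ord <- order(-abs(r), colnames(X))
  colnames(X)[ord][seq_len(min(topK, ncol(X)))]
}

#' Fit a random-forest regressor
#'
#' Bootstrap-aggregated regression trees with per-split feature subsampling
#' (\code{randomForest} defaults), \code{nTrees} trees and leaf size
#' \code{minLeaf}; deterministic given the config seed.
#'
#' @param X training subjects x selected features matrix.
#' @param y training targets.
#' @param config a \code{\link{regressorConfig}}.
#' @return A fitted \code{randomForest} object.
#' @export
fitForest <- function(X, y, config = regressorConfig()) {
  if (ncol(X) < 1L) stop("no features selected")
  if (nrow(X) < 2L) stop("at least two training subjects required")
  set.seed(config$seed)
  randomForest::randomForest(x = X, y = y, ntree = config$nTrees,
                             nodesize = config$minLeaf)
}

#' Cross-validated out-of-fold prediction
#'
#' Stratified (by group label), seeded fold assignment; correlation ranking
#' and forest fitting are repeated inside every fold on training rows only,
#' so no information from a test fold leaks into feature selection or
#' fitting. Every subject is predicted exactly once, out of fold. A
#' mean-of-training-targets baseline prediction is carried along for
#' reference. Subjects with missing values in the selected modalities are
#' excluded first (the joint-modality subset of a partially complete
#' cohort).
#'
#' @param fs an \linkS4class{AbetaFeatureSet}.
#' @param config a \code{\link{regressorConfig}}.
#' @param modalities optional subset of \code{c("eeg", "mri", "scale")} to
#'   restrict the feature matrix (mirrors EEG-only / MRI-only / joint runs).
#' @param threshold positivity threshold used for stratification and ROC.
#' @param leakyRanking rank once on the full matrix instead of per fold
#'   (reproduces the optimistic reading of a global ranking; off by
#'   default and discouraged).
#' @param folds optional explicit fold assignment (named integer vector),
#'   chiefly for instrumentation and leakage tests.
#' @return List of class \code{"PredictionResult"}: \code{predictions}
#'   (data.frame: subject, truth, predicted, baseline, fold, group),
#'   \code{selectedFeatures} (per fold), \code{excluded}, \code{config},
#'   \code{metrics} (see \code{\link{evaluatePredictions}}).
#' @export
crossValidatePredict <- function(fs, config = regressorConfig(),
                                 modalities = NULL, threshold = 0.1,
                                 leakyRanking = FALSE, folds = NULL) {
  stopifnot(is(fs, "AbetaFeatureSet"))
  X <- featureMatrix(fs)
  if (!is.null(modalities)) {
    keep <- featureModalities(fs) %in% modalities
    if (!any(keep)) stop("no features for modalities ",
                         paste(modalities, collapse = "+"))
    X <- X[, keep, drop = FALSE]
  }
  y <- targetRatio(fs)
  grp <- groupLabel(fs)

  complete <- rowSums(is.na(X)) == 0
  excluded <- rownames(X)[!complete]
  if (length(excluded))
    message(length(excluded), " subject(s) excluded from prediction ",
            "(incomplete modalities): ", paste(excluded, collapse = ", "))
  X <- X[complete, , drop = FALSE]
  y <- y[complete]
  grp <- grp[complete]
  n <- nrow(X)
  if (n < config$nFolds) stop("fewer subjects than folds")

  if (is.null(folds)) {
    set.seed(.deriveSeed(config$seed, 9001L))
    folds <- integer(n)
    names(folds) <- rownames(X)
    ## stratified assignment; the fold counter continues across strata so
    ## folds stay balanced and none is left empty
    offset <- 0L
    for (g in unique(grp)) {
      idx <- which(grp == g)
      folds[idx[sample.int(length(idx))]] <-
        (offset + seq_along(idx) - 1L) %% config$nFolds + 1L
      offset <- offset + length(idx)
    }
  } else {
    folds <- folds[rownames(X)]
  }
  if (any(tabulate(folds, config$nFolds) < 1L))
    stop("a fold has no test subject")

  pred <- base <- rep(NA_real_, n)
  selected <- vector("list", config$nFolds)
  globalRank <- if (leakyRanking) rankSelectFeatures(X, y, config$topK)
  for (f in seq_len(config$nFolds)) {
    te <- folds == f
    tr <- !te
    sel <- if (leakyRanking) globalRank
           else rankSelectFeatures(X[tr, , drop = FALSE], y[tr], config$topK)
    selected[[f]] <- sel
    foldCfg <- config
    foldCfg$seed <- .deriveSeed(config$seed, 100L + f)
    rf <- fitForest(X[tr, sel, drop = FALSE], y[tr], foldCfg)
    pred[te] <- stats::predict(rf, X[te, sel, drop = FALSE])
    base[te] <- mean(y[tr])
  }

  predictions <- data.frame(subject = rownames(X), truth = unname(y),
                            predicted = pred, baseline = base,
                            fold = unname(folds), group = unname(grp),
                            row.names = NULL)
  out <- list(predictions = predictions, selectedFeatures = selected,
              excluded = excluded, config = config,
              metrics = evaluatePredictions(y, pred, threshold,
                                            baseline = base))
  class(out) <- "PredictionResult"
  out
}

#' @export
print.PredictionResult <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "PredictionResult: %d subjects, %d folds\n  MAE %.5f | normalized error %.3f | accuracy %.3f | AUC %.3f\n",
    nrow(x$predictions), x$config$nFolds, m$mae, m$normalizedError,
    m$accuracy, m$auc))
  invisible(x)
}

## ROC over predicted-value thresholds; lower predicted ratio => positive.
.rocCurve <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  lab <- positive[ord]
  nP <- sum(positive)
  nN <- sum(!positive)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  data.frame(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr)
}

#' Prediction error and ROC metrics
#'
#' Mean absolute error, the normalized error (MAE over the fluctuation range
#' of the true values), accuracy defined as one minus the normalized error,
#' residuals, and the ROC/AUC of classifying amyloid positivity
#' (truth <= threshold) from the predicted values, sweeping a cut over the
#' predictions and integrating by the trapezoid rule.
#'
#' @param truth true marker values (non-constant).
#' @param predicted out-of-fold predictions.
#' @param threshold positivity threshold (default 0.1).
#' @param baseline optional baseline predictions evaluated alongside.
#' @return List: mae, range, normalizedError, accuracy, auc, roc
#'   (data.frame), residuals, nPositive, nNegative, degenerate; baseline
#'   metrics (baselineMae, baselineNormalizedError) when supplied.
#' @examples
#' evaluatePredictions(c(0, 0.01, 0.02), c(0.005, 0.01, 0.015))$accuracy
#' @export
evaluatePredictions <- function(truth, predicted, threshold = 0.1,
                                baseline = NULL) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (length(truth) < 2L) stop("at least two subjects required")
  rng <- max(truth) - min(truth)
  if (rng == 0)
    return(list(mae = mean(abs(predicted - truth)), range = 0,
                normalizedError = NA_real_, accuracy = NA_real_,
                auc = NA_real_, roc = NULL,
                residuals = predicted - truth, degenerate = TRUE))
  mae <- mean(abs(predicted - truth))
  positive <- truth <= threshold
  roc <- NULL
  auc <- NA_real_
  if (any(positive) && any(!positive)) {
    roc <- .rocCurve(-predicted, positive)
    auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  }
  out <- list(mae = mae, range = rng, normalizedError = mae / rng,
              accuracy = 1 - mae / rng, auc = auc, roc = roc,
              residuals = predicted - truth,
              nPositive = sum(positive), nNegative = sum(!positive),
              degenerate = FALSE)
  if (!is.null(baseline)) {
    out$baselineMae <- mean(abs(baseline - truth))
    out$baselineNormalizedError <- out$baselineMae / rng
  }
  out
}

#' Out-of-fold MAE as a function of ensemble size
#'
#' Re-runs the cross-validation at several tree counts (same folds, same
#' derived seeds) to reproduce the error-versus-trees sweep used to justify
#' the 100-tree default.
#'
#' @param fs an \linkS4class{AbetaFeatureSet}.
#' @param config base \code{\link{regressorConfig}}.
#' @param treeCounts integer vector of ensemble sizes.
#' @param ... passed to \code{\link{crossValidatePredict}}.
#' @return data.frame: nTrees, mae, normalizedError, auc.
#' @export
maeVsTrees <- function(fs, config = regressorConfig(),
                       treeCounts = c(5, 10, 25, 50, 100), ...) {
  rows <- lapply(treeCounts, function(tc) {
    cfg <- config
    cfg$nTrees <- as.integer(tc)
    m <- crossValidatePredict(fs, cfg, ...)$metrics
    data.frame(nTrees = tc, mae = m$mae,
               normalizedError = m$normalizedError, auc = m$auc)
  })
  do.call(rbind, rows)
}
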