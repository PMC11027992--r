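#' Two-sample t test between groups
#'
#' Classical two-sample t test (equal variances by default, Welch on
#' request) comparing a feature between the positive and negative groups.
#' When both groups are constant with equal means the comparison is
#' degenerate and flagged rather than tested.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param varEqual pooled-variance t (default TRUE); FALSE gives Welch.
#' @param alpha significance threshold.
#' @return List: statistic, df, p, meanA, meanB, direction
#'   (\code{"A<B"}/\code{"A>B"}/\code{"A=B"}), significant, kind, degenerate.
#' @export
twoSampleTest <- function(a, b, varEqual = TRUE, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two observations")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stop("non-finite values")
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                meanA = mean(a), meanB = mean(b), direction = "A=B",
                significant = FALSE, kind = "two-sample", degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = varEqual)
  dir <- if (mean(a) < mean(b)) "A<B" else if (mean(a) > mean(b)) "A>B"
         else "A=B"
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(a), meanB = mean(b), direction = dir,
       significant = tt$p.value < alpha, kind = "two-sample",
       degenerate = FALSE)
}

#' Paired t test between two group-mean spectra
#'
#' Pairs the two energy-distribution curves across frequency bins (the only
#' pairing structure available between groups of unequal size) and tests
#' whether their bin-wise difference is centred at zero. A constant non-zero
#' difference has zero variance; it is reported as an exact difference with
#' p = 0 and flagged degenerate.
#'
#' @param specA,specB \linkS4class{EEGSpectrum} objects on identical grids,
#'   or plain numeric curves of equal length.
#' @param range optional \code{c(low, high)} Hz restriction (used only with
#'   spectrum objects).
#' @param alpha significance threshold.
#' @return List as in \code{\link{twoSampleTest}} with kind
#'   \code{"paired"}.
#' @export
pairedSpectrumTest <- function(specA, specB, range = NULL, alpha = 0.05) {
  if (is(specA, "EEGSpectrum") && is(specB, "EEGSpectrum")) {
    if (length(specA@frequencies) != length(specB@frequencies) ||
        max(abs(specA@frequencies - specB@frequencies)) > 1e-9)
      stop("spectra are on different frequency grids")
    a <- rowMeans(specA@power)
    b <- rowMeans(specB@power)
    if (!is.null(range)) {
      sel <- specA@frequencies >= range[1] & specA@frequencies < range[2]
      a <- a[sel]; b <- b[sel]
    }
  } else {
    a <- as.numeric(specA); b <- as.numeric(specB)
    if (length(a) != length(b)) stop("curves of unequal length")
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    exact <- mean(d) != 0
    return(list(statistic = if (exact) Inf * sign(mean(d)) else 0,
                df = length(d) - 1, p = if (exact) 0 else 1,
                meanA = mean(a), meanB = mean(b),
                direction = if (mean(d) < 0) "A<B"
                            else if (mean(d) > 0) "A>B" else "A=B",
                significant = exact, kind = "paired", degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(a), meanB = mean(b),
       direction = if (mean(d) < 0) "A<B" else if (mean(d) > 0) "A>B"
                   else "A=B",
       significant = tt$p.value < alpha, kind = "paired", degenerate = FALSE)
}

#' Pearson correlation with R-squared
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform, the squared coefficient, and the least-squares line of y on x.
#'
#' @param x,y numeric vectors, length >= 3, not constant.
#' @return List: r, r2, p, n, slope, intercept, degenerate.
#' @export
pearsonAssociation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least three observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, n = length(x),
                slope = NA_real_, intercept = NA_real_, degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  slope <- ct$estimate * stats::sd(y) / stats::sd(x)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2, p = ct$p.value,
       n = length(x), slope = unname(slope),
       intercept = mean(y) - unname(slope) * mean(x), degenerate = FALSE)
}

#' Group comparison table over a feature set
#'
#' Runs the two-sample t test for every feature of an
#' \linkS4class{AbetaFeatureSet} between the positive and negative groups,
#' returning a tidy table. No multiple-testing correction is applied by
#' default, mirroring a per-comparison 0.05 threshold;
#' Benjamini-Hochberg-adjusted p-values are added when \code{adjust = TRUE}
#' (recommended for exploratory use).
#'
#' @param fs an \linkS4class{AbetaFeatureSet}.
#' @param varEqual pooled-variance t (default) or Welch.
#' @param alpha significance threshold.
#' @param adjust add a Benjamini-Hochberg \code{p_adj} column.
#' @return data.frame: feature, modality, mean_positive, mean_negative,
#'   statistic, p, (p_adj,) direction, significant.
#' @export
groupStatistics <- function(fs, varEqual = TRUE, alpha = 0.05,
                            adjust = FALSE) {
  stopifnot(is(fs, "AbetaFeatureSet"))
  X <- featureMatrix(fs)
  grp <- groupLabel(fs)
  pos <- grp == "positive"
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("each group needs at least two subjects")
  rows <- lapply(colnames(X), function(f) {
    a <- X[pos, f]; b <- X[!pos, f]
    ok <- !is.na(a) & is.finite(a)
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)))
      return(data.frame(feature = f, mean_positive = mean(a),
                        mean_negative = mean(b), statistic = NA_real_,
                        p = NA_real_, direction = NA_character_,
                        significant = FALSE))
    tt <- twoSampleTest(a, b, varEqual = varEqual, alpha = alpha)
    data.frame(feature = f, mean_positive = tt$meanA,
               mean_negative = tt$meanB, statistic = tt$statistic,
               p = tt$p,
               direction = c("A<B" = "positive<negative",
                             "A>B" = "positive>negative",
                             "A=B" = "equal")[tt$direction],
               significant = tt$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- cbind(out[, "feature", drop = FALSE],
               modality = featureModalities(fs)[out$feature],
               out[, -1])
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  }
  rownames(out) <- NULL
  out
}
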