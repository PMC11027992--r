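#' Quantize a signal into a symbol sequence
#'
#' Maps a single-channel signal onto the alphabet \code{0..l-1} using
#' \code{l - 1} strictly increasing thresholds: symbol 0 where
#' \code{x <= T1}, symbol k where \code{T_k < x <= T_{k+1}}, and symbol
#' \code{l - 1} above the last threshold. Default thresholds are the
#' empirical \code{1/l, ..., (l-1)/l} quantiles, giving approximately equal
#' symbol frequencies.
#'
#' @param signal numeric vector.
#' @param l alphabet size (>= 2).
#' @param thresholds explicit thresholds (length \code{l - 1}), strictly
#'   increasing; required when the signal is constant.
#' @return A list with \code{symbols} (integer, 0-based), \code{l},
#'   \code{n} and \code{thresholds}.
#' @examples
#' quantizeSignal(c(1, 5, 2, 9), l = 2)$symbols   # 0 1 0 1
#' @export
quantizeSignal <- function(signal, l = 2L, thresholds = NULL) {
  if (l < 2L) stop("alphabet size l must be >= 2")
  if (anyNA(signal)) stop("signal contains missing values")
  if (is.null(thresholds)) {
    if (max(signal) == min(signal))
      stop("constant signal: quantile thresholds are undefined; ",
           "supply explicit thresholds")
    thresholds <- if (l == 2L) stats::median(signal)
                  else unname(stats::quantile(signal,
                                              probs = seq_len(l - 1) / l))
  }
  if (length(thresholds) != l - 1L || is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be ", l - 1L, " non-decreasing values")
  symbols <- findInterval(signal, thresholds, left.open = TRUE)
  list(symbols = as.integer(symbols), l = as.integer(l),
       n = length(signal), thresholds = as.numeric(thresholds))
}

#' Normalized Lempel-Ziv (LZ76) complexity
#'
#' Parses the symbol sequence left to right into phrases, each phrase being
#' the shortest continuation not seen as a substring of the whole preceding
#' sequence; the trailing (possibly reproducible) phrase counts as a phrase.
#' The phrase count \code{c} is normalized as
#' \deqn{C = c \log_l(n) / n,} which is invariant under relabeling of the
#' symbols and makes sequences of different lengths comparable.
#'
#' @param seq result of \code{\link{quantizeSignal}}, or any list with
#'   integer \code{symbols} (0-based) and alphabet size \code{l}.
#' @return List with the phrase count \code{c} and normalized complexity
#'   \code{C}.
#' @examples
#' lzComplexity(list(symbols = rep(0L, 8), l = 2L))$c   # parses 0 | 0000000
#' @export
lzComplexity <- function(seq) {
  symbols <- as.integer(seq$symbols)
  l <- as.integer(seq$l)
  n <- length(symbols)
  if (n < 1L) stop("empty sequence")
  cc <- cpp_lz76(symbols, l)
  list(c = cc, C = cc * (log(n) / log(l)) / n)
}

#' Per-region Lempel-Ziv complexity summaries
#'
#' Quantizes every channel (median split at the default \code{l = 2}),
#' computes the normalized LZ76 complexity, and aggregates per scalp region
#' and overall.
#'
#' @param rec a (preprocessed) \linkS4class{EEGRecording}.
#' @param l alphabet size.
#' @param thresholds optional explicit quantization thresholds.
#' @return List with \code{perChannel} (named normalized complexities),
#'   \code{regions} (data.frame: region, mean, sd, n) and \code{overall}.
#' @export
regionComplexity <- function(rec, l = 2L, thresholds = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  .regionComplexityCore(t(rec@data), rec@regionMap[rec@channelNames], l,
                        thresholds)
}

.regionComplexityCore <- function(xt, regions, l = 2L, thresholds = NULL) {
  missing <- setdiff(.REGIONS, regions)
  if (length(missing))
    stop("region(s) with zero channels: ", paste(missing, collapse = ", "))
  perChannel <- vapply(seq_len(ncol(xt)), function(ch)
    lzComplexity(quantizeSignal(xt[, ch], l, thresholds))$C, 0)
  names(perChannel) <- colnames(xt)
  agg <- data.frame(
    region = .REGIONS,
    mean = vapply(.REGIONS, function(r) mean(perChannel[regions == r]), 0),
    sd = vapply(.REGIONS, function(r) stats::sd(perChannel[regions == r]), 0),
    n = vapply(.REGIONS, function(r) sum(regions == r), 0L),
    row.names = NULL)
  list(perChannel = perChannel, regions = agg,
       overall = list(mean = mean(perChannel), sd = stats::sd(perChannel)))
}

.binIndices <- function(x, nBins, method, trimSd = 2.5) {
  ## x: samples x channels; returns 0-based integer bin matrix
  if (method == "width") {
    cpp_equal_width_bins(x, as.integer(nBins), trimSd)
  } else {
    out <- matrix(0L, nrow(x), ncol(x))
    for (c in seq_len(ncol(x))) {
      br <- stats::quantile(x[, c], probs = seq_len(nBins - 1) / nBins,
                            names = FALSE)
      out[, c] <- findInterval(x[, c], br, left.open = TRUE)
    }
    out
  }
}

#' Histogram mutual information between two signals
#'
#' Plug-in estimator on the joint histogram:
#' \deqn{I(X, Y) = \sum_{x, y} p(x, y) \log \frac{p(x, y)}{p(x) p(y)},}
#' with empty cells contributing zero. Nonnegative by construction and
#' exactly symmetric in its arguments. The plug-in bias is of order
#' \code{(nBins - 1)^2 / (2 n)}, negligible at the default 16 bins for
#' records of tens of thousands of samples.
#'
#' @param x,y numeric vectors of equal length.
#' @param nBins marginal histogram bins (default 16).
#' @param unit \code{"nats"} (natural log, default) or \code{"bits"}.
#' @param method \code{"width"}: equal-width bins (default);
#'   \code{"quantile"}: equal-count bins.
#' @param trimSd with \code{method = "width"}, bins span the mean plus/minus
#'   \code{trimSd} standard deviations and outliers are clipped into the
#'   edge bins (default 2.5, which keeps the 16-bin discretization loss on
#'   strongly dependent signals small); \code{Inf} spans the full range.
#' @return Mutual information estimate (single number).
#' @examples
#' x <- rep(0:3, 250)
#' mutualInformation(x, x, nBins = 4, unit = "bits")   # H(X) = 2 bits
#' @export
mutualInformation <- function(x, y, nBins = 16L, unit = c("nats", "bits"),
                              method = c("width", "quantile"),
                              trimSd = 2.5) {
  unit <- match.arg(unit)
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (nBins < 2L) stop("nBins must be >= 2")
  bins <- .binIndices(cbind(x, y), nBins, method, trimSd)
  I <- cpp_mi_pairs(bins, as.integer(nBins),
                    matrix(c(0L, 1L), 1L, 2L))[1]
  if (unit == "bits") I / log(2) else I
}

#' Region-level mutual information matrix
#'
#' Entry (r, s), r != s, is the mean histogram mutual information over all
#' channel pairs with one channel in region r and the other in region s; the
#' diagonal averages over distinct within-region pairs. A region with a
#' single channel has an undefined diagonal, reported as \code{NA} (missing,
#' not zero).
#'
#' @param rec a (preprocessed) \linkS4class{EEGRecording} with at least one
#'   channel per region.
#' @param nBins marginal histogram bins.
#' @param unit \code{"nats"} or \code{"bits"}.
#' @param method,trimSd binning scheme, see \code{\link{mutualInformation}}.
#' @return Symmetric 5 x 5 matrix over regions F, P, L-T, R-T, O with
#'   attributes \code{nBins} and \code{unit}.
#' @export
regionMIMatrix <- function(rec, nBins = 16L, unit = c("nats", "bits"),
                           method = c("width", "quantile"), trimSd = 2.5) {
  stopifnot(is(rec, "EEGRecording"))
  .miMatrixCore(t(rec@data), rec@regionMap[rec@channelNames],
                nBins, match.arg(unit), match.arg(method), trimSd)
}

.miMatrixCore <- function(xt, regions, nBins = 16L, unit = "nats",
                          method = "width", trimSd = 2.5) {
  if (length(setdiff(.REGIONS, regions)))
    stop("region(s) with zero channels: ",
         paste(setdiff(.REGIONS, regions), collapse = ", "))
  bins <- .binIndices(xt, nBins, method, trimSd)

  idx <- lapply(.REGIONS, function(r) which(regions == r) - 1L)
  names(idx) <- .REGIONS
  pairList <- list()
  key <- character(0)
  for (i in seq_along(.REGIONS)) {
    for (j in i:length(.REGIONS)) {
      a <- idx[[i]]; b <- idx[[j]]
      if (i == j) {
        if (length(a) < 2L) next
        pr <- t(utils::combn(a, 2L))
      } else {
        pr <- as.matrix(expand.grid(a, b))
      }
      pairList[[length(pairList) + 1L]] <- pr
      key <- c(key, rep(paste(.REGIONS[i], .REGIONS[j], sep = "|"),
                        nrow(pr)))
    }
  }
  pairs <- do.call(rbind, pairList)
  storage.mode(pairs) <- "integer"
  mi <- cpp_mi_pairs(bins, as.integer(nBins), pairs)
  if (unit == "bits") mi <- mi / log(2)
  means <- tapply(mi, key, mean)

  M <- matrix(NA_real_, 5, 5, dimnames = list(.REGIONS, .REGIONS))
  for (i in seq_along(.REGIONS)) {
    for (j in i:length(.REGIONS)) {
      k <- paste(.REGIONS[i], .REGIONS[j], sep = "|")
      if (k %in% names(means)) M[i, j] <- M[j, i] <- means[[k]]
    }
  }
  attr(M, "nBins") <- as.integer(nBins)
  attr(M, "unit") <- unit
  M
}
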