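#' Windowed standard-deviation topographies
#'
#' Cuts the recording into consecutive non-overlapping windows (100 ms by
#' default) and takes each channel's standard deviation inside the window as
#' that channel's activity intensity, yielding one topography per window.
#' The trailing partial window is dropped.
#'
#' @param rec a (preprocessed) \linkS4class{EEGRecording}.
#' @param windowMs window length in milliseconds.
#' @return A windows x channels matrix of SDs with attributes
#'   \code{windowMs} and \code{samplingRate}.
#' @export
extractTopographies <- function(rec, windowMs = 100) {
  stopifnot(is(rec, "EEGRecording"))
  win <- as.integer(round(windowMs / 1000 * rec@samplingRate))
  if (win < 2L) stop("window must span at least two samples")
  if (ncol(rec@data) < win) stop("recording shorter than one window")
  tp <- cpp_window_sd(t(rec@data), win)
  colnames(tp) <- rec@channelNames
  attr(tp, "windowMs") <- windowMs
  attr(tp, "samplingRate") <- rec@samplingRate
  tp
}

#' Fit a cohort-level microstate model
#'
#' k-means clustering (k-means++ seeding, Lloyd iterations, \code{nstart}
#' restarts keeping the lowest within-cluster sum of squares, deterministic
#' given \code{seed}) of SD topographies pooled across subjects. Pooling
#' makes the states cohort-level objects, so per-subject occurrence
#' frequencies are comparable across subjects. Topographies are L2-normalized
#' by default so shape rather than amplitude drives the clustering; ties in
#' nearest-centre assignment go to the lowest state index.
#'
#' @param topographies windows x channels matrix (pooled across subjects),
#'   e.g. \code{rbind} of \code{\link{extractTopographies}} outputs.
#' @param k number of states (>= 2).
#' @param seed integer seed for the restarts.
#' @param subjectIds character vector, one entry per window; defaults to a
#'   single subject.
#' @param normalize L2-normalize topographies before clustering (default
#'   TRUE); set FALSE for raw-SD clustering.
#' @param nstart number of k-means++ restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart.
#' @return A \linkS4class{MicrostateModel}.
#' @export
fitMicrostates <- function(topographies, k, seed = 1L,
                           subjectIds = NULL, normalize = TRUE,
                           nstart = 10L, maxIter = 100L) {
  k <- as.integer(k)
  if (k < 2L) stop("k below the configured minimum of 2")
  if (k > nrow(topographies)) stop("k exceeds the number of topographies")
  if (is.null(subjectIds)) subjectIds <- rep("s1", nrow(topographies))
  if (length(subjectIds) != nrow(topographies))
    stop("one subject id per topography required")
  X <- as.matrix(topographies)
  if (normalize) X <- .rowNormalize(X)
  if (nrow(unique(X)) < k)
    stop("degenerate topographies: fewer than k distinct points")
  set.seed(as.integer(seed))
  km <- cpp_kmeans(X, k, as.integer(nstart), as.integer(maxIter), 1e-10)
  assign <- as.integer(km$cluster) + 1L
  centers <- km$centers
  colnames(centers) <- colnames(topographies)

  subj <- unique(subjectIds)
  occ <- t(vapply(subj, function(s) {
    tab <- tabulate(assign[subjectIds == s], nbins = k)
    tab / sum(tab)
  }, numeric(k)))
  rownames(occ) <- subj
  colnames(occ) <- paste0("state", seq_len(k))

  new("MicrostateModel", k = k, centers = centers, assignments = assign,
      subjectIds = as.character(subjectIds), occurrence = occ,
      totWithinss = km$tot.withinss, normalized = normalize,
      seed = as.integer(seed))
}

#' Per-subject microstate occurrence frequencies
#'
#' @param model a \linkS4class{MicrostateModel}.
#' @return Subjects x k matrix of occurrence proportions (rows sum to 1).
#' @export
occurrenceFrequencies <- function(model) {
  stopifnot(is(model, "MicrostateModel"))
  model@occurrence
}

#' Correlate microstate occurrence with the CSF marker
#'
#' Pearson correlation between each state's occurrence frequency and the
#' amyloid-beta 42/40 ratio across subjects, with two-sided p-values. States
#' with constant occurrence are flagged degenerate and never significant.
#'
#' @param model a \linkS4class{MicrostateModel}.
#' @param ratios named numeric of per-subject ratios, or a list of
#'   \linkS4class{SubjectRecord} covering the model's subjects.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame: state, r, r2, p, significant, direction, degenerate.
#' @export
stateStatistics <- function(model, ratios, alpha = 0.05) {
  stopifnot(is(model, "MicrostateModel"))
  if (is.list(ratios) && !is.numeric(ratios))
    ratios <- stats::setNames(vapply(ratios, abetaRatio, 0),
                              vapply(ratios, subjectId, ""))
  occ <- model@occurrence
  if (is.null(rownames(occ)))
    stop("occurrence matrix must carry subject ids as row names")
  if (nrow(occ) < 3L) stop("at least three subjects required")
  missing <- setdiff(rownames(occ), names(ratios))
  if (length(missing))
    stop("no ratio for subject(s): ", paste(missing, collapse = ", "))
  y <- ratios[rownames(occ)]
  out <- lapply(seq_len(model@k), function(s) {
    x <- occ[, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(state = s, r = NA_real_, r2 = NA_real_,
                        p = NA_real_, significant = FALSE,
                        direction = NA_character_, degenerate = TRUE))
    a <- pearsonAssociation(x, y)
    data.frame(state = s, r = a$r, r2 = a$r2, p = a$p,
               significant = a$p < alpha,
               direction = if (a$r < 0) "negative" else "positive",
               degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Scan a range of microstate counts
#'
#' Fits one model per k and reports the marker correlation table for each,
#' mirroring the exploratory scan over 5-20 states used to locate the
#' informative clustering.
#'
#' @param topographies pooled windows x channels matrix.
#' @param subjectIds one subject id per window.
#' @param ratios named per-subject ratios (see \code{\link{stateStatistics}}).
#' @param ks integer vector of state counts (default \code{5:20}).
#' @param seed base seed; each k gets a derived seed.
#' @param ... passed on to \code{\link{fitMicrostates}}.
#' @return Named list (one element per k) of \code{list(model, statistics)}.
#' @export
scanMicrostates <- function(topographies, subjectIds, ratios, ks = 5:20,
                            seed = 1L, ...) {
  out <- lapply(ks, function(k) {
    m <- fitMicrostates(topographies, k, seed = .deriveSeed(seed, k),
                        subjectIds = subjectIds, ...)
    list(model = m, statistics = stateStatistics(m, ratios))
  })
  names(out) <- paste0("k", ks)
  out
}
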