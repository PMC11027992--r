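## Feature extraction: turns one preprocessed recording into named features
## (band energies overall and per region, dominant alpha frequency,
## normalized LZ complexity per region and overall, region-pair mutual
## information) and streams a whole cohort into an AbetaFeatureSet, fitting
## the pooled microstate model along the way.

.safeRegion <- function(r) gsub("-", "", r)   # "L-T" -> "LT" in feature names

#' Extract EEG features for one subject
#'
#' @param rec an \linkS4class{EEGRecording} (raw; preprocessing is applied
#'   here unless \code{preprocess = FALSE}).
#' @param bands band table (see \code{\link{defaultBands}}).
#' @param nSegments,segmentLength spectrum averaging parameters.
#' @param l,nBins complexity alphabet size and MI histogram bins.
#' @param windowMs microstate topography window.
#' @param preprocess run \code{\link{preprocessRecording}} first.
#' @param lowcut,highcut,rejectSd preprocessing parameters.
#' @return List: \code{features} (named numeric, \code{eeg:} prefix),
#'   \code{topographies} (windows x channels), \code{spectrumCurve}
#'   (channel-mean power per bin), \code{frequencies}.
#' @export
extractSubjectFeatures <- function(rec, bands = defaultBands(),
                                   nSegments = 20L, segmentLength = 2000L,
                                   l = 2L, nBins = 16L, windowMs = 100,
                                   preprocess = TRUE, lowcut = 0.5,
                                   highcut = 100, rejectSd = 7) {
  stopifnot(is(rec, "EEGRecording"))
  xt <- t(rec@data)
  colnames(xt) <- rec@channelNames
  .extractFeaturesXt(xt, rec@samplingRate, rec@regionMap[rec@channelNames],
                     bands, nSegments, segmentLength, l, nBins, windowMs,
                     preprocess, lowcut, highcut, rejectSd)
}

.extractFeaturesXt <- function(xt, fs, regions, bands = defaultBands(),
                               nSegments = 20L, segmentLength = 2000L,
                               l = 2L, nBins = 16L, windowMs = 100,
                               preprocess = TRUE, lowcut = 0.5,
                               highcut = 100, rejectSd = 7) {
  if (preprocess)
    xt <- .preprocessCore(xt, fs, lowcut, highcut, rejectSd,
                          segmentLength)$xt

  sp <- .spectrumCore(xt, fs, nSegments, segmentLength)
  be <- .bandEnergiesCore(sp$frequencies, sp$power, bands)
  f <- c(stats::setNames(be$energy, paste0("eeg:energy_", names(be$energy))),
         `eeg:energy_total` = be$totalEnergy,
         `eeg:alpha_peak` = be$dominantAlphaFrequency)
  for (r in .REGIONS) {
    sel <- regions == r
    f[paste0("eeg:energy_", names(bands), "_", .safeRegion(r))] <-
      rowMeans(be$perChannel[, sel, drop = FALSE])
  }

  rc <- .regionComplexityCore(xt, regions, l)
  f[paste0("eeg:lz_", .safeRegion(rc$regions$region))] <- rc$regions$mean
  f["eeg:lz_overall"] <- rc$overall$mean

  M <- .miMatrixCore(xt, regions, nBins)
  for (i in seq_along(.REGIONS))
    for (j in i:length(.REGIONS))
      f[paste0("eeg:mi_", .safeRegion(.REGIONS[i]), "_",
               .safeRegion(.REGIONS[j]))] <- M[i, j]

  win <- as.integer(round(windowMs / 1000 * fs))
  tp <- cpp_window_sd(xt, win)
  colnames(tp) <- colnames(xt)

  list(features = f, topographies = tp,
       spectrumCurve = rowMeans(sp$power),
       frequencies = sp$frequencies)
}

.mriFeatures <- function(record, definitions) {
  f <- numeric(0)
  if (!is.null(record@mri)) {
    f <- c(stats::setNames(record@mri, paste0("mri:", names(record@mri))),
           stats::setNames(computeIndices(record@mri, definitions),
                           paste0("mri:", names(definitions))))
  }
  if (!is.null(record@atrophy))
    f <- c(f, stats::setNames(as.numeric(record@atrophy),
                              paste0("mri:gca_", names(record@atrophy))))
  f
}

#' Extract the full multimodal feature set for a cohort
#'
#' Streams through the cohort one subject at a time (recordings are read
#' from \code{eegDir}, taken from the record, or synthesized from the
#' generator recipe attached by \code{\link{generateCohort}}), extracts the
#' EEG features, pools the SD topographies, fits the cohort-level microstate
#' model at \code{k} states, and assembles everything into an
#' \linkS4class{AbetaFeatureSet}. The fitted \linkS4class{MicrostateModel}
#' and per-subject channel-mean spectrum curves are stored in the metadata.
#'
#' @param records named list of \linkS4class{SubjectRecord}.
#' @param eegDir directory of EDF/BrainVision files named by subject id
#'   (optional).
#' @param modalities feature families to assemble and require; subset of
#'   \code{c("eeg", "mri", "scale")}.
#' @param k microstate count for the feature-level model.
#' @param seed seed for the microstate restarts.
#' @param indexFormulas MRI index formula table.
#' @param regionMap montage used when reading EEG files from \code{eegDir};
#'   recordings synthesized from a generator recipe use the montage the
#'   generator was called with.
#' @param requiredModalities modalities a subject must have to enter the
#'   matrix. Default: \code{"eeg"} when EEG is among \code{modalities},
#'   otherwise all requested modalities. Subjects with partial modalities
#'   are thereby retained for modality-specific statistics and excluded
#'   later from joint prediction (see \code{\link{crossValidatePredict}}).
#' @param verbose print per-stage progress.
#' @param ... passed to \code{\link{extractSubjectFeatures}}.
#' @return An \linkS4class{AbetaFeatureSet}.
#' @export
extractCohortFeatures <- function(records, eegDir = NULL,
                                  modalities = c("eeg", "mri", "scale"),
                                  k = 7L, seed = 1L,
                                  indexFormulas = defaultIndexFormulas(),
                                  regionMap = defaultMontage(),
                                  requiredModalities = NULL,
                                  verbose = FALSE, ...) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  gen <- attr(records, "generator")
  extracted <- list()
  topos <- list()
  topoIds <- list()
  curves <- list()
  freqs <- NULL

  for (r in records) {
    id <- r@subjectId
    f <- numeric(0)
    if ("eeg" %in% modalities) {
      rec <- r@eeg
      if (is.null(rec) && !is.null(eegDir)) {
        edf <- file.path(eegDir, paste0(id, ".edf"))
        vhdr <- file.path(eegDir, paste0(id, ".vhdr"))
        if (file.exists(edf)) rec <- readEDF(edf, regionMap)
        else if (file.exists(vhdr)) rec <- readBrainVision(vhdr, regionMap)
      }
      ex <- NULL
      if (!is.null(rec)) {
        ex <- extractSubjectFeatures(rec, ...)
      } else if (!is.null(gen) && isTRUE(gen$withEEG)) {
        ## streaming synthesis: never materializes the EEGRecording
        core <- .synthSubjectXt(r@abetaRatio, gen$config,
                                gen$eegSeeds[[id]], gen$regionMap)
        ex <- .extractFeaturesXt(core$xt, gen$config$samplingRate,
                                 core$regions, ...)
      }
      if (!is.null(ex)) {
        f <- c(f, ex$features)
        topos[[id]] <- ex$topographies
        topoIds[[id]] <- rep(id, nrow(ex$topographies))
        curves[[id]] <- ex$spectrumCurve
        freqs <- ex$frequencies
        if (verbose) message("  extracted EEG features: ", id)
      }
    }
    if ("mri" %in% modalities) f <- c(f, .mriFeatures(r, indexFormulas))
    if ("scale" %in% modalities && !is.null(r@scales))
      f <- c(f, stats::setNames(r@scales, paste0("scale:", names(r@scales))))
    if (length(f)) extracted[[id]] <- f
  }

  model <- NULL
  if (length(topos)) {
    pooled <- do.call(rbind, topos)
    ids <- unlist(topoIds, use.names = FALSE)
    model <- fitMicrostates(pooled, k, seed = seed, subjectIds = ids)
    occ <- occurrenceFrequencies(model)
    for (id in rownames(occ))
      extracted[[id]] <- c(extracted[[id]],
                           stats::setNames(occ[id, ],
                                           paste0("eeg:ms_occ", seq_len(k))))
  }

  if (is.null(requiredModalities))
    requiredModalities <- if ("eeg" %in% modalities) "eeg" else modalities
  fs <- assembleFeatureMatrix(records, extracted,
                              requiredModalities = requiredModalities)
  md <- S4Vectors::metadata(fs)
  md$microstateModel <- model
  if (length(curves))
    md$spectra <- list(frequencies = freqs,
                       curves = do.call(rbind, curves))
  S4Vectors::metadata(fs) <- md
  fs
}
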