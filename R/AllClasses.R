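#' @importFrom S4Vectors metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

## The five scalp regions used throughout: frontal, parietal, left-temporal,
## right-temporal and occipital.
.REGIONS <- c("F", "P", "L-T", "R-T", "O")

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Multi-channel EEG recording
#'
#' Holds a channels x samples matrix in microvolts together with its sampling
#' rate, 10-20 channel labels, and the channel-to-region map used by the
#' regional complexity and mutual-information summaries. Every channel must
#' map to exactly one of the five regions \code{F}, \code{P}, \code{L-T},
#' \code{R-T}, \code{O}.
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames channel labels, one per row of \code{data}.
#' @slot regionMap named character; names are channel labels, values regions.
#' @slot preprocessed logical; has \code{\link{preprocessRecording}} run?
#' @slot badSegments indices of segments rejected during preprocessing.
#'
#' @seealso \code{\link{preprocessRecording}}, \code{\link{averageSpectrum}},
#'   \code{\link{readEDF}}, \code{\link{generateSubjectEEG}}
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channelNames = "character",
    regionMap = "character",
    preprocessed = "logical",
    badSegments = "integer"
  ),
  prototype(preprocessed = FALSE, badSegments = integer(0))
)

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "one channel name per data row required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "duplicated channel names")
  if (!all(object@channelNames %in% names(object@regionMap)))
    msg <- c(msg, "every channel must appear in regionMap")
  if (!all(object@regionMap %in% .REGIONS))
    msg <- c(msg, sprintf("regions must be one of %s",
                          paste(.REGIONS, collapse = ", ")))
  ## cheap non-finite screen: anyNA catches NA/NaN, min/max catch +-Inf
  if (length(object@data) &&
      (anyNA(object@data) || is.infinite(min(object@data)) ||
       is.infinite(max(object@data))))
    msg <- c(msg, "non-finite samples in data")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param samplingRate sampling rate in Hz.
#' @param channelNames channel labels; default taken from rownames.
#' @param regionMap named character mapping channels to the five regions; by
#'   default looked up from \code{\link{defaultMontage}}.
#' @return An \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(data, samplingRate,
                         channelNames = rownames(data),
                         regionMap = defaultMontage()) {
  if (is.null(channelNames))
    stop("channel names are required (rownames of data or channelNames=)")
  rownames(data) <- channelNames
  new("EEGRecording", data = data, samplingRate = as.numeric(samplingRate),
      channelNames = channelNames,
      regionMap = regionMap[channelNames])
}

#' @rdname accessors
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)

#' @rdname accessors
#' @export
setMethod("regionMap", "EEGRecording", function(x) x@regionMap)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate,
              if (object@preprocessed) ", preprocessed" else ""))
  tab <- table(factor(object@regionMap[object@channelNames],
                      levels = .REGIONS))
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  if (length(object@badSegments))
    cat("  rejected segments:", paste(object@badSegments, collapse = ", "),
        "\n")
})

#' Segment-averaged power spectrum
#'
#' Result of \code{\link{averageSpectrum}}: one-sided power per frequency bin
#' and channel, averaged over consecutive non-overlapping segments. Power is
#' scaled so that the sum over all bins of a channel equals that channel's
#' time-domain mean square (discrete Parseval identity).
#'
#' @slot frequencies frequency grid in Hz (uniform, starting at 0).
#' @slot power bins x channels matrix of power (microvolt squared).
#' @slot nSegments number of averaged segments.
#' @slot segmentLength segment length in samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot channelNames channel labels.
#' @export
setClass("EEGSpectrum",
  representation(frequencies = "numeric", power = "matrix",
                 nSegments = "integer", segmentLength = "integer",
                 samplingRate = "numeric", channelNames = "character"))

setValidity("EEGSpectrum", function(object) {
  msg <- character(0)
  if (any(object@power < 0)) msg <- c(msg, "negative power")
  if (length(object@frequencies) != nrow(object@power))
    msg <- c(msg, "frequency grid does not match power rows")
  df <- diff(object@frequencies)
  if (length(df) && max(abs(df - df[1])) > 1e-9 * df[1])
    msg <- c(msg, "frequency grid not uniform")
  if (length(object@frequencies) && object@frequencies[1] < 0)
    msg <- c(msg, "frequency grid must start at >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGSpectrum", function(object) {
  cat(sprintf(
    "EEGSpectrum: %d bins (0-%g Hz, resolution %g Hz) x %d channels, %d segments of %d samples\n",
    nrow(object@power), max(object@frequencies),
    object@samplingRate / object@segmentLength,
    ncol(object@power), object@nSegments, object@segmentLength))
})

#' Band energy profile
#'
#' Energies of the five canonical frequency bands (delta 0.5-3, theta 3-8,
#' alpha 8-12, beta 12-20, gamma 20-40 Hz by default), the total 0.5-40 Hz
#' energy, and the dominant alpha frequency, as computed by
#' \code{\link{bandEnergies}}. Band edges are half-open \code{[low, high)} so
#' the five bands tile the 0.5-40 Hz range exactly.
#'
#' @slot bands named list of \code{c(low, high)} band edges in Hz.
#' @slot energy named numeric, channel-averaged energy per band.
#' @slot perChannel bands x channels energy matrix.
#' @slot totalEnergy channel-averaged total energy over 0.5-40 Hz.
#' @slot dominantAlphaFrequency frequency (Hz) of the most powerful alpha bin
#'   of the channel-mean spectrum; ties broken toward the lower frequency.
#' @export
setClass("BandEnergyProfile",
  representation(bands = "list", energy = "numeric", perChannel = "matrix",
                 totalEnergy = "numeric", dominantAlphaFrequency = "numeric"))

setMethod("show", "BandEnergyProfile", function(object) {
  cat("BandEnergyProfile (channel-averaged, uV^2):\n")
  print(round(object@energy, 4))
  cat(sprintf("  total (0.5-40 Hz): %.4f   dominant alpha: %g Hz\n",
              object@totalEnergy, object@dominantAlphaFrequency))
})

#' Fitted microstate model
#'
#' k cluster-centre topographies of windowed per-channel standard deviations,
#' pooled-window assignments, and per-subject occurrence frequencies.
#' Occurrence rows sum to one.
#'
#' @slot k number of states.
#' @slot centers k x channels matrix of centre topographies.
#' @slot assignments state index of every pooled window.
#' @slot subjectIds subject of every pooled window.
#' @slot occurrence subjects x k matrix of occurrence proportions.
#' @slot totWithinss total within-cluster sum of squares of the kept restart.
#' @slot normalized were topographies L2-normalized before clustering?
#' @slot seed seed used for the restarts.
#' @export
setClass("MicrostateModel",
  representation(k = "integer", centers = "matrix", assignments = "integer",
                 subjectIds = "character", occurrence = "matrix",
                 totWithinss = "numeric", normalized = "logical",
                 seed = "integer"))

setValidity("MicrostateModel", function(object) {
  msg <- character(0)
  if (nrow(object@centers) != object@k)
    msg <- c(msg, "centers must have k rows")
  if (length(object@assignments) != length(object@subjectIds))
    msg <- c(msg, "one subject id per window required")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > object@k))
    msg <- c(msg, "assignments out of 1..k")
  if (nrow(object@occurrence) &&
      max(abs(rowSums(object@occurrence) - 1)) > 1e-8)
    msg <- c(msg, "occurrence rows must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MicrostateModel", function(object) {
  cat(sprintf(
    "MicrostateModel: k = %d states over %d windows from %d subjects (%s topographies)\n",
    object@k, length(object@assignments), nrow(object@occurrence),
    if (object@normalized) "L2-normalized" else "raw-SD"))
  cat(sprintf("  total within-cluster SS: %.4f\n", object@totWithinss))
})

#' One subject of a multimodal cohort
#'
#' Bundles a subject's CSF amyloid-beta 42/40 ratio with whatever modality
#' payloads are available: an EEG recording, the eleven MRI caliper
#' measurements, visual atrophy grades, and scale scores. The group label is
#' derived from the ratio by \code{\link{assignGroups}} and is never set by
#' hand.
#'
#' @slot subjectId opaque identifier, unique within a cohort.
#' @slot abetaRatio CSF amyloid-beta 1-42/1-40 concentration ratio.
#' @slot eeg an \linkS4class{EEGRecording}, or NULL.
#' @slot mri named numeric of linear measurements (mm), or NULL.
#' @slot atrophy named integer of GCA-F style grades 0-3
#'   (frontal/parietal/temporal), or NULL.
#' @slot scales named numeric of scale scores, or NULL.
#' @slot group \code{"positive"}, \code{"negative"} or NA before assignment.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", abetaRatio = "numeric",
                 eeg = "ANY", mri = "numericOrNULL",
                 atrophy = "integerOrNULL", scales = "numericOrNULL",
                 group = "character"),
  prototype(eeg = NULL, mri = NULL, atrophy = NULL, scales = NULL,
            group = NA_character_))

setValidity("SubjectRecord", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty string")
  if (length(object@abetaRatio) != 1L || is.na(object@abetaRatio))
    msg <- c(msg, "abetaRatio must be a single non-missing number")
  else if (object@abetaRatio < 0)
    msg <- c(msg, "abetaRatio must be >= 0")
  if (!is.null(object@eeg) && !is(object@eeg, "EEGRecording"))
    msg <- c(msg, "eeg must be an EEGRecording or NULL")
  if (!object@group %in% c("positive", "negative", NA_character_))
    msg <- c(msg, "group must be positive, negative or NA")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectRecord", function(x) x@subjectId)

#' @rdname accessors
#' @export
setMethod("abetaRatio", "SubjectRecord", function(x) x@abetaRatio)

#' @rdname accessors
#' @export
setMethod("groupLabel", "SubjectRecord", function(x) x@group)

setMethod("show", "SubjectRecord", function(object) {
  mods <- c(if (!is.null(object@eeg)) "eeg",
            if (!is.null(object@mri)) "mri",
            if (!is.null(object@atrophy)) "atrophy",
            if (!is.null(object@scales)) "scales")
  cat(sprintf("SubjectRecord %s: ratio = %.5g, group = %s, modalities: %s\n",
              object@subjectId, object@abetaRatio, object@group,
              if (length(mods)) paste(mods, collapse = "+") else "none"))
})

#' Assembled per-subject feature matrix
#'
#' A \linkS4class{SummarizedExperiment} with features as rows (named with a
#' modality prefix \code{eeg:}, \code{mri:} or \code{scale:}) and subjects as
#' columns. \code{colData} carries the target ratio and group label;
#' \code{rowData} the modality and a degeneracy flag for constant features;
#' \code{metadata} the exclusion list of subjects dropped for missing
#' modalities.
#'
#' @seealso \code{\link{assembleFeatureMatrix}},
#'   \code{\link{crossValidatePredict}}
#' @export
setClass("AbetaFeatureSet", contains = "SummarizedExperiment")

#' @rdname featureset-accessors
#' @export
setMethod("featureMatrix", "AbetaFeatureSet",
          function(x) t(assay(x, "features")))

#' @rdname featureset-accessors
#' @export
setMethod("targetRatio", "AbetaFeatureSet",
          function(x) setNames(colData(x)$abeta_ratio, colnames(x)))

#' @rdname featureset-accessors
#' @export
setMethod("groupLabel", "AbetaFeatureSet",
          function(x) setNames(as.character(colData(x)$group), colnames(x)))

#' @rdname featureset-accessors
#' @export
setMethod("featureModalities", "AbetaFeatureSet",
          function(x) setNames(as.character(rowData(x)$modality), rownames(x)))

setMethod("show", "AbetaFeatureSet", function(object) {
  tab <- table(rowData(object)$modality)
  cat(sprintf("AbetaFeatureSet: %d features x %d subjects (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  ex <- metadata(object)$exclusions
  if (length(ex))
    cat(sprintf("  %d subjects excluded: %s\n", length(ex),
                paste(names(ex), collapse = ", ")))
})
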