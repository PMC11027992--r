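#' Canonical EEG frequency bands
#'
#' Delta 0.5-3, theta 3-8, alpha 8-12, beta 12-20 and gamma 20-40 Hz. Band
#' edges are half-open \code{[low, high)}: 3 Hz belongs to theta, 8 Hz to
#' alpha, 12 Hz to beta and 20 Hz to gamma, so the five bands tile the
#' 0.5-40 Hz range exactly.
#'
#' @return Named list of \code{c(low, high)} pairs in Hz.
#' @export
defaultBands <- function() {
  list(delta = c(0.5, 3), theta = c(3, 8), alpha = c(8, 12),
       beta = c(12, 20), gamma = c(20, 40))
}

## second-order-section matrix for a Butterworth band-pass built as a cascade
## of an order-2 high-pass and an order-2 low-pass (numerically stable at the
## very low normalized corner frequencies involved).
.bandpassSos <- function(lowcut, highcut, fs) {
  hp <- signal::butter(2, lowcut / (fs / 2), type = "high")
  lp <- signal::butter(2, highcut / (fs / 2), type = "low")
  rbind(c(hp$b, hp$a), c(lp$b, lp$a))
}

#' Preprocess an EEG recording
#'
#' Zero-phase Butterworth band-pass filtering (order-2 high-pass plus order-2
#' low-pass sections, run forward and backward), amplitude-threshold rejection
#' of bad segments, and whole-brain average re-referencing of every retained
#' sample. A segment is rejected when any channel exceeds \code{rejectSd}
#' times that channel's standard deviation in absolute amplitude. After
#' re-referencing, the mean across channels is zero at every time point.
#'
#' Amplitude-threshold segment rejection stands in for manual/ICA artifact
#' screening of clinical recordings; recordings cleaned elsewhere can be
#' passed through with \code{rejectSd = Inf}.
#'
#' @param raw an \linkS4class{EEGRecording} with at least two channels.
#' @param lowcut,highcut band-pass corner frequencies in Hz.
#' @param rejectSd rejection threshold as a multiple of the channel SD.
#' @param segmentLength rejection segment length in samples.
#' @return A preprocessed \linkS4class{EEGRecording}; rejected segments are
#'   removed from the data and listed in \code{@badSegments}.
#' @export
preprocessRecording <- function(raw, lowcut = 0.5, highcut = 100,
                                rejectSd = 7, segmentLength = 2000L) {
  stopifnot(is(raw, "EEGRecording"))
  core <- .preprocessCore(t(raw@data), raw@samplingRate, lowcut, highcut,
                          rejectSd, segmentLength)
  out <- raw
  out@data <- t(core$xt)
  out@preprocessed <- TRUE
  out@badSegments <- core$bad
  methods::validObject(out)
  out
}

## samples x channels core used by preprocessRecording and the streaming
## feature extractor (avoids repeated full-matrix transposes)
.preprocessCore <- function(xt, fs, lowcut = 0.5, highcut = 100,
                            rejectSd = 7, segmentLength = 2000L) {
  if (ncol(xt) < 2L) stop("at least two channels required")
  if (highcut >= fs / 2) stop("highcut must be below the Nyquist frequency")
  if (lowcut <= 0 || lowcut >= highcut) stop("need 0 < lowcut < highcut")
  sos <- .bandpassSos(lowcut, highcut, fs)
  padlen <- as.integer(min(nrow(xt) - 1L, round(3 * fs)))
  out <- cpp_preprocess(xt, sos, padlen,
                        if (is.finite(rejectSd)) rejectSd else -1,
                        as.integer(segmentLength))
  colnames(out$xt) <- colnames(xt)
  list(xt = out$xt, bad = as.integer(out$bad))
}

#' Segment-averaged power spectrum
#'
#' Splits each channel into \code{nSegments} consecutive non-overlapping
#' segments of \code{segmentLength} samples, takes the squared-magnitude FFT
#' of every segment (rectangular window by default), and averages across
#' segments. Power is one-sided and normalized so that its sum over all bins
#' equals the time-domain mean square of the analyzed span (Parseval). The
#' frequency resolution is \code{samplingRate / segmentLength}, 0.5 Hz at the
#' defaults.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param nSegments number of segments to average (default 20).
#' @param segmentLength samples per segment (default 2000).
#' @param window \code{"rectangular"} (default) or \code{"hann"}; Hann power
#'   is compensated by the mean squared window so broadband levels match.
#' @return An \linkS4class{EEGSpectrum}.
#' @examples
#' fs <- 1000
#' x <- matrix(sin(2 * pi * 10 * (0:39999) / fs), 1, 40000)
#' rec <- EEGRecording(rbind(x, x), fs, c("O1", "O2"))
#' sp <- averageSpectrum(rec)
#' sp@frequencies[which.max(sp@power[, 1])]   # 10 Hz
#' @export
averageSpectrum <- function(rec, nSegments = 20L, segmentLength = 2000L,
                            window = c("rectangular", "hann")) {
  stopifnot(is(rec, "EEGRecording"))
  core <- .spectrumCore(t(rec@data), rec@samplingRate, nSegments,
                        segmentLength, match.arg(window))
  new("EEGSpectrum", frequencies = core$frequencies, power = core$power,
      nSegments = as.integer(nSegments),
      segmentLength = as.integer(segmentLength),
      samplingRate = rec@samplingRate, channelNames = rec@channelNames)
}

.spectrumCore <- function(xt, fs, nSegments = 20L, segmentLength = 2000L,
                          window = "rectangular") {
  nSegments <- as.integer(nSegments)
  segmentLength <- as.integer(segmentLength)
  if (segmentLength %% 2L != 0L) stop("segmentLength must be even")
  need <- nSegments * segmentLength
  if (nrow(xt) < need)
    stop(sprintf("insufficient data: need %d samples, have %d",
                 need, nrow(xt)))
  nCh <- ncol(xt)
  Y <- matrix(xt[seq_len(need), ], nrow = segmentLength)
  wnorm <- 1
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segmentLength) / segmentLength)
    Y <- Y * w
    wnorm <- mean(w^2)
  }
  P <- cpp_fft_pow(Y) / (segmentLength^2 * wnorm)
  half <- segmentLength %/% 2L
  avg <- vapply(seq_len(nCh), function(c)
    rowMeans(P[, ((c - 1L) * nSegments + 1L):(c * nSegments), drop = FALSE]),
    numeric(segmentLength))
  one <- avg[seq_len(half + 1L), , drop = FALSE]
  if (half > 1L)
    one[2:half, ] <- one[2:half, , drop = FALSE] +
      avg[segmentLength:(segmentLength - half + 2L), , drop = FALSE]
  colnames(one) <- colnames(xt)
  list(frequencies = (0:half) * fs / segmentLength, power = one)
}

#' Band energies and dominant alpha frequency
#'
#' Sums spectral power over the bins whose centre frequency falls in each
#' half-open band \code{[low, high)}, per channel, and reports the
#' channel-averaged energy per band, the total energy over the union of the
#' bands, and the dominant alpha frequency (the most powerful alpha bin of
#' the channel-mean spectrum; ties break toward the lower frequency).
#'
#' @param spec an \linkS4class{EEGSpectrum}.
#' @param bands named list of band edges; see \code{\link{defaultBands}}.
#' @return A \linkS4class{BandEnergyProfile}.
#' @export
bandEnergies <- function(spec, bands = defaultBands()) {
  stopifnot(is(spec, "EEGSpectrum"))
  core <- .bandEnergiesCore(spec@frequencies, spec@power, bands)
  new("BandEnergyProfile", bands = bands, energy = core$energy,
      perChannel = core$perChannel, totalEnergy = core$totalEnergy,
      dominantAlphaFrequency = core$dominantAlphaFrequency)
}

.bandEnergiesCore <- function(f, power, bands = defaultBands()) {
  if (max(vapply(bands, `[`, 0, 2)) > max(f) + 1e-9)
    stop("band definitions exceed the spectrum range")
  perChannel <- matrix(0, length(bands), ncol(power),
                       dimnames = list(names(bands), colnames(power)))
  for (b in seq_along(bands)) {
    sel <- f >= bands[[b]][1] & f < bands[[b]][2]
    if (!any(sel)) stop("band '", names(bands)[b], "' contains no bins")
    perChannel[b, ] <- colSums(power[sel, , drop = FALSE])
  }
  lo <- min(vapply(bands, `[`, 0, 1))
  hi <- max(vapply(bands, `[`, 0, 2))
  total <- mean(colSums(power[f >= lo & f < hi, , drop = FALSE]))

  if (!"alpha" %in% names(bands))
    stop("band table must include an 'alpha' band")
  meanPow <- rowMeans(power)
  aSel <- which(f >= bands$alpha[1] & f < bands$alpha[2])
  list(energy = stats::setNames(rowMeans(perChannel), names(bands)),
       perChannel = perChannel, totalEnergy = total,
       dominantAlphaFrequency = f[aSel[which.max(meanPow[aSel])]])
}
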