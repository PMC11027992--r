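## European Data Format (EDF) input/output.
##
## EDF stores each channel as 16-bit integers with a per-channel linear map
## between the digital range and an ASCII-encoded physical range. The codec
## below always scales with the physical limits as they are *written* (8-char
## ASCII), so write -> read round-trips are exact up to the 16-bit
## quantization step and byte-identical across runs.

.edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

## format a number into at most 8 ASCII characters, round-trippable
.edfNum8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " into 8 characters")
}

#' Write an EEG recording to an EDF file
#'
#' Plain EDF (not EDF+), one-second data records, 16-bit samples scaled to
#' each channel's physical range. The sample count must be a whole number of
#' seconds; a trailing partial second is dropped with a warning.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @param patientId,recordingId free-text EDF header fields.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readEDF}}
#' @export
writeEDF <- function(rec, path, patientId = "X", recordingId = "synthetic") {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@samplingRate
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(fs)
  x <- rec@data
  nCh <- nrow(x)
  nRec <- ncol(x) %/% fs
  if (nRec < 1L) stop("recording shorter than one EDF record (1 s)")
  if (ncol(x) %% fs != 0L) {
    warning("dropping trailing partial second for EDF export")
    x <- x[, seq_len(nRec * fs), drop = FALSE]
  }

  pminS <- pmaxS <- character(nCh)
  dig <- matrix(0L, nCh, ncol(x))
  for (ch in seq_len(nCh)) {
    lo <- min(x[ch, ]); hi <- max(x[ch, ])
    if (hi <= lo) hi <- lo + 1
    pminS[ch] <- .edfNum8(lo); pmaxS[ch] <- .edfNum8(hi)
    lo <- as.numeric(pminS[ch]); hi <- as.numeric(pmaxS[ch])
    d <- round((x[ch, ] - lo) / (hi - lo) * 65535 - 32768)
    dig[ch, ] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfPad("0", 8), .edfPad(patientId, 80), .edfPad(recordingId, 80),
    .edfPad("01.01.24", 8), .edfPad("00.00.00", 8),
    .edfPad(256L * (nCh + 1L), 8), .edfPad("", 44),
    .edfPad(nRec, 8), .edfPad("1", 8), .edfPad(nCh, 4),
    paste(vapply(rec@channelNames, .edfPad, "", width = 16), collapse = ""),
    paste(rep(.edfPad("", 80), nCh), collapse = ""),
    paste(rep(.edfPad("uV", 8), nCh), collapse = ""),
    paste(vapply(pminS, .edfPad, "", width = 8), collapse = ""),
    paste(vapply(pmaxS, .edfPad, "", width = 8), collapse = ""),
    paste(rep(.edfPad("-32768", 8), nCh), collapse = ""),
    paste(rep(.edfPad("32767", 8), nCh), collapse = ""),
    paste(rep(.edfPad("", 80), nCh), collapse = ""),
    paste(rep(.edfPad(fs, 8), nCh), collapse = ""),
    paste(rep(.edfPad("", 32), nCh), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  ## record-major, signal-contiguous layout
  arr <- aperm(array(dig, dim = c(nCh, fs, nRec)), c(2L, 1L, 3L))
  writeBin(as.integer(arr), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Supports plain continuous EDF with a common sampling rate across signals.
#' Channels absent from \code{regionMap} are dropped with a warning (e.g.
#' non-EEG auxiliary signals).
#'
#' @param path EDF file path.
#' @param regionMap named character channel-to-region map.
#' @return An \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, regionMap = defaultMontage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  rd(8); rd(44)                           # header bytes, reserved
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(nCh), function(i) trimws(rd(w)), "")
  labels <- fld(16)
  fld(80); fld(8)                         # transducer, dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))               # samples per record
  fld(32)
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across EDF signals are not supported")
  fs <- spr[1] / recDur
  raw <- readBin(con, integer(), n = nCh * spr[1] * nRec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != nCh * spr[1] * nRec)
    stop("EDF data shorter than header declares")
  arr <- aperm(array(raw, dim = c(spr[1], nCh, nRec)), c(2L, 1L, 3L))
  x <- matrix(as.numeric(arr), nCh, spr[1] * nRec)
  scale <- (pmax - pmin) / (dmax - dmin)
  x <- x * scale + (pmin - dmin * scale)
  keep <- labels %in% names(regionMap)
  if (!all(keep)) {
    warning("dropping channels without region assignment: ",
            paste(labels[!keep], collapse = ", "))
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  rownames(x) <- labels
  EEGRecording(x, fs, labels, regionMap)
}
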