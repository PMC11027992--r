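## BrainVision (.vhdr/.eeg/.vmrk) reader. The header is an INI-style text
## file; data may be binary (IEEE float32 or int16 with per-channel
## resolution) or ASCII, multiplexed (rows = time points) or vectorized
## (rows = channels).

.bvParseIni <- function(lines) {
  sec <- NULL
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character(0)
    } else if (!is.null(sec) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[sec]][key] <- val
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' Reads the \code{.vhdr} header plus its data file. Binary
#' \code{IEEE_FLOAT_32} and \code{INT_16} formats and ASCII data are
#' supported, in both multiplexed and vectorized orientation. Per-channel
#' resolutions from the header are applied, yielding microvolts.
#'
#' @param vhdrPath path to the \code{.vhdr} header file.
#' @param regionMap named character channel-to-region map.
#' @return An \linkS4class{EEGRecording}.
#' @export
readBrainVision <- function(vhdrPath, regionMap = defaultMontage()) {
  ini <- .bvParseIni(readLines(vhdrPath, warn = FALSE))
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdrPath)
  nCh <- as.integer(ci["NumberOfChannels"])
  fs <- 1e6 / as.numeric(ci["SamplingInterval"])
  orient <- toupper(ci["DataOrientation"])
  fmt <- toupper(ci["DataFormat"])
  dataPath <- file.path(dirname(vhdrPath), ci["DataFile"])
  if (!file.exists(dataPath)) stop("data file not found: ", dataPath)

  chinfo <- ini[["Channel Infos"]]
  labels <- character(nCh)
  res <- rep(1, nCh)
  for (i in seq_len(nCh)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }

  if (fmt == "BINARY") {
    bfmt <- toupper(ini[["Binary Infos"]]["BinaryFormat"])
    sz <- file.size(dataPath)
    con <- file(dataPath, "rb")
    on.exit(close(con))
    if (bfmt == "IEEE_FLOAT_32") {
      v <- readBin(con, numeric(), n = sz %/% 4, size = 4L, endian = "little")
    } else if (bfmt == "INT_16") {
      v <- readBin(con, integer(), n = sz %/% 2, size = 2L, signed = TRUE,
                   endian = "little")
    } else stop("unsupported BinaryFormat: ", bfmt)
    nSamp <- length(v) %/% nCh
    v <- v[seq_len(nSamp * nCh)]
    x <- if (orient == "MULTIPLEXED") t(matrix(v, nCh, nSamp))
         else matrix(v, nSamp, nCh)
  } else if (fmt == "ASCII") {
    skipLines <- 0L
    ai <- ini[["ASCII Infos"]]
    if (!is.null(ai) && !is.na(ai["SkipLines"]))
      skipLines <- as.integer(ai["SkipLines"])
    tab <- utils::read.table(dataPath, skip = skipLines)
    x <- as.matrix(tab)
    if (orient == "VECTORIZED") x <- t(x)
  } else stop("unsupported DataFormat: ", fmt)

  x <- t(x) * res                          # channels x samples, scaled
  dimnames(x) <- list(labels, NULL)
  keep <- labels %in% names(regionMap)
  if (!all(keep)) {
    warning("dropping channels without region assignment: ",
            paste(labels[!keep], collapse = ", "))
    x <- x[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  EEGRecording(x, fs, labels, regionMap)
}

#' Write a BrainVision ASCII recording
#'
#' Minimal vectorized-ASCII writer, chiefly useful for building small
#' plain-text fixtures and for interoperability checks against
#' \code{\link{readBrainVision}}.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param basePath path without extension; \code{.vhdr} and \code{.dat} are
#'   created next to each other.
#' @return The \code{.vhdr} path, invisibly.
#' @export
writeBrainVisionAscii <- function(rec, basePath) {
  stopifnot(is(rec, "EEGRecording"))
  vhdr <- paste0(basePath, ".vhdr")
  dat <- paste0(basePath, ".dat")
  nCh <- nrow(rec@data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(dat)),
    "DataFormat=ASCII",
    "DataOrientation=VECTORIZED",
    paste0("NumberOfChannels=", nCh),
    paste0("SamplingInterval=", format(1e6 / rec@samplingRate, digits = 12)),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nCh), rec@channelNames))
  writeLines(hdr, vhdr)
  utils::write.table(format(rec@data, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     dat, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(vhdr)
}
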