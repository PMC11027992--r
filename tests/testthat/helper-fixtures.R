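## Shared fixtures: small montages, synthetic recordings, and an independent
## brute-force LZ76 oracle used to validate the fast parser.

## ten-channel montage covering every region twice (fast unit tests)
tinyMontage <- function() {
  c(Fp1 = "F", Fp2 = "F", C3 = "P", C4 = "P", T7 = "L-T", TP7 = "L-T",
    T8 = "R-T", TP8 = "R-T", O1 = "O", O2 = "O")
}

## standard 19-channel clinical montage shipped with the package
montage19 <- function() {
  defaultMontage(system.file("extdata", "montage19.csv", package = "AbetaMM"))
}

noiseRecording <- function(nCh = 10, nSamp = 4000, fs = 1000,
                           map = tinyMontage(), sd = 1) {
  x <- matrix(rnorm(nCh * nSamp, 0, sd), nCh, nSamp)
  EEGRecording(x, fs, names(map)[seq_len(nCh)], map)
}

## brute-force LZ76 phrase count: the next phrase starting at i is the
## shortest s[i..j] that is not a substring of s[1..j-1]; the trailing
## reproducible phrase counts. Implemented with plain substring search,
## independently of the package's suffix-automaton parser.
lzOracle <- function(symbols) {
  s <- paste(symbols, collapse = "")
  n <- nchar(s)
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n &&
           grepl(substr(s, i, j), substr(s, 1, j - 1), fixed = TRUE))
      j <- j + 1L
    count <- count + 1L
    i <- j + 1L
  }
  count
}

## all strings of given length over 0..(l-1), as rows of a matrix
allStrings <- function(len, l) {
  as.matrix(do.call(expand.grid, rep(list(0:(l - 1)), len)))
}

## minimal cohort CSV on disk; returns its path
writeTinyCohortCsv <- function(path, ratios = c(0.05, 0.2, 0.1),
                               withMri = TRUE, withScales = TRUE) {
  n <- length(ratios)
  tab <- data.frame(subject_id = sprintf("T%02d", seq_len(n)),
                    abeta_ratio = ratios)
  if (withMri) {
    for (f in c("A", "B", "E", "F", "J", "H", "O", "P", "a", "b", "c"))
      tab[[paste0("mri_", f)]] <- switch(f,
        A = 130 + seq_len(n), B = 170 + seq_len(n), E = 32 + seq_len(n),
        F = 15 + seq_len(n), J = 26 + seq_len(n), H = 5 + seq_len(n),
        O = 4 + seq_len(n), P = 11 + seq_len(n), 10 + seq_len(n))
    tab$gca_frontal <- rep_len(0:3, n)
    tab$gca_parietal <- rep_len(c(1L, 2L), n)
    tab$gca_temporal <- rep_len(c(0L, 2L), n)
  }
  if (withScales) tab$scale_mmse <- 30 - seq_len(n)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  path
}
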