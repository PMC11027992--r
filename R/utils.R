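#' @importFrom Rcpp evalCpp
#' @useDynLib AbetaMM, .registration = TRUE
NULL

## Derive a stream-specific seed from a base seed, kept inside 32-bit range.
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper)
    stop(sprintf("%s must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

## L2-normalize matrix rows; zero rows are left untouched.
.rowNormalize <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nz <- nrm > 0
  x[nz, ] <- x[nz, , drop = FALSE] / nrm[nz]
  x
}
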