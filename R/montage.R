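#' Default 64-channel 10-20 montage
#'
#' Channel-to-region map for a 64-channel extended 10-20 montage, read from an
#' editable CSV shipped with the package (\code{extdata/montage64.csv}).
#' Frontal-pole/anterior-frontal/frontal/frontocentral channels map to
#' \code{F}; central, centroparietal and parietal channels to \code{P};
#' the temporal chains (FT7/T7/TP7 side and FT8/T8/TP8 side, plus the 9/10
#' positions) to \code{L-T} and \code{R-T}; parieto-occipital and occipital
#' channels to \code{O}. Midline channels follow their letter prefix.
#'
#' @param file path to a two-column CSV (\code{channel}, \code{region});
#'   defaults to the shipped map.
#' @return Named character vector mapping channel labels to regions.
#' @examples
#' table(defaultMontage())
#' @export
defaultMontage <- function(file = system.file("extdata", "montage64.csv",
                                              package = "AbetaMM")) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("channel", "region") %in% names(tab)))
    stop("montage file needs columns 'channel' and 'region'")
  bad <- setdiff(unique(tab$region), .REGIONS)
  if (length(bad))
    stop("unknown regions in montage file: ", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$channel))
    stop("duplicated channels in montage file")
  stats::setNames(tab$region, tab$channel)
}
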