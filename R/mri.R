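## Linear atrophy indices from caliper measurements on structural MRI.
## The eleven measurements (mm): A maximal transversal intracranial width,
## B maximal longitudinal intracranial width, E maximal frontal horn width,
## F minimal inter-caudate distance, J choroid plexuses distance, H maximal
## third-ventricle width, O temporal horn width, P suprasellar cistern width,
## a/b/c corpus callosum genu/body/splenium. The corpus callosum values are
## carried as raw features; no default index uses them.

#' Default index formula table
#'
#' Reads the editable formula table (\code{extdata/index_formulas.csv})
#' mapping each derived index to an arithmetic expression over the
#' measurement letters. Defaults follow standard radiology conventions:
#' Evans ratio E/A, bicaudate ratio F/A, Huckman number E+F (mm), Huckman
#' ratio (E+F)/A, third ventricular ratio H/A, ventricle index J/F, temporal
#' horn ratio O/A, suprasellar cistern ratio P/A. Replace the file (or pass
#' another) to drop in alternative definitions without code changes.
#'
#' @param file path to a \code{name,formula} CSV.
#' @return Named character vector of formulas.
#' @export
defaultIndexFormulas <- function(file = system.file("extdata",
                                                    "index_formulas.csv",
                                                    package = "AbetaMM")) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(tab)))
    stop("formula table needs columns 'name' and 'formula'")
  if (anyDuplicated(tab$name))
    stop("each index name must map to exactly one formula")
  for (i in seq_len(nrow(tab))) {
    vars <- all.vars(str2lang(tab$formula[i]))
    bad <- setdiff(vars, .MRI_FIELDS)
    if (length(bad))
      stop("formula '", tab$name[i], "' references unknown measurement(s): ",
           paste(bad, collapse = ", "))
  }
  stats::setNames(tab$formula, tab$name)
}

#' Validate linear measurements
#'
#' All values must be positive and the ventricular widths must be smaller
#' than the intracranial width (E < A, F < A, H < A).
#'
#' @param m named numeric over the eleven measurement letters.
#' @return \code{m}, invisibly, or an error naming the offending field.
#' @export
linearMeasurements <- function(m) {
  missing <- setdiff(.MRI_FIELDS, names(m))
  if (length(missing))
    stop("missing measurement(s): ", paste(missing, collapse = ", "))
  m <- m[.MRI_FIELDS]
  bad <- names(m)[!is.finite(m) | m <= 0]
  if (length(bad))
    stop("non-positive measurement: ", paste(bad, collapse = ", "))
  for (f in c("E", "F", "H"))
    if (m[[f]] >= m[["A"]])
      stop(f, " must be smaller than the intracranial width A")
  invisible(m)
}

#' Derived linear atrophy indices
#'
#' Evaluates the formula table on one subject's measurements.
#'
#' @param m named numeric over the measurement letters A, B, E, F, J, H, O,
#'   P, a, b, c (mm).
#' @param definitions formula table, see \code{\link{defaultIndexFormulas}}.
#' @return Named numeric of derived indices (dimensionless except the
#'   Huckman number, mm).
#' @examples
#' m <- c(A = 120, B = 160, E = 30, F = 18, J = 28, H = 6, O = 5, P = 12,
#'        a = 11, b = 6, c = 11)
#' computeIndices(m)[["evans_ratio"]]   # 0.25
#' @export
computeIndices <- function(m, definitions = defaultIndexFormulas()) {
  m <- linearMeasurements(m)
  env <- list2env(as.list(m))
  vapply(definitions, function(f) eval(str2lang(f), env), 0)
}

#' Validate visual atrophy grades
#'
#' Grades follow the 0-3 visual rating convention (0 no cortical atrophy,
#' 1 sulcal dilatation, 2 gyral volume loss, 3 end-stage knife-blade
#' atrophy), one grade per lobe.
#'
#' @param g named integer vector over \code{frontal}, \code{parietal},
#'   \code{temporal}.
#' @param subjectId optional id used in error messages.
#' @return \code{g}, invisibly.
#' @export
validateGrades <- function(g, subjectId = NULL) {
  missing <- setdiff(.GCA_LOBES, names(g))
  if (length(missing))
    stop("missing grade(s): ", paste(missing, collapse = ", "))
  g <- g[.GCA_LOBES]
  bad <- names(g)[is.na(g) | g != as.integer(g) | g < 0L | g > 3L]
  if (length(bad))
    stop("grade out of range 0-3 for lobe ", paste(bad, collapse = ", "),
         if (!is.null(subjectId)) paste0(" (subject ", subjectId, ")") else "")
  invisible(stats::setNames(as.integer(g), .GCA_LOBES))
}

#' Correlation between atrophy grades and the CSF marker
#'
#' Per-lobe Pearson correlation between the visual atrophy grade and the
#' amyloid-beta 42/40 ratio across subjects, with the least-squares line for
#' plotting. Atrophy is expected to decrease as the ratio increases, so the
#' correlation sign is typically negative; both r and R-squared are reported.
#'
#' @param records list of \linkS4class{SubjectRecord}; only subjects with
#'   grades are used.
#' @return data.frame: lobe, n, r, r2, p, slope, intercept, degenerate.
#' @export
atrophyMarkerCorrelation <- function(records) {
  has <- vapply(records, function(r) !is.null(r@atrophy), TRUE)
  recs <- records[has]
  if (length(recs) < 3L)
    stop("at least three subjects with atrophy grades required")
  ratio <- vapply(recs, abetaRatio, 0)
  out <- lapply(.GCA_LOBES, function(lobe) {
    g <- vapply(recs, function(r) as.numeric(r@atrophy[[lobe]]), 0)
    if (stats::sd(g) == 0)
      return(data.frame(lobe = lobe, n = length(g), r = NA_real_,
                        r2 = NA_real_, p = NA_real_, slope = NA_real_,
                        intercept = NA_real_, degenerate = TRUE))
    a <- pearsonAssociation(ratio, g)
    data.frame(lobe = lobe, n = length(g), r = a$r, r2 = a$r2, p = a$p,
               slope = a$slope, intercept = a$intercept, degenerate = FALSE)
  })
  do.call(rbind, out)
}
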