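## Cohort table dialect: CSV (or TSV by extension) with header, UTF-8, "."
## decimal, empty cells for missing values. Mandatory columns: subject_id,
## abeta_ratio. Optional: the eleven caliper measurements mri_A..mri_c, the
## three visual atrophy grades gca_frontal/gca_parietal/gca_temporal, and any
## number of scale_* columns. EEG files live in a directory, named
## <subject_id>.edf or <subject_id>.vhdr.

.MRI_FIELDS <- c("A", "B", "E", "F", "J", "H", "O", "P", "a", "b", "c")
.GCA_LOBES <- c("frontal", "parietal", "temporal")

.readTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
}

.num <- function(x) suppressWarnings(as.numeric(x))

#' Load a multimodal cohort
#'
#' Reads the per-subject cohort table and, when \code{eegDir} is given, the
#' EEG recording of every subject that has one on disk. Modalities are
#' attached only where the corresponding columns/files are complete.
#'
#' @param cohortTablePath CSV/TSV with columns \code{subject_id},
#'   \code{abeta_ratio} and optional \code{mri_*}, \code{gca_*},
#'   \code{scale_*} columns.
#' @param eegDir directory of EDF/BrainVision files named by subject id, or
#'   NULL to skip EEG loading.
#' @param regionMap channel-to-region map used for EEG files.
#' @param threshold amyloid-positivity threshold passed to
#'   \code{\link{assignGroups}}.
#' @return Named list of \linkS4class{SubjectRecord}, one per table row, with
#'   groups assigned.
#' @export
loadCohort <- function(cohortTablePath, eegDir = NULL,
                       regionMap = defaultMontage(), threshold = 0.1) {
  tab <- .readTable(cohortTablePath)
  for (col in c("subject_id", "abeta_ratio"))
    if (!col %in% names(tab))
      stop("cohort table lacks mandatory column '", col, "'")
  ids <- tab$subject_id
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ratio <- .num(tab$abeta_ratio)
  bad <- is.na(ratio)
  if (any(bad))
    stop("unparseable abeta_ratio for subject(s): ",
         paste(ids[bad], collapse = ", "))

  mriCols <- paste0("mri_", .MRI_FIELDS)
  gcaCols <- paste0("gca_", .GCA_LOBES)
  scaleCols <- grep("^scale_", names(tab), value = TRUE)

  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    mri <- NULL
    if (all(mriCols %in% names(tab))) {
      v <- .num(unlist(tab[i, mriCols]))
      if (!anyNA(v)) mri <- stats::setNames(v, .MRI_FIELDS)
    }
    atr <- NULL
    if (all(gcaCols %in% names(tab))) {
      v <- .num(unlist(tab[i, gcaCols]))
      if (!anyNA(v)) {
        atr <- stats::setNames(as.integer(v), .GCA_LOBES)
        validateGrades(atr, subjectId = ids[i])
      }
    }
    sc <- NULL
    if (length(scaleCols)) {
      v <- .num(unlist(tab[i, scaleCols]))
      keep <- !is.na(v)
      if (any(keep))
        sc <- stats::setNames(v[keep], sub("^scale_", "", scaleCols)[keep])
    }
    eeg <- NULL
    if (!is.null(eegDir)) {
      edf <- file.path(eegDir, paste0(ids[i], ".edf"))
      vhdr <- file.path(eegDir, paste0(ids[i], ".vhdr"))
      if (file.exists(edf)) eeg <- readEDF(edf, regionMap)
      else if (file.exists(vhdr)) eeg <- readBrainVision(vhdr, regionMap)
    }
    records[[i]] <- new("SubjectRecord", subjectId = ids[i],
                        abetaRatio = ratio[i], eeg = eeg, mri = mri,
                        atrophy = atr, scales = sc)
  }
  names(records) <- ids
  assignGroups(records, threshold)
}

#' Write a cohort table (and optionally its EEG files)
#'
#' Inverse of \code{\link{loadCohort}}: the table round-trips field for field
#' (numbers are written with 17 significant digits).
#'
#' @param records list of \linkS4class{SubjectRecord}.
#' @param path output CSV path.
#' @param eegDir directory to write one EDF per subject with EEG, or NULL.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(records, path, eegDir = NULL) {
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17,
                                                  format = "g"))
  scaleNames <- sort(unique(unlist(lapply(records, function(r)
    names(r@scales)))))
  rows <- lapply(records, function(r) {
    out <- c(subject_id = r@subjectId, abeta_ratio = fmt(r@abetaRatio))
    m <- stats::setNames(rep(NA_real_, length(.MRI_FIELDS)), .MRI_FIELDS)
    if (!is.null(r@mri)) m[names(r@mri)] <- r@mri
    out <- c(out, stats::setNames(fmt(m), paste0("mri_", .MRI_FIELDS)))
    g <- stats::setNames(rep(NA_real_, 3), .GCA_LOBES)
    if (!is.null(r@atrophy)) g[names(r@atrophy)] <- r@atrophy
    out <- c(out, stats::setNames(fmt(g), paste0("gca_", .GCA_LOBES)))
    if (length(scaleNames)) {
      s <- stats::setNames(rep(NA_real_, length(scaleNames)), scaleNames)
      if (!is.null(r@scales)) s[names(r@scales)] <- r@scales
      out <- c(out, stats::setNames(fmt(s), paste0("scale_", scaleNames)))
    }
    out
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(eegDir)) {
    dir.create(eegDir, showWarnings = FALSE, recursive = TRUE)
    for (r in records)
      if (!is.null(r@eeg))
        writeEDF(r@eeg, file.path(eegDir, paste0(r@subjectId, ".edf")))
  }
  invisible(path)
}

#' Assign amyloid positivity groups
#'
#' A subject is \emph{positive} (amyloid-deposition-like) when the CSF
#' amyloid-beta 42/40 ratio is less than or equal to the threshold, and
#' \emph{negative} otherwise. The boundary value is positive. The partition
#' is exhaustive and disjoint, and raising the threshold can only move
#' subjects from negative to positive.
#'
#' @param records list of \linkS4class{SubjectRecord}.
#' @param threshold positivity threshold on the ratio (default 0.1).
#' @return The records with the \code{group} slot set.
#' @examples
#' r <- new("SubjectRecord", subjectId = "s1", abetaRatio = 0.1)
#' groupLabel(assignGroups(list(r))[[1]])   # boundary is positive
#' @export
assignGroups <- function(records, threshold = 0.1) {
  .assertScalarNumber(threshold, "threshold", lower = 0)
  ratios <- vapply(records, abetaRatio, 0)
  if (any(ratios < 0)) stop("negative abeta_ratio encountered")
  lapply(records, function(r) {
    r@group <- if (r@abetaRatio <= threshold) "positive" else "negative"
    r
  })
}

#' Assemble the per-subject feature matrix
#'
#' Combines per-subject named feature vectors (prefixed \code{eeg:},
#' \code{mri:} or \code{scale:}) into an \linkS4class{AbetaFeatureSet}.
#' Column (feature) order is sorted by name, so assembly is invariant to the
#' order of the input records up to row order. Subjects lacking a required
#' modality are dropped and reported in \code{metadata(x)$exclusions};
#' remaining missing values stay explicit \code{NA}s. Constant feature
#' columns are flagged degenerate in \code{rowData}.
#'
#' @param records list of \linkS4class{SubjectRecord} (groups assigned).
#' @param extracted named list: subject id -> named numeric feature vector.
#' @param requiredModalities modalities a subject must have to be kept;
#'   default: every modality observed anywhere in \code{extracted}.
#' @return An \linkS4class{AbetaFeatureSet} (features x subjects).
#' @export
assembleFeatureMatrix <- function(records, extracted,
                                  requiredModalities = NULL) {
  ids <- vapply(records, subjectId, "")
  unknown <- setdiff(names(extracted), ids)
  if (length(unknown))
    stop("extracted features for subjects absent from records: ",
         paste(unknown, collapse = ", "))
  allNames <- sort(unique(unlist(lapply(extracted, names))))
  if (!length(allNames)) stop("no features to assemble")
  modality <- sub(":.*$", "", allNames)
  if (!all(grepl("^(eeg|mri|scale):", allNames)))
    stop("feature names must carry an eeg:/mri:/scale: modality prefix")
  stripped <- sub("^[^:]+:", "", allNames)
  dup <- stripped[duplicated(stripped)]
  if (length(dup))
    stop("feature name collision across modalities: ",
         paste(unique(dup), collapse = ", "))
  if (is.null(requiredModalities)) requiredModalities <- unique(modality)

  subjects <- names(extracted)
  X <- matrix(NA_real_, length(subjects), length(allNames),
              dimnames = list(subjects, allNames))
  for (s in subjects) {
    v <- extracted[[s]]
    if (anyDuplicated(names(v)))
      stop("duplicated feature names for subject ", s)
    X[s, names(v)] <- v
  }

  exclusions <- character(0)
  keep <- rep(TRUE, length(subjects))
  for (i in seq_along(subjects)) {
    missingMod <- vapply(requiredModalities, function(m) {
      cols <- modality == m
      any(is.na(X[i, cols]))
    }, TRUE)
    if (any(missingMod)) {
      keep[i] <- FALSE
      exclusions[subjects[i]] <-
        paste("missing modality:",
              paste(requiredModalities[missingMod], collapse = "+"))
    }
  }
  if (!any(keep)) stop("all subjects excluded during assembly")
  if (length(exclusions))
    message(length(exclusions), " subject(s) excluded: ",
            paste(names(exclusions), collapse = ", "))
  X <- X[keep, , drop = FALSE]

  recById <- stats::setNames(records, ids)
  ratios <- vapply(rownames(X), function(s) abetaRatio(recById[[s]]), 0)
  groups <- vapply(rownames(X), function(s) groupLabel(recById[[s]]), "")
  rng <- apply(X, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) 0 else max(col) - min(col)
  })
  se <- SummarizedExperiment(
    assays = list(features = t(X)),
    rowData = S4Vectors::DataFrame(modality = modality,
                                   degenerate = rng == 0,
                                   row.names = allNames),
    colData = S4Vectors::DataFrame(abeta_ratio = ratios, group = groups,
                                   row.names = rownames(X)))
  S4Vectors::metadata(se) <- list(exclusions = exclusions,
                                  n_features = length(allNames),
                                  required_modalities = requiredModalities)
  new("AbetaFeatureSet", se)
}

#' Export a feature set as CSV plus a JSON provenance sidecar
#'
#' @param fs an \linkS4class{AbetaFeatureSet}.
#' @param path CSV path; the sidecar is written to \code{<path>.json}.
#' @param extra named list merged into the sidecar (e.g. seeds, parameters).
#' @return \code{path}, invisibly.
#' @export
exportFeatures <- function(fs, path, extra = list()) {
  X <- featureMatrix(fs)
  tab <- data.frame(subject_id = rownames(X),
                    abeta_ratio = targetRatio(fs),
                    group = groupLabel(fs), X, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  side <- c(list(
    package = "AbetaMM",
    version = as.character(utils::packageVersion("AbetaMM")),
    n_subjects = nrow(X),
    n_features = ncol(X),
    modalities = as.list(table(featureModalities(fs))),
    exclusions = as.list(S4Vectors::metadata(fs)$exclusions)), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
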