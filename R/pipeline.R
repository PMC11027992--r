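#' Read a run configuration
#'
#' Loads a YAML configuration and merges it over the packaged defaults
#' (\code{extdata/default_config.yaml}): positivity threshold, preprocessing
#' band, spectrum segmentation, complexity/MI parameters, microstate window
#' and k, regressor hyperparameters, modality switches and the master seed.
#'
#' @param path YAML file, or NULL for the defaults.
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  def <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                     package = "AbetaMM"))
  if (is.null(path)) return(def)
  usr <- yaml::read_yaml(path)
  merge <- function(a, b) {
    for (k in names(b))
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) merge(a[[k]], b[[k]])
                else b[[k]]
    a
  }
  merge(def, usr)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[3]
  out <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name, proc.time()[3] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> load -> extract -> group statistics ->
#' predict -> report into one seeded, reproducible run. Outputs are plain
#' CSV/JSON files under \code{outDir}; every output file's MD5 hash is
#' recorded in \code{manifest.json}, and a rerun with the same configuration
#' and data reproduces the hashes bit for bit.
#'
#' When \code{cohortTable} is NULL a synthetic cohort is generated (written
#' under \code{outDir/data} so the run exercises the same file formats real
#' data would use). With real data, point \code{cohortTable}/\code{eegDir}
#' at the cohort CSV and EEG directory. Cohorts without MRI columns degrade
#' gracefully to an EEG-only run with a logged notice.
#'
#' @param outDir output directory (created if needed).
#' @param config configuration list or YAML path (see
#'   \code{\link{readRunConfig}}).
#' @param cohortTable optional cohort CSV; NULL simulates.
#' @param eegDir optional EEG directory accompanying \code{cohortTable}.
#' @param seed overrides the config seed.
#' @param writeEEG write the simulated EEG as EDF files and re-read them
#'   (default TRUE); FALSE streams recordings in memory, which is faster
#'   and skips the \code{outDir/data} tree.
#' @return Invisibly, a list: paths of the outputs, metrics of the
#'   prediction stage, the manifest.
#' @export
runPipeline <- function(outDir, config = NULL, cohortTable = NULL,
                        eegDir = NULL, seed = NULL, writeEEG = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  if (is.null(config)) config <- readRunConfig()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  modalities <- intersect(unlist(config$modalities),
                          c("eeg", "mri", "scale"))

  ## --- simulate / load -----------------------------------------------------
  regionMap <- if (!is.null(config$cohort$montage))
    defaultMontage(config$cohort$montage) else defaultMontage()
  if (is.null(cohortTable)) {
    nSub <- config$cohort$n_subjects %||% 82L
    cohortCfg <- do.call(effectConfig, c(
      list(nSubjects = nSub,
           mriMissing = config$cohort$mri_missing %||%
             as.integer(round(nSub * 5 / 82)),
           threshold = config$threshold, seed = config$seed)))
    if (writeEEG) {
      records <- .stage("simulate", {
        generateCohort(cohortCfg, dir = file.path(outDir, "data"),
                       regionMap = regionMap)
      })
      records <- .stage("load", {
        r <- loadCohort(attr(records, "paths")$cohortTable,
                        regionMap = regionMap, threshold = config$threshold)
        r
      })
      eegDir <- file.path(outDir, "data", "eeg")
    } else {
      records <- .stage("simulate",
                        generateCohort(cohortCfg, regionMap = regionMap))
    }
  } else {
    records <- .stage("load",
                      loadCohort(cohortTable, regionMap = regionMap,
                                 threshold = config$threshold))
  }

  ## graceful degradation when a modality is absent from the data
  hasMri <- any(vapply(records, function(r) !is.null(r@mri) ||
                         !is.null(r@atrophy), TRUE))
  hasScale <- any(vapply(records, function(r) !is.null(r@scales), TRUE))
  if ("mri" %in% modalities && !hasMri) {
    message("no MRI data found; continuing with an EEG-only run")
    modalities <- setdiff(modalities, "mri")
  }
  if ("scale" %in% modalities && !hasScale)
    modalities <- setdiff(modalities, "scale")

  ## --- extract --------------------------------------------------------------
  fs <- .stage("extract", extractCohortFeatures(
    records, eegDir = eegDir, modalities = modalities,
    regionMap = regionMap,
    k = config$microstates$k, seed = .deriveSeed(config$seed, 77L),
    nSegments = config$spectral$n_segments,
    segmentLength = config$spectral$segment_length,
    l = config$complexity$l, nBins = config$complexity$n_bins,
    windowMs = config$microstates$window_ms,
    lowcut = config$preprocess$lowcut, highcut = config$preprocess$highcut,
    rejectSd = config$preprocess$reject_sd))
  featPath <- file.path(outDir, "features.csv")
  exportFeatures(fs, featPath, extra = list(seed = config$seed,
                                            modalities = modalities))

  ## --- analyze groups -------------------------------------------------------
  paths <- c(features = featPath, sidecar = paste0(featPath, ".json"))
  stats <- .stage("analyze-groups", {
    gs <- groupStatistics(fs)
    utils::write.csv(gs, file.path(outDir, "group_stats.csv"),
                     row.names = FALSE)
    extras <- list()
    md <- S4Vectors::metadata(fs)
    if (!is.null(md$spectra)) {
      grp <- groupLabel(fs)[rownames(md$spectra$curves)]
      sel <- md$spectra$frequencies >= 0.5 & md$spectra$frequencies < 40
      mean0 <- function(g) colMeans(md$spectra$curves[grp == g, sel,
                                                      drop = FALSE])
      pt <- pairedSpectrumTest(mean0("positive"), mean0("negative"))
      extras$spectrumTest <- pt[c("statistic", "df", "p", "direction",
                                  "significant")]
    }
    if (!is.null(md$microstateModel)) {
      ms <- stateStatistics(md$microstateModel, targetRatio(fs))
      utils::write.csv(ms, file.path(outDir, "microstate_stats.csv"),
                       row.names = FALSE)
    }
    if ("mri" %in% modalities) {
      ac <- atrophyMarkerCorrelation(records)
      utils::write.csv(ac, file.path(outDir, "atrophy_correlation.csv"),
                       row.names = FALSE)
    }
    extras
  })
  for (f in c("group_stats.csv", "microstate_stats.csv",
              "atrophy_correlation.csv")) {
    p <- file.path(outDir, f)
    if (file.exists(p)) paths[sub("\\.csv$", "", f)] <- p
  }

  ## --- predict --------------------------------------------------------------
  rcfg <- regressorConfig(nTrees = config$regressor$n_trees,
                          minLeaf = config$regressor$min_leaf,
                          topK = config$regressor$top_k,
                          nFolds = config$regressor$n_folds,
                          seed = .deriveSeed(config$seed, 42L))
  pr <- .stage("predict", crossValidatePredict(fs, rcfg,
                                               threshold = config$threshold))
  utils::write.csv(pr$predictions, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(pr$metrics$roc, file.path(outDir, "roc.csv"),
                   row.names = FALSE)
  metrics <- pr$metrics[c("mae", "range", "normalizedError", "accuracy",
                          "auc", "baselineMae", "baselineNormalizedError")]
  metrics <- c(metrics, stats,
               list(nSubjectsPredicted = nrow(pr$predictions),
                    excluded = pr$excluded, seed = config$seed,
                    modalities = modalities))
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, predictions = file.path(outDir, "predictions.csv"),
             roc = file.path(outDir, "roc.csv"),
             metrics = file.path(outDir, "metrics.json"))

  ## --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "AbetaMM",
    version = as.character(utils::packageVersion("AbetaMM")),
    seed = config$seed,
    modalities = modalities,
    n_subjects = length(records),
    files = as.list(tools::md5sum(unname(paths))))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(paths = c(paths, manifest = manifestPath),
                 metrics = pr$metrics, manifest = manifest,
                 featureSet = fs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
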