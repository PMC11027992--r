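test_that("loadCohort populates one record per row with all modalities", {
  csv <- writeTinyCohortCsv(withr::local_tempfile(fileext = ".csv"))
  recs <- loadCohort(csv)
  expect_length(recs, 3)
  expect_setequal(names(recs), c("T01", "T02", "T03"))
  r <- recs[["T01"]]
  expect_equal(abetaRatio(r), 0.05)
  expect_named(r@mri, c("A", "B", "E", "F", "J", "H", "O", "P", "a", "b", "c"))
  expect_equal(unname(r@atrophy), c(0L, 1L, 0L))
  expect_equal(r@scales[["mmse"]], 29)
})

test_that("loadCohort rejects bad tables with informative errors", {
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,abeta_ratio", "A1,0.05", "A2,"), bad)
  expect_error(loadCohort(bad), "A2")

  writeLines(c("subject_id,abeta_ratio", "A1,0.05", "A1,0.06"), bad)
  expect_error(loadCohort(bad), "duplicate")

  writeLines(c("subject_id,something", "A1,0.05"), bad)
  expect_error(loadCohort(bad), "abeta_ratio")
})

test_that("group assignment follows the inclusive-positive threshold rule", {
  mk <- function(r, id) new("SubjectRecord", subjectId = id, abetaRatio = r)
  recs <- assignGroups(list(mk(0.05, "a"), mk(0.2, "b"), mk(0.1, "c")))
  grp <- vapply(recs, groupLabel, "")
  expect_equal(unname(grp), c("positive", "negative", "positive"))
  expect_equal(sum(grp == "positive"), 2L)

  expect_error(assignGroups(list(mk(0.05, "a"),
                                 new("SubjectRecord", subjectId = "n",
                                     abetaRatio = 0) )), NA)
})

test_that("raising the threshold never moves a subject out of positive", {
  set.seed(11)
  ratios <- exp(runif(40, log(1e-4), log(0.3)))
  recs <- lapply(seq_along(ratios), function(i)
    new("SubjectRecord", subjectId = paste0("s", i), abetaRatio = ratios[i]))
  for (pair in list(c(0.05, 0.1), c(0.1, 0.15))) {
    p1 <- vapply(assignGroups(recs, pair[1]), groupLabel, "") == "positive"
    p2 <- vapply(assignGroups(recs, pair[2]), groupLabel, "") == "positive"
    expect_true(all(p2[p1]))         # monotone
  }
  ## idempotence
  once <- assignGroups(recs, 0.1)
  twice <- assignGroups(once, 0.1)
  expect_identical(vapply(once, groupLabel, ""),
                   vapply(twice, groupLabel, ""))
})

test_that("feature matrix assembly sorts columns and drops incomplete subjects", {
  mk <- function(r, id) assignGroups(list(new("SubjectRecord",
                                              subjectId = id,
                                              abetaRatio = r)))[[1]]
  recs <- list(a = mk(0.05, "a"), b = mk(0.2, "b"))
  extracted <- list(
    a = c(`mri:evans_ratio` = 0.3, `eeg:beta_energy` = 2.1),
    b = c(`eeg:beta_energy` = 2.4, `mri:evans_ratio` = 0.25))
  fs <- assembleFeatureMatrix(recs, extracted)
  expect_s4_class(fs, "AbetaFeatureSet")
  expect_equal(colnames(featureMatrix(fs)),
               c("eeg:beta_energy", "mri:evans_ratio"))
  expect_equal(dim(featureMatrix(fs)), c(2L, 2L))

  ## subject lacking MRI is excluded when mri is required
  extracted$b <- extracted$b["eeg:beta_energy"]
  fs2 <- suppressMessages(
    assembleFeatureMatrix(recs, extracted,
                          requiredModalities = c("eeg", "mri")))
  expect_length(S4Vectors::metadata(fs2)$exclusions, 1)
  expect_equal(names(S4Vectors::metadata(fs2)$exclusions), "b")
  expect_equal(rownames(featureMatrix(fs2)), "a")
})

test_that("assembly rejects cross-modality name collisions and unknown ids", {
  mk <- function(r, id) assignGroups(list(new("SubjectRecord",
                                              subjectId = id,
                                              abetaRatio = r)))[[1]]
  recs <- list(a = mk(0.05, "a"))
  expect_error(assembleFeatureMatrix(
    recs, list(a = c(`eeg:evans` = 1, `mri:evans` = 2))), "collision")
  expect_error(assembleFeatureMatrix(
    recs, list(zz = c(`eeg:x` = 1))), "zz")
})

test_that("assembly is invariant to record order up to row order", {
  mk <- function(r, id) assignGroups(list(new("SubjectRecord",
                                              subjectId = id,
                                              abetaRatio = r)))[[1]]
  recs <- list(a = mk(0.05, "a"), b = mk(0.2, "b"), c = mk(0.15, "c"))
  extracted <- list(a = c(`eeg:x` = 1, `eeg:y` = 2),
                    b = c(`eeg:x` = 3, `eeg:y` = 4),
                    c = c(`eeg:x` = 5, `eeg:y` = 6))
  f1 <- featureMatrix(assembleFeatureMatrix(recs, extracted))
  f2 <- featureMatrix(assembleFeatureMatrix(rev(recs), rev(extracted)))
  expect_identical(f1, f2[rownames(f1), ])
})

test_that("cohort tables round-trip field for field", {
  csv <- writeTinyCohortCsv(withr::local_tempfile(fileext = ".csv"),
                            ratios = c(0.012345678901234, 0.2))
  recs <- loadCohort(csv)
  out <- withr::local_tempfile(fileext = ".csv")
  writeCohort(recs, out)
  recs2 <- loadCohort(out)
  for (id in names(recs)) {
    expect_identical(abetaRatio(recs[[id]]), abetaRatio(recs2[[id]]))
    expect_identical(recs[[id]]@mri, recs2[[id]]@mri)
    expect_identical(recs[[id]]@atrophy, recs2[[id]]@atrophy)
    expect_identical(recs[[id]]@scales, recs2[[id]]@scales)
    expect_identical(groupLabel(recs[[id]]), groupLabel(recs2[[id]]))
  }
})

test_that("EDF files round-trip within 16-bit quantization", {
  set.seed(3)
  rec <- noiseRecording(nCh = 4, nSamp = 3000, sd = 20)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, path)
  back <- readEDF(path, tinyMontage())
  expect_equal(channelNames(back), channelNames(rec)[1:4])
  expect_equal(samplingRate(back), 1000)
  tol <- (max(rec@data) - min(rec@data)) / 65535 * 1.01
  expect_lt(max(abs(eegData(back) - rec@data)), tol)
})

test_that("EDF export is byte-deterministic", {
  set.seed(4)
  rec <- noiseRecording(nCh = 3, nSamp = 2000)
  p1 <- withr::local_tempfile(fileext = ".edf")
  p2 <- withr::local_tempfile(fileext = ".edf")
  writeEDF(rec, p1); writeEDF(rec, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("BrainVision ASCII and binary data are read correctly", {
  set.seed(5)
  rec <- noiseRecording(nCh = 4, nSamp = 500)
  base <- file.path(withr::local_tempdir(), "bv")
  writeBrainVisionAscii(rec, base)
  back <- readBrainVision(paste0(base, ".vhdr"), tinyMontage())
  expect_equal(eegData(back), rec@data, tolerance = 1e-9)
  expect_equal(samplingRate(back), 1000)

  ## hand-built binary multiplexed float32 file
  dir2 <- withr::local_tempdir()
  dat <- file.path(dir2, "b.eeg")
  con <- file(dat, "wb")
  writeBin(as.numeric(rec@data), con, size = 4L, endian = "little")
  ## multiplexed = one time point per "row": data written channel-fastest
  close(con)
  hdr <- file.path(dir2, "b.vhdr")
  writeLines(c("[Common Infos]", "DataFile=b.eeg", "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED", "NumberOfChannels=4",
               "SamplingInterval=1000",
               "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "[Channel Infos]",
               sprintf("Ch%d=%s,,1,uV", 1:4, channelNames(rec))), hdr)
  back2 <- readBrainVision(hdr, tinyMontage())
  expect_equal(samplingRate(back2), 1000)
  expect_equal(back2@data, rec@data, tolerance = 1e-6)
})
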