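test_that("configuration validation enforces the documented bounds", {
  expect_error(effectConfig(nSubjects = 3), "at least 4")
  expect_error(effectConfig(positiveFraction = 0), "positiveFraction")
  expect_error(effectConfig(ratioRange = c(0.2, 0.1)), "ratioRange")
  expect_error(effectConfig(betaGammaEnergyDeficit = -0.1), ">= 0")
  expect_error(effectConfig(betaGammaEnergyDeficit = 1), "below 1")
})

test_that("cohort generation is deterministic and byte-identical on disk", {
  cfg <- effectConfig(nSubjects = 4, mriMissing = 1L, seed = 77)
  map <- montage19()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateCohort(cfg, dir = d1, regionMap = map)
  generateCohort(cfg, dir = d2, regionMap = map)
  for (f in c("cohort.csv", file.path("eeg", "S001.edf"),
              file.path("eeg", "S004.edf")))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("marker values respect range, mixture split and modal payloads", {
  cfg <- effectConfig(seed = 5)
  recs <- generateCohort(cfg, withEEG = FALSE)
  ratios <- vapply(recs, abetaRatio, 0)
  expect_true(all(ratios >= cfg$ratioRange[1] & ratios <= cfg$ratioRange[2]))
  grp <- vapply(recs, groupLabel, "")
  expect_gt(sum(grp == "positive"), 10)
  expect_gt(sum(grp == "negative"), 10)
  ## positive <=> ratio at or below the threshold
  expect_identical(unname(grp == "positive"), unname(ratios <= 0.1))
  ## the configured number of subjects lack MRI/scales (joint subset smaller)
  noMri <- sum(vapply(recs, function(r) is.null(r@mri), TRUE))
  expect_equal(noMri, 5L)
  withScales <- sum(vapply(recs, function(r) !is.null(r@scales), TRUE))
  expect_equal(withScales, 77L)
})

test_that("subject EEG carries the planted spectral structure", {
  cfg <- effectConfig()
  map <- montage19()
  rec <- generateSubjectEEG(0.15, cfg, seed = 8, regionMap = map)
  expect_s4_class(rec, "EEGRecording")
  expect_equal(ncol(eegData(rec)), 52000L)
  be <- bandEnergies(averageSpectrum(preprocessRecording(rec,
                                                         rejectSd = Inf)))
  ## alpha-dominant resting spectrum by construction
  expect_gt(be@energy[["alpha"]], be@energy[["beta"]])
  expect_gt(be@energy[["alpha"]], be@energy[["gamma"]])
  expect_equal(be@dominantAlphaFrequency, 10, tolerance = 2)

  expect_error(generateSubjectEEG(0.15, effectConfig(duration = 30),
                                  seed = 1, regionMap = map),
               "20 segments")
})

test_that("a stronger energy deficit yields a larger group difference", {
  map <- montage19()
  ## group difference in channel-averaged beta energy at three deficit levels
  betaDiff <- function(deficit, seed) {
    cfg <- effectConfig(nSubjects = 30, betaGammaEnergyDeficit = deficit,
                        mriMissing = 0L, seed = seed)
    recs <- generateCohort(cfg, withEEG = FALSE)
    gen <- attr(recs, "generator")
    beta <- vapply(recs, function(r) {
      core <- AbetaMM:::.synthSubjectXt(abetaRatio(r), cfg,
                                        gen$eegSeeds[[subjectId(r)]], map)
      xt <- AbetaMM:::.preprocessCore(core$xt, cfg$samplingRate)$xt
      sp <- AbetaMM:::.spectrumCore(xt, cfg$samplingRate)
      AbetaMM:::.bandEnergiesCore(sp$frequencies, sp$power)$energy[["beta"]]
    }, 0)
    grp <- vapply(recs, groupLabel, "")
    mean(beta[grp == "negative"]) - mean(beta[grp == "positive"])
  }
  ## common random numbers: the same seeds at every deficit level pair the
  ## comparison, so only the planted effect differs between levels
  d0 <- vapply(1:2, function(s) betaDiff(0, 300 + s), 0)
  dMid <- vapply(1:2, function(s) betaDiff(0.25, 300 + s), 0)
  dBig <- vapply(1:2, function(s) betaDiff(0.5, 300 + s), 0)
  expect_true(all(dMid > d0))
  expect_true(all(dBig > dMid))
  expect_gt(mean(dBig), 1)        # a 50% energy deficit is clearly visible
})

test_that("two channels driven by one latent source share information", {
  cfg <- effectConfig()
  map <- montage19()
  rec <- generateSubjectEEG(0.02, cfg, seed = 9, regionMap = map)
  x <- eegData(rec)
  reg <- regionMap(rec)[channelNames(rec)]
  fCh <- which(reg == "F")[1:2]
  pCh <- which(reg == "P")[1:2]
  ## F channels share the pair source with L-T; P channels do not
  miF <- mutualInformation(x[fCh[1], ], x[which(reg == "L-T")[1], ])
  miP <- mutualInformation(x[pCh[1], ], x[which(reg == "O")[1], ])
  expect_gt(miF, miP)
})

test_that("all-zero effects give calibrated group tests on MRI features", {
  ## generator null soundness, checked on the cheap modality: with every
  ## effect off, grade-vs-group and measurement-vs-group tests should show
  ## ~uniform p-values across replicate cohorts
  set.seed(81)
  ps <- replicate(400, {
    cfg <- effectConfig(nSubjects = 40, betaGammaEnergyDeficit = 0,
                        complexityDeficit = 0, miDeficit = 0,
                        atrophyR2 = 0, microstateCoupling = 0,
                        mriEffect = 0, scaleEffect = 0,
                        mriMissing = 0L, seed = sample.int(2^30, 1))
    recs <- generateCohort(cfg, withEEG = FALSE)
    grp <- vapply(recs, groupLabel, "")
    ev <- vapply(recs, function(r) r@mri[["E"]] / r@mri[["A"]], 0)
    if (length(unique(grp)) < 2) return(NA_real_)
    twoSampleTest(ev[grp == "positive"], ev[grp == "negative"])$p
  })
  ps <- ps[!is.na(ps)]
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("planted microstate templates are recovered from the raw EEG", {
  skip_if_not_installed("mclust")
  cfg <- effectConfig()
  map <- montage19()
  topos <- list(); labs <- list(); ids <- list()
  for (s in 1:4) {
    rec <- generateSubjectEEG(0.05 * s, cfg, seed = 400 + s, regionMap = map)
    planted <- attr(rec, "plantedStates")
    pre <- preprocessRecording(rec, rejectSd = Inf)   # keep windows aligned
    tp <- extractTopographies(pre)
    stateAt <- rep(planted$states, planted$durations)
    lab <- rep(NA_integer_, nrow(tp))
    for (w in seq_len(nrow(tp))) {
      seg <- stateAt[((w - 1) * 100 + 1):(w * 100)]
      tb <- table(seg)
      ## compare only windows dominated (>= 90%) by one planted state
      if (max(tb) / 100 >= 0.9) lab[w] <- as.integer(names(tb)[which.max(tb)])
    }
    topos[[s]] <- tp; labs[[s]] <- lab; ids[[s]] <- rep(s, nrow(tp))
  }
  mod <- fitMicrostates(do.call(rbind, topos), k = 7, seed = 12,
                        subjectIds = as.character(unlist(ids)))
  lab <- unlist(labs)
  sel <- !is.na(lab)
  ari <- mclust::adjustedRandIndex(mod@assignments[sel], lab[sel])
  expect_gte(ari, 0.9)
})

test_that("the ratio-coupled microstate emerges with a negative correlation", {
  cfg <- effectConfig(nSubjects = 40, mriMissing = 0L, seed = 14)
  map <- montage19()
  recs <- generateCohort(cfg, withEEG = FALSE)
  gen <- attr(recs, "generator")
  topos <- lapply(recs, function(r) {
    core <- AbetaMM:::.synthSubjectXt(abetaRatio(r), cfg,
                                      gen$eegSeeds[[subjectId(r)]], map)
    xt <- AbetaMM:::.preprocessCore(core$xt, cfg$samplingRate)$xt
    AbetaMM:::cpp_window_sd(xt, 100L)
  })
  ids <- rep(names(recs), vapply(topos, nrow, 0L))
  mod <- fitMicrostates(do.call(rbind, topos), k = 7, seed = 6,
                        subjectIds = ids)
  ratios <- vapply(recs, abetaRatio, 0)
  st <- stateStatistics(mod, ratios)
  neg <- st[st$direction == "negative" & st$significant, ]
  expect_gte(nrow(neg), 1)
  expect_lt(min(neg$r), -0.5)
})
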