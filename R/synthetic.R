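#' Effect configuration for the synthetic-cohort generator
#'
#' Bundles the cohort size, marker distribution and planted effect structure
#' that \code{\link{generateCohort}} emulates: lower beta/gamma band energy,
#' lower frontal/parietal signal complexity, weaker frontal/left-temporal and
#' occipital/right-temporal coupling in amyloid-positive subjects, atrophy
#' grades with a target squared correlation to the marker, and one microstate
#' whose occurrence frequency falls as the marker rises. Effects are planted
#' continuously through the logistic weight
#' \code{w(ratio) = plogis((log(threshold) - log(ratio)) / 0.5)}, which is
#' near 1 deep in the positive range and near 0 deep in the negative range,
#' so group contrasts and regression signal coexist.
#'
#' @param nSubjects cohort size (>= 4).
#' @param ratioRange truncation bounds of the marker mixture.
#' @param positiveFraction expected proportion of amyloid-positive subjects
#'   (default 47/82).
#' @param threshold positivity threshold on the ratio.
#' @param betaGammaEnergyDeficit maximal relative reduction of beta and gamma
#'   band energy in strongly positive subjects.
#' @param complexityDeficit maximal share of frontal/parietal broadband power
#'   re-routed into narrowband alpha (lowers Lempel-Ziv complexity without
#'   changing total energy).
#' @param complexityRegions regions carrying the complexity deficit.
#' @param miDeficit maximal relative reduction of the shared-source coupling
#'   for the configured region pairs.
#' @param miPairs list of region pairs with coupled latent sources.
#' @param atrophyR2 target squared correlation between each atrophy grade and
#'   the marker.
#' @param mriEffect,scaleEffect multipliers (0..1) on the disease coupling of
#'   the linear measurements and of the cognitive scale scores; 0 makes the
#'   modality carry no marker signal.
#' @param nStates number of planted microstate templates.
#' @param microstateCoupling strength of the ratio coupling of state 1's
#'   occurrence probability (0..1).
#' @param microstateDepth channel-gain modulation depth of the templates.
#' @param bandAmps baseline RMS amplitude (microvolts) per band.
#' @param subjectAmpSd log-SD of per-subject band amplitude jitter.
#' @param channelGainSd log-SD of per-channel gain jitter.
#' @param noiseSd RMS of the flat broadband noise floor (microvolts).
#' @param globalCoupling relative amplitude of the all-channel common source.
#' @param pairCoupling baseline relative amplitude of the pair sources.
#' @param samplingRate Hz; \code{duration} seconds of eyes-closed rest
#'   (defaults 1000 Hz, 52 s: twenty 2000-sample spectrum segments plus a
#'   six-segment margin for amplitude-based segment rejection).
#' @param mriMissing number of subjects without MRI (and scales), emulating
#'   an EEG-complete / joint-incomplete cohort.
#' @param seed integer master seed.
#' @return A validated list of class \code{"EffectConfig"}.
#' @export
effectConfig <- function(nSubjects = 82L,
                         ratioRange = c(2e-5, 0.25),
                         positiveFraction = 47 / 82,
                         threshold = 0.1,
                         betaGammaEnergyDeficit = 0.2,
                         complexityDeficit = 0.2,
                         complexityRegions = c("F", "P"),
                         miDeficit = 0.3,
                         miPairs = list(c("F", "L-T"), c("O", "R-T")),
                         atrophyR2 = 0.2,
                         mriEffect = 1,
                         scaleEffect = 1,
                         nStates = 7L,
                         microstateCoupling = 0.6,
                         microstateDepth = 0.9,
                         bandAmps = c(delta = 4, theta = 3, alpha = 6,
                                      beta = 2.5, gamma = 1.5),
                         subjectAmpSd = 0.08,
                         channelGainSd = 0.05,
                         noiseSd = 1,
                         globalCoupling = 0.12,
                         pairCoupling = 0.45,
                         samplingRate = 1000,
                         duration = 52,
                         mriMissing = 5L,
                         seed = 1L) {
  cfg <- list(nSubjects = as.integer(nSubjects), ratioRange = ratioRange,
              positiveFraction = positiveFraction, threshold = threshold,
              betaGammaEnergyDeficit = betaGammaEnergyDeficit,
              complexityDeficit = complexityDeficit,
              complexityRegions = complexityRegions, miDeficit = miDeficit,
              miPairs = miPairs, atrophyR2 = atrophyR2,
              mriEffect = mriEffect, scaleEffect = scaleEffect,
              nStates = as.integer(nStates),
              microstateCoupling = microstateCoupling,
              microstateDepth = microstateDepth, bandAmps = bandAmps,
              subjectAmpSd = subjectAmpSd, channelGainSd = channelGainSd,
              noiseSd = noiseSd, globalCoupling = globalCoupling,
              pairCoupling = pairCoupling, samplingRate = samplingRate,
              duration = duration, mriMissing = as.integer(mriMissing),
              seed = as.integer(seed))
  if (cfg$nSubjects < 4L)
    stop("nSubjects must be at least 4 (groups and folds cannot form)")
  if (!(positiveFraction > 0 && positiveFraction < 1))
    stop("positiveFraction must lie strictly between 0 and 1")
  if (ratioRange[1] >= ratioRange[2]) stop("ratioRange low must be < high")
  eff <- c(betaGammaEnergyDeficit, complexityDeficit, miDeficit, atrophyR2,
           microstateCoupling, mriEffect, scaleEffect)
  if (any(eff < 0)) stop("effect magnitudes must be >= 0")
  if (betaGammaEnergyDeficit >= 1 || complexityDeficit >= 1 ||
      miDeficit > 1 || microstateCoupling > 1)
    stop("relative deficits must be below 1")
  if (cfg$mriMissing >= cfg$nSubjects) stop("mriMissing >= nSubjects")
  class(cfg) <- "EffectConfig"
  cfg
}

## logistic disease weight: ~1 deep positive, ~0 deep negative
.diseaseWeight <- function(ratio, threshold) {
  stats::plogis((log(threshold) - log(ratio)) / 0.5)
}

## truncated log-normal mixture straddling the threshold
.sampleRatios <- function(cfg) {
  n <- cfg$nSubjects
  pos <- stats::rbinom(n, 1, cfg$positiveFraction) == 1
  draw <- function(k, meanlog, sdlog, lo, hi) {
    out <- numeric(k)
    left <- seq_len(k)
    while (length(left)) {
      v <- stats::rlnorm(length(left), meanlog, sdlog)
      ok <- v >= lo & v <= hi
      out[left[ok]] <- v[ok]
      left <- left[!ok]
    }
    out
  }
  r <- numeric(n)
  r[pos] <- draw(sum(pos), log(0.04), 0.8, cfg$ratioRange[1], cfg$threshold)
  r[!pos] <- draw(sum(!pos), log(0.15), 0.35,
                  cfg$threshold + 1e-12, cfg$ratioRange[2])
  r
}

## grades 0-3 per lobe with corr(grade, ratio)^2 calibrated to atrophyR2.
## The latent correlation is inflated by two analytic/empirical attenuation
## factors: discretization of the latent normal into four grades
## (lambda1, from the fixed cutpoints) and the nonlinearity between the raw
## ratio and its negated log-score (kappa, measured on the realized draws).
.sampleGrades <- function(ratio, cfg) {
  cuts <- stats::qnorm(c(0.35, 0.65, 0.88))
  probs <- diff(c(0, 0.35, 0.65, 0.88, 1))
  gmean <- sum(0:3 * probs)
  gsd <- sqrt(sum((0:3)^2 * probs) - gmean^2)
  lambda1 <- sum(stats::dnorm(cuts)) / gsd
  u <- as.numeric(scale(-log(ratio)))
  kappa <- abs(stats::cor(u, ratio))
  rho <- min(0.999, sqrt(cfg$atrophyR2) / (lambda1 * kappa))
  n <- length(ratio)
  sapply(.GCA_LOBES, function(l) {
    z <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
    findInterval(z, cuts)
  })
}

.clip <- function(x, lo, hi = Inf) pmin(pmax(x, lo), hi)

.sampleMeasurements <- function(w) {
  n <- length(w)
  A <- stats::rnorm(n, 135, 5)
  B <- stats::rnorm(n, 172, 6)
  E <- A * .clip(0.25 + 0.05 * w + stats::rnorm(n, 0, 0.015), 0.15, 0.45)
  F_ <- A * .clip(0.10 + 0.04 * w + stats::rnorm(n, 0, 0.010), 0.05, 0.30)
  J <- F_ * .clip(1.6 + stats::rnorm(n, 0, 0.10), 1.2, 2.2)
  H <- .clip(4 + 4 * w + stats::rnorm(n, 0, 0.8), 1, 15)
  O <- .clip(3 + 3 * w + stats::rnorm(n, 0, 0.7), 0.5, 12)
  P <- .clip(10 + 3 * w + stats::rnorm(n, 0, 1.5), 2, 25)
  a <- .clip(11 - 2 * w + stats::rnorm(n, 0, 1.2), 3)
  b <- .clip(6 - 1.5 * w + stats::rnorm(n, 0, 0.8), 1.5)
  cc <- .clip(11 - 2 * w + stats::rnorm(n, 0, 1.2), 3)
  cbind(A = A, B = B, E = E, F = F_, J = J, H = H, O = O, P = P,
        a = a, b = b, c = cc)
}

.sampleScales <- function(w) {
  n <- length(w)
  cbind(mmse = .clip(29 - 11 * w + stats::rnorm(n, 0, 2.0), 0, 30),
        moca = .clip(28 - 12 * w + stats::rnorm(n, 0, 2.5), 0, 30))
}

## per-state occurrence probabilities; state 1 coupled to the marker
.stateProbs <- function(w, cfg) {
  k <- cfg$nStates
  p1 <- (1 + cfg$microstateCoupling * (2 * w - 1)) / k
  c(p1, rep((1 - p1) / (k - 1), k - 1))
}

## smooth, mutually distinct channel-gain templates
.stateTemplates <- function(nCh, cfg) {
  k <- cfg$nStates
  pos <- (seq_len(nCh) - 1) / nCh
  t(vapply(seq_len(k), function(s) {
    f <- 1 + (s - 1) %% 3
    1 + cfg$microstateDepth * cos(2 * pi * (f * pos + (s - 1) / k))
  }, numeric(nCh)))
}

#' Generate one subject's synthetic EEG recording
#'
#' The signal is a sum of band-limited noise components (delta..gamma) whose
#' beta/gamma amplitudes fall with the disease weight, shared latent sources
#' carrying the between-region coupling structure, a flat broadband noise
#' floor, and a microstate template sequence that re-scales all channels
#' every ~100 ms (switch times jittered +/-20 ms so windows and states are
#' not artificially aligned). Channels in the configured complexity regions
#' have part of their broadband power re-routed into narrowband alpha for
#' positive subjects. Deterministic given the seed.
#'
#' @param ratio the subject's marker value.
#' @param cfg an \code{\link{effectConfig}}.
#' @param seed integer seed for this subject.
#' @param regionMap channel-to-region map (defines the montage).
#' @return An \linkS4class{EEGRecording}.
#' @export
generateSubjectEEG <- function(ratio, cfg = effectConfig(), seed = 1L,
                               regionMap = defaultMontage()) {
  core <- .synthSubjectXt(ratio, cfg, seed, regionMap)
  x <- t(core$xt)
  out <- EEGRecording(x, cfg$samplingRate, names(regionMap), regionMap)
  attr(out, "plantedStates") <- core$planted
  out
}

## samples x channels synthesis core (used directly by the streaming
## extractor so the hot path never transposes the full matrix)
.synthSubjectXt <- function(ratio, cfg = effectConfig(), seed = 1L,
                            regionMap = defaultMontage()) {
  fs <- cfg$samplingRate
  nSamp <- as.integer(round(cfg$duration * fs))
  if (nSamp < 20L * 2000L)
    stop("duration must cover at least 20 segments of 2000 samples")
  channels <- names(regionMap)
  regions <- unname(regionMap)
  nCh <- length(channels)
  w <- .diseaseWeight(ratio, cfg$threshold)
  bands <- defaultBands()

  set.seed(as.integer(seed))
  ## per-subject band amplitude and per-channel gain jitter
  ampB <- cfg$bandAmps * exp(stats::rnorm(5, 0, cfg$subjectAmpSd))
  gCh <- exp(stats::rnorm(nCh, 0, cfg$channelGainSd))
  amp <- outer(ampB, gCh)                      # bands x channels, RMS uV
  bg <- sqrt(1 - cfg$betaGammaEnergyDeficit * w)
  amp[c("beta", "gamma"), ] <- amp[c("beta", "gamma"), ] * bg
  ## complexity deficit: energy-preserving shift of broadband into alpha
  m <- cfg$complexityDeficit * w
  inCx <- regions %in% cfg$complexityRegions
  if (m > 0 && any(inCx)) {
    T2 <- colSums(amp[, inCx, drop = FALSE]^2)
    sub <- amp[, inCx, drop = FALSE] * sqrt(1 - m)
    sub["alpha", ] <- sqrt(sub["alpha", ]^2 + m * T2)
    amp[, inCx] <- sub
  }

  ## shared sources: one global + one per configured region pair, each a
  ## unit-RMS broadband source; coupling weights scale with the channel RMS
  chRms <- sqrt(colSums(amp^2) + cfg$noiseSd^2)
  nSrc <- 1L + length(cfg$miPairs)
  srcW <- matrix(0, nCh, nSrc)
  srcW[, 1] <- cfg$globalCoupling * chRms
  cpl <- cfg$pairCoupling * sqrt(1 - cfg$miDeficit * w)
  for (p in seq_along(cfg$miPairs)) {
    sel <- regions %in% cfg$miPairs[[p]]
    srcW[sel, p + 1L] <- cpl * chRms[sel]
  }
  ## keep total channel power approximately level across coupling levels
  shared2 <- rowSums(srcW^2)
  amp <- amp * rep(sqrt(.clip(1 - shared2 / chRms^2, 0.05)), each = 5)

  ## per-bin synthesis amplitudes (positive-frequency bins, DC excluded)
  df <- fs / nSamp
  fmax <- min(110, fs / 2 - df)
  nBins <- as.integer(floor(fmax / df))
  fbin <- seq_len(nBins) * df
  sigma2 <- matrix(0, nBins, nCh)
  for (b in seq_along(bands)) {
    sel <- fbin >= bands[[b]][1] & fbin < bands[[b]][2]
    nb <- sum(sel)
    sigma2[sel, ] <- sigma2[sel, ] +
      rep((amp[b, ] * nSamp)^2 / (4 * nb), each = nb)
  }
  noiseSel <- fbin >= 0.5
  sigma2[noiseSel, ] <- sigma2[noiseSel, ] +
    (cfg$noiseSd * nSamp)^2 / (4 * sum(noiseSel))
  chanAmp <- sqrt(sigma2)
  srcSel <- fbin >= 0.5 & fbin < 40
  srcAmp <- matrix(0, nBins, nSrc)
  srcAmp[srcSel, ] <- nSamp / (2 * sqrt(sum(srcSel)))

  ## microstate switching sequence (~100 ms, jittered +/- 20 ms)
  probs <- .stateProbs(w, cfg)
  maxWin <- as.integer(ceiling(nSamp / (0.08 * fs))) + 2L
  durs <- as.integer(round(stats::runif(maxWin, 0.08, 0.12) * fs))
  keep <- which(cumsum(durs) - durs < nSamp)
  durs <- durs[keep]
  states <- sample.int(cfg$nStates, length(durs), replace = TRUE,
                       prob = probs)
  starts <- cumsum(c(0L, durs[-length(durs)]))
  templ <- .stateTemplates(nCh, cfg)
  winGain <- t(templ[states, , drop = FALSE])   # nCh x nWin

  xt <- cpp_synth_eeg(nSamp, chanAmp, srcAmp, srcW, winGain,
                      starts, durs)
  colnames(xt) <- channels
  list(xt = xt, regions = regions,
       planted = list(states = states, starts = starts, durations = durs))
}

#' Generate a synthetic multimodal cohort
#'
#' Draws marker values from a two-component log-normal mixture straddling the
#' positivity threshold (weights matching the configured positive fraction),
#' then samples atrophy grades calibrated to the target grade-marker squared
#' correlation, linear measurements in physiologic millimeter ranges with
#' mild disease coupling, scale scores, and (optionally) one EEG recording
#' per subject. A configurable number of subjects lack MRI and scales,
#' emulating an EEG-complete cohort whose joint-modality subset is smaller.
#' Fully deterministic given \code{cfg$seed}.
#'
#' @param cfg an \code{\link{effectConfig}}.
#' @param dir if non-NULL, write \code{cohort.csv} and \code{eeg/<id>.edf}
#'   under this directory (the exact formats \code{\link{loadCohort}}
#'   reads) and keep EEG out of memory.
#' @param withEEG attach/write EEG (default TRUE). When \code{dir} is NULL
#'   the records carry no EEG data; the generator recipe travels in the
#'   \code{"generator"} attribute, and \code{\link{extractCohortFeatures}}
#'   synthesizes each recording on the fly, one subject at a time.
#' @param regionMap channel-to-region map used for the EEG.
#' @return Named list of \linkS4class{SubjectRecord} with groups assigned;
#'   attributes \code{generator} (config, per-subject EEG seeds) and, when
#'   \code{dir} is given, \code{paths}.
#' @export
generateCohort <- function(cfg = effectConfig(), dir = NULL, withEEG = TRUE,
                           regionMap = defaultMontage()) {
  stopifnot(inherits(cfg, "EffectConfig"))
  n <- cfg$nSubjects
  ids <- sprintf("S%03d", seq_len(n))

  set.seed(.deriveSeed(cfg$seed, 1L))
  ratio <- .sampleRatios(cfg)
  w <- .diseaseWeight(ratio, cfg$threshold)
  set.seed(.deriveSeed(cfg$seed, 2L))
  grades <- .sampleGrades(ratio, cfg)
  set.seed(.deriveSeed(cfg$seed, 3L))
  meas <- .sampleMeasurements(w * cfg$mriEffect)
  set.seed(.deriveSeed(cfg$seed, 4L))
  scales <- .sampleScales(w * cfg$scaleEffect)
  set.seed(.deriveSeed(cfg$seed, 5L))
  noMri <- if (cfg$mriMissing > 0L) sample.int(n, cfg$mriMissing)
           else integer(0)
  eegSeeds <- vapply(seq_len(n), function(i) .deriveSeed(cfg$seed, 1000L + i),
                     1L)

  records <- lapply(seq_len(n), function(i) {
    hasMri <- !(i %in% noMri)
    new("SubjectRecord", subjectId = ids[i], abetaRatio = ratio[i],
        mri = if (hasMri) stats::setNames(meas[i, ], .MRI_FIELDS) else NULL,
        atrophy = if (hasMri)
          stats::setNames(as.integer(grades[i, ]), .GCA_LOBES) else NULL,
        scales = if (hasMri) stats::setNames(scales[i, ],
                                             colnames(scales)) else NULL)
  })
  names(records) <- ids
  records <- assignGroups(records, cfg$threshold)
  attr(records, "generator") <- list(config = cfg,
                                     eegSeeds = stats::setNames(eegSeeds, ids),
                                     regionMap = regionMap,
                                     withEEG = withEEG)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tablePath <- file.path(dir, "cohort.csv")
    writeCohort(records, tablePath)
    eegDir <- NULL
    if (withEEG) {
      eegDir <- file.path(dir, "eeg")
      dir.create(eegDir, showWarnings = FALSE)
      for (i in seq_len(n)) {
        rec <- generateSubjectEEG(ratio[i], cfg, eegSeeds[i], regionMap)
        writeEDF(rec, file.path(eegDir, paste0(ids[i], ".edf")))
      }
    }
    attr(records, "paths") <- list(cohortTable = tablePath, eegDir = eegDir)
  }
  records
}
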