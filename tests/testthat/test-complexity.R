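test_that("quantization thresholds and symbol assignment follow the contract", {
  q <- quantizeSignal(c(1, 5, 2, 9), l = 2)
  expect_equal(q$symbols, c(0L, 1L, 0L, 1L))

  set.seed(31)
  x <- rnorm(5001)
  q2 <- quantizeSignal(x, 2)
  expect_equal(mean(q2$symbols == 0), 0.5, tolerance = 2 / 5001)

  u <- runif(10000)
  q4 <- quantizeSignal(u, 4)
  expect_true(all(abs(tabulate(q4$symbols + 1L, 4) / 10000 - 0.25) < 0.02))

  expect_error(quantizeSignal(rep(1, 10), 2), "explicit thresholds")
  q5 <- quantizeSignal(rep(1, 10), 2, thresholds = 0)
  expect_true(all(q5$symbols == 1L))
})

test_that("LZ76 phrase counts match hand-worked cases", {
  expect_equal(lzComplexity(list(symbols = 0L, l = 2L))$c, 1L)
  expect_equal(lzComplexity(list(symbols = rep(0L, 8), l = 2L))$c, 2L)
  expect_error(lzComplexity(list(symbols = integer(0), l = 2L)), "empty")
  ## normalization C = c log_l(n) / n
  r <- lzComplexity(list(symbols = c(0L, 1L, 0L, 0L, 1L, 1L), l = 2L))
  expect_equal(r$C, r$c * log2(6) / 6)
})

test_that("the parser agrees with the brute-force oracle on short strings", {
  for (len in 1:8) {
    strs <- allStrings(len, 2)
    for (i in seq_len(nrow(strs))) {
      sym <- as.integer(strs[i, ])
      expect_identical(lzComplexity(list(symbols = sym, l = 2L))$c,
                       lzOracle(sym))
    }
  }
  for (len in 1:4) {
    strs <- allStrings(len, 4)
    for (i in seq_len(nrow(strs))) {
      sym <- as.integer(strs[i, ])
      expect_identical(lzComplexity(list(symbols = sym, l = 4L))$c,
                       lzOracle(sym))
    }
  }
})

test_that("complexity is invariant under symbol relabeling", {
  set.seed(32)
  for (r in 1:20) {
    sym <- sample(0:2, 400, replace = TRUE)
    perm <- sample(0:2)
    relab <- perm[sym + 1L]
    expect_identical(cpp_c <- lzComplexity(list(symbols = sym, l = 3L))$c,
                     lzComplexity(list(symbols = relab, l = 3L))$c)
  }
})

test_that("periodic signals are less complex than noise", {
  set.seed(33)
  fs <- 1000
  square <- rep(c(rep(1, 50), rep(-1, 50)), 40)   # 10 Hz square wave
  noise <- rnorm(4000)
  cSq <- lzComplexity(quantizeSignal(square + rnorm(4000, 0, 1e-3), 2))$C
  cNo <- lzComplexity(quantizeSignal(noise, 2))$C
  expect_lt(cSq, cNo / 2)
})

test_that("region complexity aggregates per region and flags empty regions", {
  set.seed(34)
  rec <- noiseRecording(nSamp = 4000)
  rc <- regionComplexity(rec)
  expect_setequal(rc$regions$region, c("F", "P", "L-T", "R-T", "O"))
  expect_true(all(rc$regions$n == 2))
  expect_equal(rc$overall$mean, mean(rc$perChannel))

  map <- tinyMontage()[1:8]                    # no occipital channels
  recNoO <- EEGRecording(matrix(rnorm(8 * 4000), 8, 4000), 1000,
                         names(map), map)
  expect_error(regionComplexity(recNoO), "zero channels: O")
})

test_that("white-noise regions have indistinguishable complexity", {
  set.seed(35)
  ps <- replicate(10, {
    rec <- noiseRecording(nSamp = 4000)
    rc <- regionComplexity(rec)
    reg <- rec@regionMap[channelNames(rec)]
    summary(stats::aov(rc$perChannel ~ factor(reg)))[[1]][["Pr(>F)"]][1]
  })
  expect_gt(mean(ps), 0.2)          # roughly uniform p-values under the null
  expect_gt(max(ps), 0.1)
})

test_that("mutual information matches exact identities", {
  x <- rep(0:3, 250)
  expect_equal(mutualInformation(x, x, nBins = 4, unit = "bits"), 2)
  set.seed(36)
  a <- rnorm(50000); b <- rnorm(50000)
  expect_lt(mutualInformation(a, b, 16), 0.01)     # independence limit
  expect_identical(mutualInformation(a, b, 16), mutualInformation(b, a, 16))
  expect_error(mutualInformation(a, b[-1], 16), "equal length")
})

test_that("adding independent noise to one signal cannot raise MI", {
  set.seed(37)
  diffs <- replicate(15, {
    x <- rnorm(20000)
    y <- 0.8 * x + 0.6 * rnorm(20000)
    mutualInformation(x, y + rnorm(20000), 16) - mutualInformation(x, y, 16)
  })
  expect_lt(mean(diffs), 0)
  expect_lt(mean(diffs > 0), 0.2)
})

test_that("region MI matrix is symmetric and reflects a shared source", {
  set.seed(38)
  map <- tinyMontage()
  n <- 20000
  src <- rnorm(n)
  x <- matrix(rnorm(10 * n), 10, n)
  reg <- map[names(map)]
  sel <- reg %in% c("F", "L-T")
  x[sel, ] <- x[sel, ] + rep(0.8 * src, each = sum(sel))
  rec <- EEGRecording(x, 1000, names(map), map)
  M <- regionMIMatrix(rec)
  expect_true(isSymmetric(unclass(M)[1:5, 1:5]))
  expect_gt(M["F", "L-T"], 5 * M["P", "O"])
  expect_gt(M["F", "L-T"], M["F", "P"])

  ## a single-channel region reports a missing (NA) diagonal
  map1 <- c(tinyMontage()[-2])                # one frontal channel only
  rec1 <- EEGRecording(matrix(rnorm(9 * 3000), 9, 3000), 1000,
                       names(map1), map1)
  M1 <- regionMIMatrix(rec1)
  expect_true(is.na(M1["F", "F"]))
  expect_false(anyNA(M1["P", ]))
})

test_that("off-diagonal MI of independent channels is uniformly small", {
  set.seed(39)
  rec <- noiseRecording(nSamp = 20000)
  M <- regionMIMatrix(rec)
  off <- M[upper.tri(M)]
  expect_lt(max(off), 0.01)
})
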