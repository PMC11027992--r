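test_that("topography extraction counts windows and computes window SDs", {
  map <- tinyMontage()
  set.seed(41)
  x <- matrix(rnorm(10 * 10000), 10, 10000)
  x[3, ] <- 5                                  # constant channel
  a <- 2.5
  x[5, ] <- a * sin(2 * pi * 10 * (1:10000) / 1000)  # whole cycles per window
  rec <- EEGRecording(x, 1000, names(map), map)
  tp <- extractTopographies(rec, windowMs = 100)
  expect_equal(dim(tp), c(100L, 10L))
  expect_true(all(tp[, 3] == 0))
  expect_equal(unname(tp[, 5]), rep(a / sqrt(2), 100), tolerance = 0.02)

  short <- EEGRecording(x[, 1:50, drop = FALSE], 1000, names(map), map)
  expect_error(extractTopographies(short), "shorter than one window")
})

test_that("k-means recovers well-separated planted templates", {
  skip_if_not_installed("mclust")
  set.seed(42)
  templ <- matrix(rnorm(3 * 12), 3, 12)
  templ <- templ / sqrt(rowSums(templ^2))
  truth <- sample(1:3, 600, replace = TRUE)
  X <- templ[truth, ] + matrix(rnorm(600 * 12, 0, 0.08), 600, 12)
  mod <- fitMicrostates(X, k = 3, seed = 7)
  expect_gte(mclust::adjustedRandIndex(mod@assignments, truth), 0.95)
})

test_that("degenerate clustering requests are rejected", {
  X <- matrix(rnorm(50 * 6), 50, 6)
  expect_error(fitMicrostates(X, k = 1, seed = 1), "minimum of 2")
  expect_error(fitMicrostates(X, k = 51, seed = 1), "exceeds")
  same <- matrix(1, 20, 6)
  expect_error(fitMicrostates(same, k = 2, seed = 1), "degenerate")
})

test_that("occurrence frequencies sum to one per subject for every k", {
  set.seed(43)
  X <- matrix(rnorm(400 * 8), 400, 8)
  ids <- rep(sprintf("s%d", 1:8), each = 50)
  for (k in c(2, 5, 7)) {
    occ <- occurrenceFrequencies(fitMicrostates(X, k, seed = 2,
                                                subjectIds = ids))
    expect_equal(dim(occ), c(8L, k))
    expect_equal(unname(rowSums(occ)), rep(1, 8))
  }
})

test_that("the clusterer agrees with stats::kmeans on separable data", {
  skip_if_not_installed("mclust")
  set.seed(48)
  templ <- 3 * matrix(rnorm(4 * 8), 4, 8)
  truth <- sample(1:4, 500, replace = TRUE)
  X <- templ[truth, ] + matrix(rnorm(500 * 8, 0, 0.3), 500, 8)
  mod <- fitMicrostates(X, 4, seed = 1, normalize = FALSE)
  ref <- stats::kmeans(X, 4, nstart = 10, iter.max = 100)
  expect_equal(mclust::adjustedRandIndex(mod@assignments, ref$cluster), 1)
  expect_lt(abs(mod@totWithinss - ref$tot.withinss) / ref$tot.withinss,
            1e-6)
})

test_that("restarts never keep a worse objective than their first run", {
  set.seed(44)
  X <- matrix(rnorm(300 * 6), 300, 6)
  for (seed in 1:4) {
    w1 <- fitMicrostates(X, 4, seed = seed, nstart = 1)@totWithinss
    w10 <- fitMicrostates(X, 4, seed = seed, nstart = 10)@totWithinss
    expect_lte(w10, w1 + 1e-12)
  }
})

test_that("state statistics flag the ratio-coupled state with its sign", {
  set.seed(45)
  n <- 60
  ratio <- exp(runif(n, log(1e-3), log(0.2)))
  ## occurrence of state 1 falls as the ratio rises
  occ1 <- 0.1 + 0.2 * (1 - scale(log(ratio))[, 1] / 3) + rnorm(n, 0, 0.01)
  occ1 <- pmin(pmax(occ1, 0.02), 0.9)
  occ <- cbind(occ1, matrix((1 - occ1) / 3, n, 3))
  rownames(occ) <- sprintf("s%d", 1:n)
  ## wrap into a model object
  mod <- new("MicrostateModel", k = 4L, centers = matrix(0, 4, 5),
             assignments = rep(1L, n), subjectIds = sprintf("s%d", 1:n),
             occurrence = occ / rowSums(occ), totWithinss = 0,
             normalized = TRUE, seed = 1L)
  st <- stateStatistics(mod, stats::setNames(ratio, sprintf("s%d", 1:n)))
  expect_true(st$significant[1])
  expect_equal(st$direction[1], "negative")

  ## constant occurrence is degenerate, never significant
  occC <- cbind(rep(0.25, n), occ[, 2:4] * 0.75 / rowSums(occ[, 2:4]))
  rownames(occC) <- sprintf("s%d", 1:n)
  modC <- new("MicrostateModel", k = 4L, centers = matrix(0, 4, 5),
              assignments = rep(1L, n), subjectIds = sprintf("s%d", 1:n),
              occurrence = occC, totWithinss = 0, normalized = TRUE,
              seed = 1L)
  stC <- stateStatistics(modC, stats::setNames(ratio, sprintf("s%d", 1:n)))
  expect_true(stC$degenerate[1])
  expect_false(stC$significant[1])

  ## fewer than three subjects is degenerate for a correlation
  occ2 <- occ[1:2, ] / rowSums(occ[1:2, ])
  mod2 <- new("MicrostateModel", k = 4L, centers = matrix(0, 4, 5),
              assignments = rep(1L, 2), subjectIds = c("s1", "s2"),
              occurrence = occ2, totWithinss = 0, normalized = TRUE,
              seed = 1L)
  expect_error(stateStatistics(mod2, stats::setNames(ratio[1:2],
                                                     c("s1", "s2"))),
               "three subjects")
})

test_that("permuted ratios produce ~nominal false-positive rates", {
  set.seed(46)
  n <- 50
  occ <- matrix(runif(n * 5), n, 5)
  occ <- occ / rowSums(occ)
  rownames(occ) <- sprintf("s%d", 1:n)
  mod <- new("MicrostateModel", k = 5L, centers = matrix(0, 5, 4),
             assignments = rep(1L, n), subjectIds = sprintf("s%d", 1:n),
             occurrence = occ, totWithinss = 0, normalized = TRUE, seed = 1L)
  ratio <- exp(runif(n, log(1e-3), log(0.2)))
  hits <- replicate(200, {
    st <- stateStatistics(mod, stats::setNames(sample(ratio),
                                               sprintf("s%d", 1:n)))
    mean(st$significant)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.035)
})

test_that("a cohort-level scan reports statistics per k", {
  set.seed(47)
  X <- matrix(rnorm(300 * 6), 300, 6)
  ids <- rep(sprintf("s%d", 1:10), each = 30)
  ratios <- stats::setNames(exp(runif(10, log(1e-3), log(0.2))),
                            sprintf("s%d", 1:10))
  sc <- scanMicrostates(X, ids, ratios, ks = c(2, 3), seed = 9)
  expect_named(sc, c("k2", "k3"))
  expect_equal(nrow(sc$k3$statistics), 3)
})
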