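test_that("word streams are deterministic and respect the sample range", {
  cfg <- simConfig(samplesPerStory = 5000L, seed = 7L)
  a <- generateWordStream(cfg, 1L)
  b <- generateWordStream(cfg, 1L)
  expect_identical(a$stream@onsets, b$stream@onsets)
  expect_identical(a$embeddings@embeddings, b$embeddings@embeddings)
  c <- generateWordStream(cfg, 2L)
  expect_false(identical(a$stream@onsets, c$stream@onsets))
  expect_true(all(diff(a$stream@onsets) > 0))
  expect_true(all(a$stream@onsets >= 0 & a$stream@onsets < 5000L))
  # flags are consistent sentence bookkeeping
  expect_equal(length(a$stream@sentenceStart), length(a$stream@words))
  expect_true(a$stream@sentenceStart[1])
})

test_that("a story too short for the mean gap still yields at least one word", {
  cfg <- simConfig(samplesPerStory = 50L, meanWordGap = 51, nDelays = 5L,
                   seed = 3L)
  for (i in 1:20) {
    ws <- generateWordStream(cfg, i)
    expect_gte(length(ws$stream@words), 1L)
    expect_true(all(ws$stream@onsets < 50L))
  }
})

test_that("inter-onset gaps follow the configured geometric mean", {
  cfg <- simConfig(samplesPerStory = 250000L, meanWordGap = 20, seed = 11L)
  ws <- generateWordStream(cfg, 1L)
  gaps <- diff(ws$stream@onsets)
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 20), 3 * se)
})

test_that("ground truth is a normalized CP filter with smooth delay rows", {
  cfg <- simConfig(seed = 5L)
  f <- generateGroundTruth(cfg)@filter
  expect_true(f@normalized)
  expect_equal(rowSums(f@delayFactors^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(rowSums(f@embedFactors^2), rep(1, 3), tolerance = 1e-10)
  expect_equal(rowSums(f@channelFactors^2), rep(1, 3), tolerance = 1e-10)
  expect_true(all(f@alpha > 0))
  # determinism and non-degeneracy
  expect_identical(generateGroundTruth(cfg)@filter@delayFactors,
                   f@delayFactors)
  cfg2 <- simConfig(seed = 6L)
  expect_false(identical(generateGroundTruth(cfg2)@filter@delayFactors,
                         f@delayFactors))
})

test_that("rank-1 ground truth expands to an outer product", {
  cfg <- simConfig(rank = 1L, alpha = 2.5, seed = 9L)
  f <- generateGroundTruth(cfg)@filter
  W <- cpExpand(f)@weights
  ref <- 2.5 * outer(outer(f@delayFactors[1, ], f@embedFactors[1, ]),
                     f@channelFactors[1, ])
  expect_equal(W, ref, tolerance = 1e-12)
})

test_that("noiseless recordings equal the dense-filter convolution oracle", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 300L, nChannels = 4L,
                   embedDim = 5L, nDelays = 6L, rank = 2L, noiseSd = 0,
                   seed = 13L)
  gt <- generateGroundTruth(cfg)
  ws <- generateWordStream(cfg, 1L)
  rec <- simulateRecording(ws$stream, ws$embeddings, gt, cfg)
  ser <- buildSeries(ws$stream, ws$embeddings)
  oracle <- bruteForcePredict(cpExpand(gt@filter)@weights, ser)
  expect_equal(rec@signal, oracle, tolerance = 1e-10)
  expect_false(rec@zscored)
})

test_that("zero filter with unit noise gives unit channel variance", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 50000L, nChannels = 4L,
                   embedDim = 5L, nDelays = 6L, rank = 1L, noiseSd = 1,
                   seed = 17L)
  gt <- generateGroundTruth(cfg)
  zero <- new("GroundTruth",
              filter = cpFilter(gt@filter@delayFactors,
                                gt@filter@embedFactors,
                                gt@filter@channelFactors, alpha = 0),
              embedSd = gt@embedSd)
  ws <- generateWordStream(cfg, 1L)
  rec <- simulateRecording(ws$stream, ws$embeddings, zero, cfg)
  v <- apply(rec@signal, 2L, var)
  expect_true(all(abs(v - 1) < 0.05))
})

test_that("recording variance decomposes into signal plus noise variance", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 40000L, nChannels = 6L,
                   embedDim = 8L, nDelays = 8L, rank = 2L, noiseSd = 0.5,
                   seed = 19L)
  gt <- generateGroundTruth(cfg)
  ws <- generateWordStream(cfg, 1L)
  noisy <- simulateRecording(ws$stream, ws$embeddings, gt, cfg)
  cfg0 <- simConfig(nStories = 1L, samplesPerStory = 40000L, nChannels = 6L,
                    embedDim = 8L, nDelays = 8L, rank = 2L, noiseSd = 0,
                    seed = 19L)
  clean <- simulateRecording(ws$stream, ws$embeddings, gt, cfg0)
  vN <- apply(noisy@signal, 2L, var)
  vC <- apply(clean@signal, 2L, var)
  expect_equal(vN, vC + 0.25, tolerance = 0.05)
})

test_that("repeats share the signal and differ only in noise", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 2000L, nChannels = 4L,
                   embedDim = 5L, nDelays = 5L, rank = 2L, noiseSd = 0,
                   nRepeats = 3L, seed = 23L)
  gt <- generateGroundTruth(cfg)
  ws <- generateWordStream(cfg, 1L)
  reps <- simulateRepeats(ws$stream, ws$embeddings, gt, cfg)
  expect_equal(reps@repeats[1, , ], reps@repeats[2, , ], tolerance = 1e-12)

  cfgN <- simConfig(nStories = 1L, samplesPerStory = 2000L, nChannels = 4L,
                    embedDim = 5L, nDelays = 5L, rank = 2L, noiseSd = 0.5,
                    nRepeats = 3L, seed = 23L)
  repsN <- simulateRepeats(ws$stream, ws$embeddings, gt, cfgN)
  expect_false(identical(repsN@repeats[1, , ], repsN@repeats[2, , ]))

  cfgBad <- simConfig(nRepeats = 1L)
  expect_error(simulateRepeats(ws$stream, ws$embeddings, gt, cfgBad),
               "nRepeats")
})

test_that("the repeat mean converges to the signal at the 1/sqrt(n) rate", {
  base <- list(samplesPerStory = 4000L, nChannels = 4L, embedDim = 5L,
               nDelays = 5L, rank = 2L, seed = 29L, nStories = 1L)
  gt <- generateGroundTruth(do.call(simConfig, c(base, noiseSd = 1)))
  ws <- generateWordStream(do.call(simConfig, c(base, noiseSd = 1)), 1L)
  signal <- simulateRecording(ws$stream, ws$embeddings, gt,
                              do.call(simConfig, c(base, noiseSd = 0)))@signal
  rmse <- vapply(c(2L, 32L), function(n) {
    cfg <- do.call(simConfig, c(base, noiseSd = 1, nRepeats = n))
    reps <- simulateRepeats(ws$stream, ws$embeddings, gt, cfg)
    m <- apply(reps@repeats, c(2, 3), mean)
    sqrt(mean((m - signal)^2))
  }, numeric(1))
  # noise sd 1: expected RMSE 1/sqrt(2) vs 1/sqrt(32), ratio 4
  expect_equal(rmse[1] / rmse[2], 4, tolerance = 0.15)
})

test_that("z-scoring centers and scales every channel", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 1000L, seed = 31L)
  ds <- simulateDataset(cfg)
  z <- zscoreRecording(ds@stories[[1]]$recording)
  expect_equal(colMeans(z@signal), rep(0, ncol(z@signal)), tolerance = 1e-12)
  expect_equal(apply(z@signal, 2, sd), rep(1, ncol(z@signal)),
               tolerance = 1e-12)
  expect_true(z@zscored)
})
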