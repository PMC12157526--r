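test_that("cpExpand materializes the component sum exactly", {
  # single basis component -> a single 1 in the tensor
  e <- function(n, i) { v <- numeric(n); v[i] <- 1; v }
  f <- cpFilter(matrix(e(4, 2), 1), matrix(e(3, 3), 1), matrix(e(5, 1), 1),
                alpha = 1)
  W <- cpExpand(f)@weights
  expect_equal(sum(W != 0), 1L)
  expect_equal(W[2, 3, 1], 1)

  # zero alpha -> zero tensor
  f0 <- randomCP(2, 3, 4, 5, seed = 30)
  f0@alpha[] <- 0
  expect_true(all(cpExpand(f0)@weights == 0))

  # random rank-3: per-entry 3-term sum oracle
  f3 <- randomCP(3, 4, 3, 2, seed = 31)
  W3 <- cpExpand(f3)@weights
  for (d in 1:4) for (n in 1:3) for (c in 1:2) {
    ref <- sum(f3@alpha * f3@delayFactors[, d] * f3@embedFactors[, n] *
                 f3@channelFactors[, c])
    expect_equal(W3[d, n, c], ref, tolerance = 1e-12)
  }
})

test_that("factorized prediction equals the dense oracle", {
  f <- randomCP(2, 5, 4, 3, seed = 32)
  ser <- randomSeries(60L, 4L, 10L, seed = 33)

  f0 <- f; f0@alpha[] <- 0
  expect_true(all(predictCP(f0, ser) == 0))

  # event embedding orthogonal to every embedding factor -> zero prediction
  base <- qr.Q(qr(t(rbind(f@embedFactors, c(1, -2, 3, 4)))))
  orth <- base[, 3]  # orthogonal to both rows
  serO <- new("SparseEmbeddingSeries", nSamples = 20L, onsets = 5L,
              embeddings = matrix(orth, 1))
  expect_lt(max(abs(predictCP(f, serO))), 1e-12)

  for (s in 1:10) {
    fs <- randomCP(3, 6, 5, 4, seed = 300 + s)
    ss <- randomSeries(80L, 5L, 12L, seed = 400 + s)
    dense <- predictFull(cpExpand(fs), ss)
    fact <- predictCP(fs, ss)
    expect_lt(max(abs(dense - fact)) / max(abs(dense)), 1e-8)
  }
})

test_that("the loss combines mean squared error and the expanded-tensor penalty", {
  f <- randomCP(2, 4, 3, 4, seed = 34)
  ser <- randomSeries(50L, 3L, 8L, seed = 35)
  pred <- predictCP(f, ser)

  # perfect prediction, lambda 0 -> 0
  expect_equal(cpLoss(f, ser, pred, ridgePenalty = 0), 0, tolerance = 1e-12)

  # zero filter on a z-scored recording, lambda 0 -> about 1
  localSeed(36, {
    M <- scale(matrix(rnorm(50 * 4), 50, 4))
    attr(M, "scaled:center") <- NULL; attr(M, "scaled:scale") <- NULL
    f0 <- f; f0@alpha[] <- 0
    expect_equal(cpLoss(f0, ser, M, ridgePenalty = 0), 49 / 50,
                 tolerance = 1e-10)   # sample-variance denominator T - 1
  })

  # random case: factorized loss equals the direct two-term evaluation
  localSeed(37, {
    M2 <- matrix(rnorm(50 * 4), 50, 4)
    lam <- 0.3
    dense <- cpExpand(f)@weights
    direct <- mean((pred - M2)^2) +
      lam * sum(dense^2) / (4 * 4 * 3)   # C * D * N
    expect_equal(cpLoss(f, ser, M2, ridgePenalty = lam), direct,
                 tolerance = 1e-10)
  })
})

test_that("normalization pulls scales out without changing the tensor", {
  f <- randomCP(3, 5, 4, 6, seed = 38)
  nf <- cpNormalize(f)
  expect_true(nf@normalized)
  expect_equal(rowSums(nf@delayFactors^2), rep(1, 3), tolerance = 1e-12)
  expect_true(all(nf@alpha >= 0))
  expect_equal(cpExpand(nf)@weights, cpExpand(f)@weights, tolerance = 1e-10)

  # idempotence
  nf2 <- cpNormalize(nf)
  expect_equal(nf2@alpha, nf@alpha, tolerance = 1e-12)
  expect_equal(nf2@delayFactors, nf@delayFactors, tolerance = 1e-12)

  # scaling one delay row by 7 multiplies its alpha by 7, tensor invariant
  f7 <- f
  f7@delayFactors[2, ] <- 7 * f7@delayFactors[2, ]
  n7 <- cpNormalize(f7)
  expect_equal(n7@alpha[2], 7 * nf@alpha[2], tolerance = 1e-10)
  expect_equal(cpExpand(n7)@weights, cpExpand(f7)@weights, tolerance = 1e-10)

  # negative scale is absorbed into the channel factor
  fn <- f
  fn@alpha[1] <- -fn@alpha[1]
  nn <- cpNormalize(fn)
  expect_true(all(nn@alpha >= 0))
  expect_equal(cpExpand(nn)@weights, cpExpand(fn)@weights, tolerance = 1e-10)

  fz <- f
  fz@embedFactors[2, ] <- 0
  expect_error(cpNormalize(fz), "degenerate")
})

test_that("the expansion is invariant to paired sign flips of one component", {
  f <- randomCP(2, 4, 3, 5, seed = 39)
  g <- f
  g@delayFactors[1, ] <- -g@delayFactors[1, ]
  g@embedFactors[1, ] <- -g@embedFactors[1, ]
  expect_equal(cpExpand(g)@weights, cpExpand(f)@weights, tolerance = 1e-12)
})

test_that("fitCP recovers a rank-1 filter from noiseless data", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 4000L, nChannels = 5L,
                   embedDim = 6L, nDelays = 5L, rank = 1L, alpha = 2,
                   noiseSd = 0, nRepeats = 2L, seed = 40L)
  ds <- simulateDataset(cfg)
  trS <- list(buildSeries(ds@stories[[1]]$stream, ds@stories[[1]]$embeddings))
  fit <- fitCP(trS, list(ds@stories[[1]]$recording), rank = 1L, nDelays = 5L,
               cfg = trainConfig(maxEpochs = 500L, seed = 41L))
  teS <- buildSeries(ds@testStory$stream, ds@testStory$embeddings)
  pred <- predictCP(fit$filter, teS)
  truthPred <- predictCP(ds@truth@filter, teS)
  cors <- vapply(1:5, function(c) cor(pred[, c], truthPred[, c]), numeric(1))
  expect_true(all(cors > 0.99))
})

test_that("fitCP is deterministic given the seed and rejects bad input", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 800L, nChannels = 4L,
                   embedDim = 5L, nDelays = 4L, rank = 2L, seed = 42L)
  ds <- simulateDataset(cfg)
  trS <- list(buildSeries(ds@stories[[1]]$stream, ds@stories[[1]]$embeddings))
  tc <- trainConfig(maxEpochs = 40L, seed = 43L)
  f1 <- fitCP(trS, list(ds@stories[[1]]$recording), 2L, 4L, tc)
  f2 <- fitCP(trS, list(ds@stories[[1]]$recording), 2L, 4L, tc)
  expect_identical(f1$lossTrace, f2$lossTrace)
  expect_identical(f1$filter@delayFactors, f2$filter@delayFactors)
  expect_error(fitCP(trS, list(), 2L, 4L), "one recording per series")
  expect_error(fitCP(trS, list(ds@stories[[1]]$recording), 0L, 4L), "rank")
})

test_that("mini-batched fitting matches the loss contract on contiguous blocks", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 1200L, nChannels = 4L,
                   embedDim = 5L, nDelays = 4L, rank = 2L, noiseSd = 0.2,
                   seed = 44L)
  ds <- simulateDataset(cfg)
  trS <- list(buildSeries(ds@stories[[1]]$stream, ds@stories[[1]]$embeddings))
  fit <- fitCP(trS, list(ds@stories[[1]]$recording), 2L, 4L,
               trainConfig(maxEpochs = 150L, batchSize = 400L, seed = 45L))
  # three contiguous batches per epoch; the fit must still converge sensibly
  expect_true(all(is.finite(fit$lossTrace)))
  expect_lt(tail(fit$lossTrace, 1), fit$lossTrace[1])
  full <- cpLoss(fit$filter, trS, list(ds@stories[[1]]$recording),
                 ridgePenalty = 0.1)
  expect_equal(tail(fit$lossTrace, 1), full, tolerance = 0.05)
})

test_that("leave-one-out influence matches recomputation from scratch", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 3000L, nChannels = 6L,
                   embedDim = 6L, nDelays = 5L, rank = 3L, noiseSd = 0.3,
                   nRepeats = 3L, seed = 46L)
  ds <- simulateDataset(cfg)
  teS <- buildSeries(ds@testStory$stream, ds@testStory$embeddings)
  reps <- ds@testStory$repeats
  filt <- ds@truth@filter
  infl <- looInfluence(filt, teS, reps)
  cm <- ccMax(reps)$ccmax
  fullMean <- mean(ccNorm(predictCP(filt, teS), reps, cm))
  for (r in 1:3) {
    sub <- cpDropComponents(filt, r)
    oracle <- fullMean - mean(ccNorm(predictCP(sub, teS), reps, cm))
    expect_equal(infl$influence[infl$component == r], oracle,
                 tolerance = 1e-12)
  }
  # a zero-alpha component has zero influence by definition
  f0 <- cpDropComponents(filt, 2L)
  infl0 <- looInfluence(f0, teS, reps)
  expect_equal(infl0$influence[infl0$component == 2L], 0)
})

test_that("duplicated half-scale components have identical influence", {
  f <- cpNormalize(randomCP(1, 5, 4, 6, seed = 47))
  dup <- cpFilter(rbind(f@delayFactors, f@delayFactors),
                  rbind(f@embedFactors, f@embedFactors),
                  rbind(f@channelFactors, f@channelFactors),
                  alpha = rep(f@alpha / 2, 2), normalized = TRUE)
  cfg <- simConfig(nStories = 1L, samplesPerStory = 2000L, nChannels = 6L,
                   embedDim = 4L, nDelays = 5L, rank = 1L, noiseSd = 0.2,
                   nRepeats = 3L, seed = 48L)
  ws <- generateWordStream(cfg, 99L)
  gt <- new("GroundTruth", filter = f, embedSd = rep(1, 4))
  reps <- simulateRepeats(ws$stream, ws$embeddings, gt, cfg)
  ser <- buildSeries(ws$stream, ws$embeddings)
  infl <- looInfluence(dup, ser, reps)
  expect_equal(infl$influence[1], infl$influence[2], tolerance = 1e-12)
})

test_that("matchComponents undoes a known permutation and sign flip", {
  ref <- cpNormalize(randomCP(3, 6, 5, 7, seed = 49))
  perm <- c(3L, 1L, 2L)
  est <- cpFilter(ref@delayFactors[perm, ],
                  -ref@embedFactors[perm, ],
                  -ref@channelFactors[perm, ],
                  alpha = ref@alpha[perm], normalized = TRUE)
  m <- matchComponents(est, ref)
  expect_equal(m$est[perm], 1:3)
  expect_equal(m$corDelay, rep(1, 3), tolerance = 1e-10)
  expect_equal(m$corEmbed, rep(1, 3), tolerance = 1e-10)
  expect_equal(m$corChannel, rep(1, 3), tolerance = 1e-10)
  expect_equal(m$alphaEst, ref@alpha, tolerance = 1e-12)
})
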