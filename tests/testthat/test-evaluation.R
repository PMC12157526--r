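test_that("ccMax is 1 for identical repeats and clamps pure noise", {
  localSeed(50, {
    sig <- matrix(rnorm(500 * 3), 500, 3)
    reps <- repeatSet(list(sig, sig, sig))
    cm <- ccMax(reps)
    expect_equal(cm$ccmax, rep(1, 3), tolerance = 1e-10)
    expect_false(any(cm$clamped))

    noise <- repeatSet(lapply(1:4, function(k) matrix(rnorm(600 * 3), 600, 3)))
    cmN <- ccMax(noise)
    expect_true(all(cmN$ccmax[cmN$clamped] == 0.2))
    expect_true(mean(cmN$clamped) > 0.5)  # almost surely all clamped

    # constant channel never propagates NaN
    const <- repeatSet(lapply(1:3, function(k) matrix(1, 100, 2)))
    cmC <- ccMax(const)
    expect_equal(cmC$ccmax, c(0.2, 0.2))
    expect_true(all(cmC$clamped))
  })
})

test_that("ccMax matches the closed-form ceiling for known signal and noise", {
  # signal sd 1, noise sd 1, 5 repeats: CCmax -> sqrt(1 / (1 + 1/5))
  localSeed(51, {
    T <- 20000L
    sig <- matrix(rnorm(T * 4), T, 4)
    reps <- repeatSet(lapply(1:5, function(k) sig + matrix(rnorm(T * 4), T, 4)))
    cm <- ccMax(reps)
    expect_equal(cm$ccmax, rep(sqrt(1 / (1 + 1 / 5)), 4), tolerance = 0.03)
  })
})

test_that("ccNorm normalizes the repeat-mean correlation by the ceiling", {
  localSeed(52, {
    sig <- matrix(rnorm(800 * 3), 800, 3)
    noiseless <- repeatSet(list(sig, sig))
    expect_equal(ccNorm(sig, noiseless), rep(1, 3), tolerance = 1e-10)
    # antisymmetry against the clamp floor
    noisy <- repeatSet(lapply(1:3, function(k) sig + matrix(rnorm(2400), 800, 3)))
    cm <- ccMax(noisy)$ccmax
    ybar <- apply(noisy@repeats, c(2, 3), mean)
    expect_equal(ccNorm(-ybar, noisy, cm), -1 / cm, tolerance = 1e-10)
    # zero-variance prediction channel -> 0
    flat <- sig; flat[, 2] <- 0
    cn <- ccNorm(flat, noiseless)
    expect_equal(cn[2], 0)
    expect_equal(cn[c(1, 3)], rep(1, 2), tolerance = 1e-10)
  })
})

test_that("CCnorm approaches 1 when predicting with the generating filter", {
  cfg <- simConfig(nStories = 1L, samplesPerStory = 8000L, nChannels = 6L,
                   embedDim = 8L, nDelays = 6L, rank = 2L, noiseSd = 0.05,
                   nRepeats = 4L, seed = 53L)
  ds <- simulateDataset(cfg)
  teS <- buildSeries(ds@testStory$stream, ds@testStory$embeddings)
  ev <- evaluateModel(predictCP(ds@truth@filter, teS), ds@testStory$repeats)
  expect_equal(meanCCnorm(ev), 1, tolerance = 0.05)
})

test_that("excess CCmax localizes injected post-onset structure", {
  localSeed(54, {
    T <- 4000L; C <- 4L
    onsets <- sort(sample(0:(T - 50L), 120L))
    # stationary noise-free repeats -> excess about 0 everywhere
    sig <- matrix(rnorm(T * C), T, C)
    flat <- excessCCmax(repeatSet(list(sig, sig)), onsets, rateHz = 50)
    expect_equal(dim(flat), c(8L, C))
    expect_lt(max(abs(flat)), 0.05)

    # signal present only 100-200 ms (samples 5..9) after each onset
    base <- matrix(0, T, C)
    for (tau in onsets) {
      rows <- tau + 5:9 + 1L
      rows <- rows[rows <= T]
      base[rows, ] <- base[rows, ] + rnorm(1)
    }
    reps <- repeatSet(lapply(1:4, function(k)
      base + matrix(rnorm(T * C), T, C)))
    ex <- excessCCmax(reps, onsets, rateHz = 50)
    expect_equal(unname(which.max(rowMeans(ex))), 2L)
  })
})

test_that("post-onset windows tile the lag axis once for well-spaced onsets", {
  onsets <- seq(0L, 3900L, by = 100L)   # 2 s apart at 50 Hz: no overlap
  T <- 4000L
  localSeed(55, {
    sig <- matrix(rnorm(T * 2), T, 2)
    reps <- repeatSet(list(sig, sig + 0.1 * matrix(rnorm(T * 2), T, 2)))
    # count samples each window selects: 5 per onset, disjoint across windows
    counts <- integer(8)
    sel <- vector("list", 8)
    for (k in 1:8) {
      lags <- (k - 1L) * 5L + 0:4
      s <- unique(unlist(lapply(lags, function(d) onsets + d)))
      sel[[k]] <- sort(s[s >= 0 & s < T])
      counts[k] <- length(sel[[k]])
    }
    expect_true(all(counts == length(onsets) * 5L))
    expect_equal(length(unique(unlist(sel))), sum(counts))  # disjoint
    # and the implementation accepts exactly these subsets
    ex <- excessCCmax(reps, onsets, rateHz = 50)
    expect_equal(nrow(ex), 8L)
  })
})

test_that("excessPCA decomposes the window-by-channel matrix", {
  localSeed(56, {
    a <- rnorm(8); b <- rnorm(12)
    rank1 <- outer(a, b)
    p1 <- excessPCA(rank1)
    expect_gt(p1$explainedVarianceRatio[1], 1 - 1e-10)
    expect_lte(sum(p1$explainedVarianceRatio), 1 + 1e-12)

    # two orthogonal channel patterns are recovered up to sign
    u <- qr.Q(qr(matrix(rnorm(24), 12, 2)))
    # mean-zero orthonormal timecourses (orthogonal to the constant), with
    # distinct power so the PC order is determined
    tc <- qr.Q(qr(cbind(1, matrix(rnorm(16), 8, 2))))[, 2:3] %*% diag(c(3, 1))
    M <- tc %*% t(u)
    p2 <- excessPCA(M)
    align <- abs(crossprod(p2$loadings, u))
    expect_equal(sort(diag(align), decreasing = TRUE), c(1, 1),
                 tolerance = 1e-8)
  })
})

test_that("bootstrap comparison behaves at the extremes and matches enumeration", {
  localSeed(57, {
    b <- rnorm(30)
    expect_equal(bootstrapCompare(b + 1, b, nBoot = 500L, seed = 1L), 0)
    # exchangeable inputs: p averages to about 0.5 over datasets
    ps <- vapply(1:200, function(i) {
      x <- rnorm(8); y <- rnorm(8)
      bootstrapCompare(x, y, nBoot = 300L, seed = i)
    }, numeric(1))
    expect_lt(abs(mean(ps) - 0.5), 0.06)
  })
  # exhaustive enumeration oracle at C = 5
  d <- c(-0.8, -0.1, 0.3, 0.5, 1.1)
  grids <- expand.grid(rep(list(1:5), 5))
  exact <- mean(apply(grids, 1, function(idx) mean(d[idx]) <= 0))
  est <- bootstrapCompare(d, rep(0, 5), nBoot = 40000L, seed = 2L)
  expect_equal(est, exact, tolerance = 0.01)
  expect_warning(bootstrapCompare(1:5, 5:1, nBoot = 50L, seed = 1L),
                 "coarse")
})

test_that("the permutation test is extreme for a perfect prediction", {
  localSeed(58, {
    sig <- matrix(rnorm(3000 * 3), 3000, 3)
    reps <- repeatSet(lapply(1:3, function(k)
      sig + 0.5 * matrix(rnorm(9000), 3000, 3)))
    ybar <- apply(reps@repeats, c(2, 3), mean)
    out <- permutationTest(ybar, reps, nPerm = 99L, blockLen = 50L, seed = 3L)
    expect_equal(out$p, 1 / 100)
    expect_equal(length(out$null), 99L)
    # all null shifts are at least blockLen away from zero lag
    expect_true(all(abs(out$null) < out$observed))
    expect_error(permutationTest(ybar[1:80, ], repeatSet(
      lapply(1:3, function(k) reps@repeats[k, 1:80, ])),
      nPerm = 10L, blockLen = 50L), "too short")
  })
})
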