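#' Create a synthetic-dataset configuration
#'
#' Defaults emulate naturalistic-listening recordings on a 50 Hz grid: word
#' onsets arrive with a geometric gap law (mean 20 samples = 400 ms),
#' embeddings have a geometrically decaying eigenspectrum so that a modest
#' number of directions carries most of the variance, the ground-truth filter
#' is a sum of smooth rank-1 delay/embedding/channel components with
#' well-separated scales, and channel noise is white Gaussian.
#'
#' @param nStories number of training stories.
#' @param samplesPerStory samples per story.
#' @param nChannels channels.
#' @param embedDim embedding dimension.
#' @param nDelays filter delays.
#' @param rank ground-truth rank.
#' @param meanWordGap mean inter-word gap in samples.
#' @param noiseSd additive channel noise sd.
#' @param nRepeats repeats of the held-out story.
#' @param seed RNG seed.
#' @param embedDecay geometric decay of the embedding eigenvalues.
#' @param alpha component scales, decreasing by default.
#' @param rateHz sampling rate.
#' @return a [SimConfig-class]
#' @export
simConfig <- function(nStories = 3L, samplesPerStory = 30000L,
                      nChannels = 20L, embedDim = 15L, nDelays = 10L,
                      rank = 3L, meanWordGap = 20, noiseSd = 0.1,
                      nRepeats = 5L, seed = 1L, embedDecay = 0.85,
                      alpha = rev(seq_len(rank)), rateHz = 50) {
  new("SimConfig",
      nStories = as.integer(nStories),
      samplesPerStory = as.integer(samplesPerStory),
      nChannels = as.integer(nChannels),
      embedDim = as.integer(embedDim),
      nDelays = as.integer(nDelays),
      rank = as.integer(rank),
      meanWordGap = as.numeric(meanWordGap),
      noiseSd = as.numeric(noiseSd),
      nRepeats = as.integer(nRepeats),
      seed = as.integer(seed),
      embedDecay = as.numeric(embedDecay),
      alpha = as.numeric(alpha),
      rateHz = as.numeric(rateHz))
}

# smooth unit-norm Gaussian bump over D delays
.gaussBump <- function(D) {
  ctr <- stats::runif(1, 0, D - 1)
  width <- stats::runif(1, max(D / 10, 0.5), max(D / 4, 1))
  v <- exp(-((seq_len(D) - 1) - ctr)^2 / (2 * width^2))
  v / sqrt(sum(v^2))
}

.unitVec <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

#' Generate the ground truth of a synthetic dataset
#'
#' Draws a normalized CP filter with smooth Gaussian-bump delay factors,
#' random unit embedding and channel factors, and the configured positive
#' component scales, plus the diagonal embedding covariance from which word
#' embeddings are drawn. Deterministic given `cfg@seed`.
#'
#' @param cfg a [SimConfig-class]
#' @return a [GroundTruth-class]
#' @export
generateGroundTruth <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  withSeed(deriveSeed(cfg@seed, 0L), {
    R <- cfg@rank
    UD <- t(vapply(seq_len(R), function(r) .gaussBump(cfg@nDelays),
                   numeric(cfg@nDelays)))
    UE <- t(vapply(seq_len(R), function(r) .unitVec(cfg@embedDim),
                   numeric(cfg@embedDim)))
    UC <- t(vapply(seq_len(R), function(r) .unitVec(cfg@nChannels),
                   numeric(cfg@nChannels)))
    filt <- new("CPFilter", delayFactors = UD, embedFactors = UE,
                channelFactors = UC, alpha = cfg@alpha, normalized = TRUE)
    sds <- sqrt(cfg@embedDecay^(seq_len(cfg@embedDim) - 1))
    new("GroundTruth", filter = filt, embedSd = sds)
  })
}

#' Generate a word stream and its embeddings for one story
#'
#' Inter-onset gaps are geometric with the configured mean (memoryless,
#' stationary). Sentence lengths are uniform on 4..15 words; the first word
#' of each sentence is flagged as a start, the last as an end. Embeddings
#' are zero-mean Gaussian with the configured diagonal covariance. The first
#' onset is forced into `[0, T)` so a stream never has zero words.
#' Deterministic given `(cfg@seed, storyIndex)`.
#'
#' @param cfg a [SimConfig-class]
#' @param storyIndex 1-based story index (the held-out story uses
#'   `nStories + 1` by convention).
#' @return list with `stream` ([WordStream-class]) and `embeddings`
#'   ([EmbeddingSet-class])
#' @export
generateWordStream <- function(cfg, storyIndex) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  T <- cfg@samplesPerStory
  if (T < 1L)
    stop("story too short to place at least one word")
  withSeed(deriveSeed(cfg@seed, storyIndex), {
    p <- 1 / cfg@meanWordGap
    # draw more gaps than can fit, then truncate
    nMax <- max(16L, ceiling(2.5 * T / cfg@meanWordGap) + 16L)
    gaps <- 1L + stats::rgeom(nMax, p)
    onsets <- cumsum(gaps) - 1L          # 0-based
    onsets[1L] <- min(onsets[1L], T - 1L)  # never zero words
    onsets <- onsets[onsets < T]
    while (onsets[length(onsets)] < T - 1L &&
           (last <- onsets[length(onsets)] + 1L + stats::rgeom(1L, p)) < T)
      onsets <- c(onsets, last)
    S <- length(onsets)
    # Markov sentence process: lengths uniform on 4..15
    starts <- logical(S); ends <- logical(S)
    j <- 1L
    while (j <= S) {
      len <- sample(4:15, 1L)
      starts[j] <- TRUE
      ends[min(j + len - 1L, S)] <- TRUE
      j <- j + len
    }
    words <- paste0("w", storyIndex, "_", seq_len(S))
    emb <- matrix(stats::rnorm(S * cfg@embedDim), S, cfg@embedDim)
    sds <- sqrt(cfg@embedDecay^(seq_len(cfg@embedDim) - 1))
    emb <- emb * rep(sds, each = S)
    list(
      stream = new("WordStream", words = words, onsets = as.integer(onsets),
                   sentenceStart = starts, sentenceEnd = ends,
                   storyId = paste0("story", storyIndex),
                   nSamples = T),
      embeddings = new("EmbeddingSet", embeddings = emb,
                       contextLen = 20L, provenance = "synthetic")
    )
  })
}

#' Simulate one story's recording from a ground-truth filter
#'
#' Forward-predicts the sparse embedding series through the ground-truth CP
#' filter and adds i.i.d. Gaussian channel noise. The result is *not*
#' z-scored; normalization is an explicit separate step
#' (see [zscoreRecording()]).
#'
#' @param stream a [WordStream-class]
#' @param embeddings matching [EmbeddingSet-class]
#' @param truth a [GroundTruth-class]
#' @param cfg a [SimConfig-class]
#' @param noiseSeed seed for the noise draw
#' @return a [StoryRecording-class]
#' @export
simulateRecording <- function(stream, embeddings, truth, cfg,
                              noiseSeed = deriveSeed(cfg@seed, 10000L)) {
  stopifnot_dim(ncol(embeddings@embeddings) == embedDim(truth@filter),
                "embedding dimension does not match ground-truth filter")
  stopifnot_dim(cfg@nChannels == nChannels(truth@filter),
                "channel count does not match ground-truth filter")
  series <- buildSeries(stream, embeddings, stream@nSamples)
  signal <- predictSeries(truth@filter, series)
  noisy <- withSeed(noiseSeed, {
    signal + matrix(stats::rnorm(length(signal), sd = cfg@noiseSd),
                    nrow(signal), ncol(signal))
  })
  new("StoryRecording", signal = noisy, rateHz = cfg@rateHz,
      zscored = FALSE, storyId = stream@storyId)
}

#' Simulate repeated presentations of one story
#'
#' All repeats share the deterministic filter-driven signal; noise is drawn
#' independently per repeat.
#'
#' @inheritParams simulateRecording
#' @return a [RepeatSet-class]
#' @export
simulateRepeats <- function(stream, embeddings, truth, cfg,
                            noiseSeed = deriveSeed(cfg@seed, 20000L)) {
  if (cfg@nRepeats < 2L)
    stop("nRepeats must be >= 2: the noise ceiling is undefined otherwise")
  series <- buildSeries(stream, embeddings, stream@nSamples)
  signal <- predictSeries(truth@filter, series)
  T <- nrow(signal); C <- ncol(signal)
  reps <- withSeed(noiseSeed, {
    arr <- array(0, dim = c(cfg@nRepeats, T, C))
    for (k in seq_len(cfg@nRepeats))
      arr[k, , ] <- signal +
        matrix(stats::rnorm(T * C, sd = cfg@noiseSd), T, C)
    arr
  })
  new("RepeatSet", repeats = reps, rateHz = cfg@rateHz)
}

#' Simulate a complete dataset
#'
#' Generates the ground truth, `nStories` training stories with recordings,
#' and one extra held-out story presented `nRepeats` times.
#'
#' @param cfg a [SimConfig-class]
#' @return a [StoryDataset-class]
#' @export
simulateDataset <- function(cfg) {
  truth <- generateGroundTruth(cfg)
  stories <- lapply(seq_len(cfg@nStories), function(i) {
    ws <- generateWordStream(cfg, i)
    rec <- simulateRecording(ws$stream, ws$embeddings, truth, cfg,
                             noiseSeed = deriveSeed(cfg@seed, 10000L + i))
    list(stream = ws$stream, embeddings = ws$embeddings, recording = rec)
  })
  wsTest <- generateWordStream(cfg, cfg@nStories + 1L)
  reps <- simulateRepeats(wsTest$stream, wsTest$embeddings, truth, cfg)
  new("StoryDataset", stories = stories,
      testStory = list(stream = wsTest$stream,
                       embeddings = wsTest$embeddings, repeats = reps),
      truth = truth, config = cfg)
}

#' Z-score a recording per channel
#'
#' Explicit normalization step: each channel is centered and scaled to unit
#' variance. Applied per story before model fitting.
#'
#' @param recording a [StoryRecording-class]
#' @return a z-scored [StoryRecording-class]
#' @export
zscoreRecording <- function(recording) {
  m <- recording@signal
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0))
    stop("cannot z-score: constant channel(s) ",
         paste(which(sdv == 0), collapse = ", "))
  new("StoryRecording",
      signal = sweep(sweep(m, 2L, mu), 2L, sdv, "/"),
      rateHz = recording@rateHz, zscored = TRUE,
      storyId = recording@storyId)
}
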