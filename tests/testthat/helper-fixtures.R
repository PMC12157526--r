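# fixtures built in code; all randomness goes through withr-free local seeds

localSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

randomCP <- function(R, D, N, C, seed = 1, normalized = FALSE) {
  localSeed(seed, {
    f <- cpFilter(matrix(rnorm(R * D), R, D), matrix(rnorm(R * N), R, N),
                  matrix(rnorm(R * C), R, C), alpha = runif(R, 0.5, 2))
    if (normalized) cpNormalize(f) else f
  })
}

randomSeries <- function(T, N, nEvents, seed = 1) {
  localSeed(seed, {
    onsets <- sort(sample(0:(T - 1L), nEvents))
    new("SparseEmbeddingSeries", nSamples = as.integer(T),
        onsets = as.integer(onsets),
        embeddings = matrix(rnorm(nEvents * N), nEvents, N))
  })
}

# independent oracle: materialize the dense filter and apply the forward
# model by direct triple summation over t, d, n
bruteForcePredict <- function(weights, series) {
  X <- denseSeries(series)
  D <- dim(weights)[1L]; N <- dim(weights)[2L]; C <- dim(weights)[3L]
  T <- nrow(X)
  pred <- matrix(0, T, C)
  for (t in seq_len(T)) {
    for (d in 0:(D - 1L)) {
      if (t - d >= 1L) {
        for (n in seq_len(N)) {
          if (X[t - d, n] != 0)
            pred[t, ] <- pred[t, ] + weights[d + 1L, n, ] * X[t - d, n]
        }
      }
    }
  }
  pred
}

emptyStream <- function(T = 100L, id = "empty") {
  new("WordStream", words = character(0), onsets = integer(0),
      sentenceStart = logical(0), sentenceEnd = logical(0),
      storyId = id, nSamples = as.integer(T))
}

makeStream <- function(onsets, T, starts = NULL, ends = NULL, id = "s") {
  n <- length(onsets)
  new("WordStream", words = paste0("w", seq_len(n)),
      onsets = as.integer(onsets),
      sentenceStart = if (is.null(starts)) rep(FALSE, n) else starts,
      sentenceEnd = if (is.null(ends)) rep(FALSE, n) else ends,
      storyId = id, nSamples = as.integer(T))
}

embSet <- function(m) new("EmbeddingSet", embeddings = m, contextLen = 20L,
                          provenance = "test")

# minimal 16-bit PCM mono WAV writer (test-side reference, independent of
# the package reader)
writeWav16 <- function(wave, rate, path) {
  pcm <- as.integer(pmax(pmin(round(wave * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSize <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + dataSize, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
}
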