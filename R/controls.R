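#' Read a PCM WAV file
#'
#' Minimal reader for uncompressed 8/16/32-bit PCM and 32-bit float WAV.
#' Multichannel audio is averaged to mono.
#'
#' @param path WAV file path
#' @return list with `wave` (numeric vector in [-1, 1]) and `rate` (Hz)
#' @export
readWavPCM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  while (is.null(data)) {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("truncated WAV file")
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audioFormat = sum(as.integer(raw[1:2]) * c(1, 256)),
        nChannels = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt)) stop("WAV data chunk before fmt chunk")
      n <- size %/% (fmt$bits %/% 8L)
      data <- if (fmt$audioFormat == 3L) {
        readBin(con, "double", n, size = 4L, endian = "little")
      } else if (fmt$bits == 16L) {
        readBin(con, "integer", n, size = 2L, signed = TRUE,
                endian = "little") / 32768
      } else if (fmt$bits == 8L) {
        (readBin(con, "integer", n, size = 1L, signed = FALSE,
                 endian = "little") - 128) / 128
      } else if (fmt$bits == 32L) {
        readBin(con, "integer", n, size = 4L, endian = "little") / 2^31
      } else stop("unsupported WAV bit depth: ", fmt$bits)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (fmt$nChannels > 1L) {
    data <- rowMeans(matrix(data, ncol = fmt$nChannels, byrow = TRUE))
  }
  list(wave = data, rate = fmt$rate)
}

# triangular mel filterbank (HTK mel scale), nMels x nBins
.melFilterbank <- function(nMels, nFFT, rate, fMin = 0, fMax = rate / 2) {
  hz2mel <- function(f) 2595 * log10(1 + f / 700)
  mel2hz <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- mel2hz(seq(hz2mel(fMin), hz2mel(fMax), length.out = nMels + 2L))
  bins <- floor((nFFT + 1) * pts / rate)
  nBins <- nFFT %/% 2L + 1L
  fb <- matrix(0, nMels, nBins)
  for (m in seq_len(nMels)) {
    l <- bins[m]; c <- bins[m + 1L]; r <- bins[m + 2L]
    if (c > l) for (k in (l + 1L):c) fb[m, k + 1L] <- (k - l) / (c - l)
    if (r > c) for (k in (c + 1L):r)
      if (k + 1L <= nBins) fb[m, k + 1L] <- (r - k) / (r - c)
  }
  fb
}

#' Log-mel spectrogram control features on the recording grid
#'
#' Resamples the audio to `targetRate` (default 16 kHz), computes a Hann-
#' windowed power spectrogram with the given FFT size and a 25 ms hop,
#' applies an 80-band triangular mel filterbank, takes the log with a small
#' floor (so silence maps to `log(floor)` rather than -Inf), and linearly
#' interpolates the frames onto the recording's sample grid.
#'
#' @param wave numeric waveform
#' @param rate waveform sampling rate in Hz
#' @param nSamples number of samples of the target recording grid
#' @param gridRateHz recording grid rate (default 50 Hz)
#' @param nMels mel bands (default 80)
#' @param hopMs hop length in ms (default 25)
#' @param nFFT FFT size at the target rate (default 2048)
#' @param targetRate analysis rate (default 16000 Hz)
#' @param epsRel log floor, relative to the maximum mel power
#' @return nSamples x nMels matrix
#' @export
logMelFeatures <- function(wave, rate, nSamples, gridRateHz = 50,
                           nMels = 80L, hopMs = 25, nFFT = 2048L,
                           targetRate = 16000, epsRel = 1e-10) {
  if (any(!is.finite(wave))) stop("waveform must be finite")
  if (rate != targetRate) {
    wave <- signal::resample(wave, p = targetRate, q = rate)
  }
  hop <- as.integer(round(targetRate * hopMs / 1000))
  if (length(wave) < nFFT)
    wave <- c(wave, numeric(nFFT - length(wave)))
  starts <- seq(1L, length(wave) - nFFT + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nFFT) / nFFT)  # Hann
  frames <- vapply(starts, function(s) wave[s:(s + nFFT - 1L)] * win,
                   numeric(nFFT))
  spec <- stats::mvfft(frames)
  power <- abs(spec[seq_len(nFFT %/% 2L + 1L), , drop = FALSE])^2
  fb <- .melFilterbank(nMels, nFFT, targetRate)
  mel <- t(fb %*% power)                      # frames x nMels
  floorVal <- max(mel) * epsRel
  if (floorVal <= 0) floorVal <- epsRel       # silent audio
  mel <- log(pmax(mel, floorVal))
  # frame centers in seconds -> interpolate onto the recording grid
  frameT <- (starts - 1L + nFFT / 2) / targetRate
  gridT <- (seq_len(nSamples) - 1L) / gridRateHz
  out <- matrix(0, nSamples, nMels)
  for (m in seq_len(nMels))
    out[, m] <- stats::approx(frameT, mel[, m], xout = gridT, rule = 2)$y
  out
}

#' Binary event control features
#'
#' Word onsets, sentence starts and sentence ends as binary sequences: 1 at
#' the samples where the event occurs, 0 elsewhere.
#'
#' @param stream a [WordStream-class]
#' @param length series length T
#' @return T x 3 matrix with columns `word_onset`, `sentence_start`,
#'   `sentence_end`
#' @export
eventFeatures <- function(stream, length = stream@nSamples) {
  if (base::length(stream@onsets) > 0L && max(stream@onsets) >= length)
    stop("onsets beyond series length")
  out <- matrix(0, length, 3L,
                dimnames = list(NULL, c("word_onset", "sentence_start",
                                        "sentence_end")))
  out[stream@onsets + 1L, 1L] <- 1
  out[stream@onsets[stream@sentenceStart] + 1L, 2L] <- 1
  out[stream@onsets[stream@sentenceEnd] + 1L, 3L] <- 1
  out
}

# lag a T x P feature matrix to T x (P * delays), zero-padded at the start
.lagFeatures <- function(feat, nDelays) {
  T <- nrow(feat); P <- ncol(feat)
  out <- matrix(0, T, P * nDelays)
  for (d in 0:(nDelays - 1L)) {
    out[(d + 1L):T, (d * P + 1L):((d + 1L) * P)] <-
      feat[seq_len(T - d), , drop = FALSE]
  }
  out
}

#' Assemble the low-level control design for one story
#'
#' Lagged log-mel spectrogram (15 delays by default) plus the binary event
#' features (unlagged by default; set `eventDelays > 1` to lag them equally),
#' and an intercept column.
#'
#' @param melFeatures T x nMels matrix from [logMelFeatures()], or NULL to
#'   use event features only
#' @param stream a [WordStream-class]
#' @param length series length T
#' @param melDelays delays applied to the spectrogram (default 15)
#' @param eventDelays delays applied to the event features (default 1 = no
#'   lagging)
#' @return T x P control design matrix (first column is the intercept)
#' @export
buildControlDesign <- function(melFeatures = NULL, stream,
                               length = stream@nSamples, melDelays = 15L,
                               eventDelays = 1L) {
  parts <- list(matrix(1, length, 1L))
  if (!is.null(melFeatures)) {
    if (nrow(melFeatures) != length)
      stop("mel features must be aligned to the recording grid")
    parts <- c(parts, list(.lagFeatures(melFeatures, melDelays)))
  }
  ev <- eventFeatures(stream, length)
  parts <- c(parts, list(if (eventDelays > 1L) .lagFeatures(ev, eventDelays)
                         else ev))
  do.call(cbind, parts)
}

#' Residualize recordings against low-level control features
#'
#' Fits a ridge-less full-rank (ordinary least squares) model of the
#' recordings on the control designs over the *combined* train and test
#' stories (the default, `mode = "joint"`; a conventional `"train-only"`
#' mode fits on training stories and applies the fit to all), subtracts the
#' control prediction everywhere, and re-z-scores the residuals per channel
#' per story so subsequent model fitting sees normalized inputs.
#'
#' Residualization is a projection: applying it twice changes nothing beyond
#' numerical tolerance (exactly, for a single story, thanks to the intercept
#' column and per-channel scaling).
#'
#' @param recordings list of [StoryRecording-class] (or T x C matrices)
#' @param controlDesigns list of matching T x P control design matrices
#' @param mode `"joint"` (fit on all stories, reproducing the reference
#'   procedure) or `"train-only"`
#' @param trainStories indices of training stories (used by `"train-only"`)
#' @param rezscore re-z-score residuals per channel per story (default TRUE)
#' @return list with `residuals` (list of [StoryRecording-class]) and `coef`
#'   (P x C control coefficients)
#' @export
residualize <- function(recordings, controlDesigns,
                        mode = c("joint", "train-only"),
                        trainStories = seq_along(recordings),
                        rezscore = TRUE) {
  mode <- match.arg(mode)
  mats <- lapply(recordings, function(r)
    if (is(r, "StoryRecording")) r@signal else r)
  for (i in seq_along(mats))
    if (nrow(mats[[i]]) != nrow(controlDesigns[[i]]))
      stop(sprintf("control design %d not aligned to its recording", i))
  fitIdx <- if (mode == "joint") seq_along(mats) else trainStories
  X <- do.call(rbind, controlDesigns[fitIdx])
  Y <- do.call(rbind, mats[fitIdx])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient control design: using pseudo-inverse solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
    W <- sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], Y))
  } else {
    W <- qr.coef(qrX, Y)
  }
  W <- as.matrix(W)
  res <- lapply(seq_along(mats), function(i) {
    resid <- mats[[i]] - controlDesigns[[i]] %*% W
    rec <- recordings[[i]]
    out <- new("StoryRecording", signal = resid,
               rateHz = if (is(rec, "StoryRecording")) rec@rateHz else 50,
               zscored = FALSE,
               storyId = if (is(rec, "StoryRecording")) rec@storyId
                         else paste0("story", i))
    if (rezscore) zscoreRecording(out) else out
  })
  list(residuals = res, coef = W)
}
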