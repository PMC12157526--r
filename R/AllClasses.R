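#' @import methods
NULL

#' WordStream: timed word events for one story
#'
#' Ordered word events with onset samples and sentence-boundary flags. Onsets
#' are 0-based sample indices on the recording grid of the story the stream
#' belongs to.
#'
#' @slot words character vector of word tokens.
#' @slot onsets integer vector of 0-based onset samples, non-decreasing,
#'   each in `[0, nSamples)`.
#' @slot sentenceStart,sentenceEnd logical flags, same length as `words`.
#' @slot storyId single character identifier.
#' @slot nSamples number of samples T of the story's recording grid.
#' @export
setClass("WordStream",
  representation(
    words = "character",
    onsets = "integer",
    sentenceStart = "logical",
    sentenceEnd = "logical",
    storyId = "character",
    nSamples = "integer"
  )
)

setValidity("WordStream", function(object) {
  n <- length(object@words)
  if (length(object@onsets) != n ||
      length(object@sentenceStart) != n ||
      length(object@sentenceEnd) != n)
    return("words, onsets and sentence flags must have equal length")
  if (length(object@nSamples) != 1L || object@nSamples < 1L)
    return("nSamples must be a single positive integer")
  if (n > 0L) {
    if (is.unsorted(object@onsets))
      return("onsets must be non-decreasing")
    if (min(object@onsets) < 0L || max(object@onsets) >= object@nSamples)
      return(sprintf("onsets must lie in [0, %d)", object@nSamples))
  }
  TRUE
})

#' EmbeddingSet: per-word embedding matrix
#'
#' One embedding row per word of a paired [WordStream]. Embeddings are
#' treated as given numeric input (e.g. PCA-reduced language-model states).
#'
#' @slot embeddings S x N numeric matrix, one row per word.
#' @slot contextLen number of context words the embeddings encode.
#' @slot provenance free-text tag describing where the embeddings came from.
#' @export
setClass("EmbeddingSet",
  representation(
    embeddings = "matrix",
    contextLen = "integer",
    provenance = "character"
  )
)

setValidity("EmbeddingSet", function(object) {
  if (!is.numeric(object@embeddings))
    return("embeddings must be numeric")
  if (any(!is.finite(object@embeddings)))
    return("embeddings must be finite")
  TRUE
})

#' SparseEmbeddingSeries: event-sparse embedding time series
#'
#' The T x N embedding time series X that is zero everywhere except at word
#' onsets, stored sparsely as (onset, embedding-row) events. Words sharing a
#' sample are merged into one event whose embedding is their sum, as the
#' linear model requires.
#'
#' @slot nSamples series length T.
#' @slot onsets strictly increasing 0-based event samples.
#' @slot embeddings events x N matrix, one row per event.
#' @export
setClass("SparseEmbeddingSeries",
  representation(
    nSamples = "integer",
    onsets = "integer",
    embeddings = "matrix"
  )
)

setValidity("SparseEmbeddingSeries", function(object) {
  if (length(object@onsets) != nrow(object@embeddings))
    return("one embedding row per event required")
  if (length(object@onsets) > 0L) {
    if (any(diff(object@onsets) <= 0L))
      return("event onsets must be strictly increasing")
    if (min(object@onsets) < 0L || max(object@onsets) >= object@nSamples)
      return("event onsets must lie in [0, nSamples)")
  }
  TRUE
})

#' StoryRecording: multichannel neural time series for one story
#'
#' @slot signal T x C numeric matrix (time by channel).
#' @slot rateHz sampling rate in Hz.
#' @slot zscored whether the signal has been z-scored per channel.
#' @slot storyId single character identifier.
#' @export
setClass("StoryRecording",
  representation(
    signal = "matrix",
    rateHz = "numeric",
    zscored = "logical",
    storyId = "character"
  )
)

setValidity("StoryRecording", function(object) {
  if (!is.numeric(object@signal) || any(!is.finite(object@signal)))
    return("signal must be a finite numeric matrix")
  if (length(object@rateHz) != 1L || object@rateHz <= 0)
    return("rateHz must be a single positive number")
  TRUE
})

#' RepeatSet: repeated presentations of one held-out story
#'
#' @slot repeats n_rep x T x C numeric array; n_rep >= 2.
#' @slot rateHz sampling rate in Hz.
#' @export
setClass("RepeatSet",
  representation(repeats = "array", rateHz = "numeric")
)

setValidity("RepeatSet", function(object) {
  d <- dim(object@repeats)
  if (length(d) != 3L)
    return("repeats must be an n_rep x T x C array")
  if (d[1L] < 2L)
    return("at least 2 repeats are required (noise ceiling undefined otherwise)")
  if (any(!is.finite(object@repeats)))
    return("repeats must be finite")
  TRUE
})

#' CPFilter: rank-R canonical polyadic filter
#'
#' The model's parameters: a D x N x C FIR filter represented as a sum of R
#' rank-1 components, each the outer product of a delay factor, an embedding
#' factor and a channel factor, scaled by a per-component coefficient alpha.
#' When `normalized` is TRUE every factor row has unit Euclidean norm and
#' alpha is non-negative, so alpha carries all the scale.
#'
#' @slot delayFactors R x D matrix of delay factors.
#' @slot embedFactors R x N matrix of embedding factors.
#' @slot channelFactors R x C matrix of channel factors.
#' @slot alpha length-R non-negative (when normalized) scale vector.
#' @slot normalized logical flag.
#' @export
setClass("CPFilter",
  representation(
    delayFactors = "matrix",
    embedFactors = "matrix",
    channelFactors = "matrix",
    alpha = "numeric",
    normalized = "logical"
  )
)

setValidity("CPFilter", function(object) {
  R <- nrow(object@delayFactors)
  if (R < 1L) return("rank must be >= 1")
  if (nrow(object@embedFactors) != R || nrow(object@channelFactors) != R ||
      length(object@alpha) != R)
    return("factor matrices and alpha must agree on rank R")
  if (any(!is.finite(object@delayFactors)) ||
      any(!is.finite(object@embedFactors)) ||
      any(!is.finite(object@channelFactors)) || any(!is.finite(object@alpha)))
    return("all factor entries and alpha must be finite")
  if (isTRUE(object@normalized)) {
    tol <- 1e-8
    nd <- rowSums(object@delayFactors^2)
    ne <- rowSums(object@embedFactors^2)
    nc <- rowSums(object@channelFactors^2)
    if (any(abs(nd - 1) > tol) || any(abs(ne - 1) > tol) ||
        any(abs(nc - 1) > tol))
      return("normalized filter must have unit-norm factor rows")
    if (any(object@alpha < 0))
      return("normalized filter must have alpha >= 0")
  }
  TRUE
})

#' FullFilter: dense D x N x C FIR filter
#'
#' The full-rank baseline's parameters and the expansion target of a
#' [CPFilter].
#'
#' @slot weights D x N x C numeric array.
#' @export
setClass("FullFilter", representation(weights = "array"))

setValidity("FullFilter", function(object) {
  if (length(dim(object@weights)) != 3L)
    return("weights must be a D x N x C array")
  if (any(!is.finite(object@weights)))
    return("weights must be finite")
  TRUE
})

#' PCAReducer: fitted PCA projection for embeddings
#'
#' @slot rotation N x K orthonormal basis (columns are principal axes).
#' @slot center length-N training mean, subtracted before projection.
#' @slot explainedVarianceRatio per-component variance ratios (all
#'   components of the fit, not only the retained K).
#' @slot k number of retained components.
#' @export
setClass("PCAReducer",
  representation(
    rotation = "matrix",
    center = "numeric",
    explainedVarianceRatio = "numeric",
    k = "integer"
  )
)

setValidity("PCAReducer", function(object) {
  if (ncol(object@rotation) != object@k)
    return("rotation must have k columns")
  evr <- object@explainedVarianceRatio
  if (any(evr < -1e-12) || any(evr > 1 + 1e-12))
    return("explained variance ratios must lie in [0, 1]")
  if (is.unsorted(rev(evr), strictly = FALSE) && any(diff(evr) > 1e-12))
    return("explained variance ratios must be non-increasing")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(g)))) > 1e-6)
    return("rotation columns must be orthonormal")
  TRUE
})

#' EvalReport: per-channel model evaluation
#'
#' @slot ccmax per-channel noise ceiling (after clamping).
#' @slot ccnorm per-channel ceiling-normalized correlation.
#' @slot meanCCnorm mean CCnorm over channels.
#' @slot clamped per-channel flag: TRUE where the ceiling was clamped to the
#'   floor.
#' @export
setClass("EvalReport",
  representation(
    ccmax = "numeric",
    ccnorm = "numeric",
    meanCCnorm = "numeric",
    clamped = "logical"
  )
)

setValidity("EvalReport", function(object) {
  if (length(object@ccmax) != length(object@ccnorm) ||
      length(object@clamped) != length(object@ccmax))
    return("ccmax, ccnorm and clamped must have one entry per channel")
  TRUE
})

#' SimConfig: synthetic-dataset configuration
#'
#' All counts and noise levels of the synthetic generator. Defaults follow
#' the study conditions the model assumes: 50 Hz sampling grid, a geometric
#' word-gap law, low-dimensional embeddings with geometrically decaying
#' spectrum, and a smooth rank-R ground-truth filter.
#'
#' @slot nStories number of training stories I.
#' @slot samplesPerStory samples per story T.
#' @slot nChannels channels C.
#' @slot embedDim embedding dimension N.
#' @slot nDelays filter delays D.
#' @slot rank ground-truth rank R.
#' @slot meanWordGap mean inter-word gap in samples.
#' @slot noiseSd additive Gaussian channel noise sd.
#' @slot nRepeats number of repeats of the held-out story.
#' @slot seed integer RNG seed.
#' @slot embedDecay geometric decay ratio of embedding eigenvalues.
#' @slot alpha ground-truth component scales (length `rank`).
#' @slot rateHz sampling rate in Hz.
#' @export
setClass("SimConfig",
  representation(
    nStories = "integer",
    samplesPerStory = "integer",
    nChannels = "integer",
    embedDim = "integer",
    nDelays = "integer",
    rank = "integer",
    meanWordGap = "numeric",
    noiseSd = "numeric",
    nRepeats = "integer",
    seed = "integer",
    embedDecay = "numeric",
    alpha = "numeric",
    rateHz = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  counts <- c(object@nStories, object@samplesPerStory, object@nChannels,
              object@embedDim, object@nDelays, object@rank, object@nRepeats)
  if (any(counts < 1L)) return("all counts must be >= 1")
  if (object@meanWordGap < 1) return("meanWordGap must be >= 1 sample")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@nDelays > object@samplesPerStory)
    return("nDelays must not exceed samplesPerStory")
  if (length(object@alpha) != object@rank || any(object@alpha <= 0))
    return("alpha must have one positive entry per component")
  if (object@embedDecay <= 0 || object@embedDecay > 1)
    return("embedDecay must lie in (0, 1]")
  TRUE
})

#' GroundTruth: generating process of a synthetic dataset
#'
#' @slot filter normalized [CPFilter] that generates the signal.
#' @slot embedSd per-dimension embedding standard deviations (the square
#'   roots of the diagonal embedding covariance).
#' @export
setClass("GroundTruth",
  representation(filter = "CPFilter", embedSd = "numeric")
)

#' StoryDataset: a full synthetic or loaded dataset
#'
#' @slot stories list; each element a list with components `stream`
#'   ([WordStream]), `embeddings` ([EmbeddingSet]) and `recording`
#'   ([StoryRecording]).
#' @slot testStory list with `stream`, `embeddings` and `repeats`
#'   ([RepeatSet]) for the held-out repeated story, or empty list.
#' @slot truth the generating [GroundTruth] when simulated, else NULL.
#' @slot config the [SimConfig] used, when simulated, else NULL.
#' @export
setClass("StoryDataset",
  representation(
    stories = "list",
    testStory = "list",
    truth = "ANY",
    config = "ANY"
  )
)
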