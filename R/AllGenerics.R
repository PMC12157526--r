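#' Number of channels of an object
#' @param x object with a channel mode
#' @return integer channel count
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of filter delays of an object
#' @param x object with a delay mode
#' @return integer delay count
#' @export
setGeneric("nDelays", function(x) standardGeneric("nDelays"))

#' Embedding dimension of an object
#' @param x object with an embedding mode
#' @return integer embedding dimension
#' @export
setGeneric("embedDim", function(x) standardGeneric("embedDim"))

#' Rank (number of components) of a filter
#' @param x a filter object
#' @return integer rank
#' @export
setGeneric("filterRank", function(x) standardGeneric("filterRank"))

#' Component scale coefficients
#' @param x a CP filter
#' @return numeric vector alpha
#' @export
setGeneric("alpha", function(x) standardGeneric("alpha"))

#' Predict a multichannel time series from an event-sparse embedding series
#'
#' Applies the FIR forward model: the filter is convolved with the sparse
#' embedding series, predicting every channel at every sample. The cost is
#' proportional to the number of word events, never to the dense series
#' length times filter size.
#'
#' @param filter a [CPFilter-class] or [FullFilter-class]
#' @param series a [SparseEmbeddingSeries-class]
#' @return T x C numeric matrix of predictions
#' @export
setGeneric("predictSeries", function(filter, series)
  standardGeneric("predictSeries"))

#' @export
#' @describeIn nChannels channels of a recording
setMethod("nChannels", "StoryRecording", function(x) ncol(x@signal))
#' @export
#' @describeIn nChannels channels of a repeat set
setMethod("nChannels", "RepeatSet", function(x) dim(x@repeats)[3L])
#' @export
#' @describeIn nChannels channels of a CP filter
setMethod("nChannels", "CPFilter", function(x) ncol(x@channelFactors))
#' @export
#' @describeIn nChannels channels of a full filter
setMethod("nChannels", "FullFilter", function(x) dim(x@weights)[3L])

#' @export
#' @describeIn nDelays delays of a CP filter
setMethod("nDelays", "CPFilter", function(x) ncol(x@delayFactors))
#' @export
#' @describeIn nDelays delays of a full filter
setMethod("nDelays", "FullFilter", function(x) dim(x@weights)[1L])

#' @export
#' @describeIn embedDim embedding dimension of a CP filter
setMethod("embedDim", "CPFilter", function(x) ncol(x@embedFactors))
#' @export
#' @describeIn embedDim embedding dimension of a full filter
setMethod("embedDim", "FullFilter", function(x) dim(x@weights)[2L])
#' @export
#' @describeIn embedDim embedding dimension of a sparse series
setMethod("embedDim", "SparseEmbeddingSeries", function(x) ncol(x@embeddings))
#' @export
#' @describeIn embedDim embedding dimension of an embedding set
setMethod("embedDim", "EmbeddingSet", function(x) ncol(x@embeddings))

#' @export
#' @describeIn filterRank rank of a CP filter
setMethod("filterRank", "CPFilter", function(x) nrow(x@delayFactors))

#' @export
#' @describeIn alpha scales of a CP filter
setMethod("alpha", "CPFilter", function(x) x@alpha)

setMethod("show", "CPFilter", function(object) {
  cat(sprintf("CPFilter: rank %d, D=%d delays, N=%d embedding dims, C=%d channels\n",
              filterRank(object), nDelays(object), embedDim(object),
              nChannels(object)))
  cat(sprintf("  normalized: %s; alpha: %s\n", object@normalized,
              paste(signif(object@alpha, 4), collapse = ", ")))
})

setMethod("show", "FullFilter", function(object) {
  d <- dim(object@weights)
  cat(sprintf("FullFilter: D=%d x N=%d x C=%d dense FIR weights\n",
              d[1L], d[2L], d[3L]))
})

setMethod("show", "WordStream", function(object) {
  cat(sprintf("WordStream '%s': %d words over %d samples (%d sentences)\n",
              object@storyId, length(object@words), object@nSamples,
              sum(object@sentenceStart)))
})

setMethod("show", "StoryRecording", function(object) {
  cat(sprintf("StoryRecording '%s': %d samples x %d channels @ %g Hz%s\n",
              object@storyId, nrow(object@signal), ncol(object@signal),
              object@rateHz, if (object@zscored) " (z-scored)" else ""))
})

setMethod("show", "RepeatSet", function(object) {
  d <- dim(object@repeats)
  cat(sprintf("RepeatSet: %d repeats of %d samples x %d channels @ %g Hz\n",
              d[1L], d[2L], d[3L], object@rateHz))
})

setMethod("show", "SparseEmbeddingSeries", function(object) {
  cat(sprintf("SparseEmbeddingSeries: %d events, dim %d, length %d\n",
              length(object@onsets), ncol(object@embeddings),
              object@nSamples))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d channels, mean CCnorm = %.4f (%d clamped ceilings)\n",
              length(object@ccnorm), object@meanCCnorm, sum(object@clamped)))
})

setMethod("show", "PCAReducer", function(object) {
  cat(sprintf("PCAReducer: %d -> %d dims (%.1f%% variance retained)\n",
              nrow(object@rotation), object@k,
              100 * sum(object@explainedVarianceRatio[seq_len(object@k)])))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d stories x %d samples, C=%d, N=%d, D=%d, rank %d\n",
    object@nStories, object@samplesPerStory, object@nChannels,
    object@embedDim, object@nDelays, object@rank))
  cat(sprintf("  mean word gap %g, noise sd %g, %d repeats, seed %d\n",
              object@meanWordGap, object@noiseSd, object@nRepeats,
              object@seed))
})

setMethod("show", "StoryDataset", function(object) {
  cat(sprintf("StoryDataset: %d training stories%s\n", length(object@stories),
              if (length(object@testStory)) " + held-out repeated story"
              else ""))
})

#' Per-channel noise ceiling of an evaluation
#' @param x an [EvalReport-class]
#' @return numeric vector
#' @export
ccMaxValues <- function(x) x@ccmax

#' Per-channel ceiling-normalized correlations of an evaluation
#' @param x an [EvalReport-class]
#' @return numeric vector
#' @export
ccNormValues <- function(x) x@ccnorm

#' Mean CCnorm of an evaluation
#' @param x an [EvalReport-class]
#' @return scalar
#' @export
meanCCnorm <- function(x) x@meanCCnorm
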