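#' Build the event-sparse embedding time series for one story
#'
#' The model's regressor is a T x N series that is zero everywhere except at
#' word onsets, where it equals the word's embedding. It is stored sparsely
#' as (onset, embedding) events. Words sharing a sample are merged into one
#' event whose embedding is the sum of theirs, which the linear forward model
#' forces.
#'
#' @param stream a [WordStream-class]
#' @param embeddings matching [EmbeddingSet-class] (one row per word)
#' @param length series length T in samples
#' @return a [SparseEmbeddingSeries-class]
#' @export
buildSeries <- function(stream, embeddings, length = stream@nSamples) {
  emb <- embeddings@embeddings
  if (nrow(emb) != base::length(stream@words))
    stop(sprintf("embedding rows (%d) do not match word count (%d) for '%s'",
                 nrow(emb), base::length(stream@words), stream@storyId))
  if (base::length(stream@onsets) > 0L && max(stream@onsets) >= length)
    stop(sprintf("onset %d beyond series length %d in '%s'",
                 max(stream@onsets), length, stream@storyId))
  if (base::length(stream@onsets) == 0L) {
    return(new("SparseEmbeddingSeries", nSamples = as.integer(length),
               onsets = integer(0),
               embeddings = matrix(0, 0L, ncol(emb))))
  }
  merged <- rowsum(emb, group = stream@onsets, reorder = TRUE)
  onsets <- as.integer(rownames(merged))
  dimnames(merged) <- NULL
  new("SparseEmbeddingSeries", nSamples = as.integer(length),
      onsets = onsets, embeddings = merged)
}

#' Densify a sparse embedding series
#'
#' @param series a [SparseEmbeddingSeries-class]
#' @return T x N numeric matrix
#' @export
denseSeries <- function(series) {
  X <- matrix(0, series@nSamples, ncol(series@embeddings))
  if (length(series@onsets))
    X[series@onsets + 1L, ] <- series@embeddings
  X
}

#' Lagged dense design matrix for the full-rank solver
#'
#' Row t, delay block d (d = 0..D-1) holds the embedding series at t - d;
#' entries before the story start are zero (the convolution restarts at every
#' story boundary). Only the full-rank ridge path uses this dense form; the
#' low-rank model consumes the sparse events directly.
#'
#' @param series a [SparseEmbeddingSeries-class]
#' @param nDelays number of delays D
#' @return T x (D*N) matrix; columns ordered delay-major
#'   (block d occupies columns d*N + 1 .. (d+1)*N)
#' @export
laggedDesign <- function(series, nDelays) {
  D <- as.integer(nDelays)
  if (D < 1L) stop("nDelays must be >= 1")
  T <- series@nSamples
  if (D > T) stop("nDelays exceeds series length")
  X <- denseSeries(series)
  N <- ncol(X)
  out <- matrix(0, T, D * N)
  for (d in 0:(D - 1L)) {
    if (d < T)
      out[(d + 1L):T, (d * N + 1L):((d + 1L) * N)] <-
        X[seq_len(T - d), , drop = FALSE]
  }
  out
}

#' Fit a PCA reducer on training embeddings
#'
#' Standard mean-centered PCA (rotation only, no whitening). The retained
#' dimension K is the smallest count whose cumulative explained variance
#' ratio reaches `varianceThreshold`. Fit on training stories only; the same
#' reducer is then applied to held-out embeddings without refitting.
#'
#' @param trainEmbeddings stacked S_total x N matrix of training embeddings
#' @param varianceThreshold fraction of variance to retain, in (0, 1]
#' @return a [PCAReducer-class]
#' @export
fitPCA <- function(trainEmbeddings, varianceThreshold = 0.95) {
  if (!is.matrix(trainEmbeddings) || nrow(trainEmbeddings) < 2L)
    stop("need at least 2 embedding rows to fit PCA")
  if (varianceThreshold <= 0 || varianceThreshold > 1)
    stop("varianceThreshold must lie in (0, 1]")
  pc <- stats::prcomp(trainEmbeddings, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= .Machine$double.eps)
    stop("degenerate embeddings: zero total variance")
  evr <- vars / total
  k <- which(cumsum(evr) >= varianceThreshold - 1e-12)[1L]
  if (is.na(k)) k <- length(evr)
  new("PCAReducer",
      rotation = pc$rotation[, seq_len(k), drop = FALSE],
      center = pc$center,
      explainedVarianceRatio = evr,
      k = as.integer(k))
}

#' Project embeddings onto a fitted PCA basis
#'
#' Subtracts the training mean and projects onto the retained components.
#'
#' @param reducer a [PCAReducer-class]
#' @param embeddings an [EmbeddingSet-class] or numeric matrix
#' @return object of the same kind with K columns
#' @export
applyPCA <- function(reducer, embeddings) {
  m <- if (is(embeddings, "EmbeddingSet")) embeddings@embeddings
       else embeddings
  if (ncol(m) != nrow(reducer@rotation))
    stop(sprintf("embedding dim %d does not match reducer input dim %d",
                 ncol(m), nrow(reducer@rotation)))
  proj <- sweep(m, 2L, reducer@center) %*% reducer@rotation
  if (is(embeddings, "EmbeddingSet"))
    new("EmbeddingSet", embeddings = proj,
        contextLen = embeddings@contextLen,
        provenance = paste0(embeddings@provenance, ":pca", reducer@k))
  else proj
}
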