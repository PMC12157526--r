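#' Component weight timecourses
#'
#' The prediction decomposes over components as
#' `pred[t, c] = sum_r W[r, t] * U^C[r, c]`, where
#' `W[r, t] = alpha_r * sum_{n,d} U^D[r, d] U^E[r, n] X[t - d, n]` is the
#' strength of component r's channel pattern at time t.
#'
#' @param filter a normalized [CPFilter-class]
#' @param series a [SparseEmbeddingSeries-class]
#' @return R x T matrix of component weights
#' @export
componentWeights <- function(filter, series) {
  if (ncol(series@embeddings) != embedDim(filter))
    stop("embedding dimension does not match filter")
  t(.cpWeightMatrix(filter, series))
}

#' Most-activating contexts per component
#'
#' Scores every corpus context by the raw dot product of its embedding with
#' the component's embedding factor and returns the top (or bottom) k. Ties
#' are broken by corpus order. Cosine scoring is available as an option.
#'
#' @param filter a normalized [CPFilter-class]
#' @param contexts character vector of context strings (e.g. 5-word windows)
#' @param contextEmbeddings matching rows x N embedding matrix
#' @param k contexts to return per component
#' @param sign `"positive"` for the highest scores, `"negative"` for the most
#'   negative
#' @param scoring `"dot"` (default) or `"cosine"`
#' @return data.frame with columns `component`, `rank`, `context`, `score`
#' @export
topContexts <- function(filter, contexts, contextEmbeddings, k = 5L,
                        sign = c("positive", "negative"),
                        scoring = c("dot", "cosine")) {
  sign <- match.arg(sign)
  scoring <- match.arg(scoring)
  if (length(contexts) == 0L) stop("empty context corpus")
  if (length(contexts) != nrow(contextEmbeddings))
    stop("one embedding row per context required")
  if (k > length(contexts)) stop("k exceeds corpus size")
  E <- contextEmbeddings
  if (scoring == "cosine") {
    nrm <- sqrt(rowSums(E^2))
    nrm[nrm == 0] <- 1
    E <- E / nrm
  }
  scores <- E %*% t(filter@embedFactors)    # contexts x R
  do.call(rbind, lapply(seq_len(filterRank(filter)), function(r) {
    s <- scores[, r]
    ord <- if (sign == "positive") order(-s, seq_along(s))
           else order(s, seq_along(s))
    idx <- ord[seq_len(k)]
    data.frame(component = r, rank = seq_len(k),
               context = contexts[idx], score = s[idx])
  }))
}

# shared normalized-power computation
.factorPower <- function(factors, alpha, normalization) {
  q <- colSums(alpha^2 * factors^2)
  if (all(q == 0)) stop("power undefined for an all-zero filter")
  switch(normalization,
         euclidean = q / sqrt(sum(q^2)),
         sum = q / sum(q))
}

#' Normalized power over delays
#'
#' `Q^D[d] = sum_r alpha_r^2 * U^D[r, d]^2`, normalized to `P^D = Q^D /
#' ||Q^D||`. Invariant to a global rescaling of alpha; summarizes where in
#' post-onset time the model concentrates its energy.
#'
#' @param filter a normalized [CPFilter-class]
#' @param normalization `"euclidean"` (default, unit 2-norm) or `"sum"`
#'   (sums to one)
#' @return non-negative D-vector
#' @export
delayPower <- function(filter, normalization = c("euclidean", "sum")) {
  .factorPower(filter@delayFactors, filter@alpha, match.arg(normalization))
}

#' Normalized power over channels
#'
#' `Q^C[c] = sum_r alpha_r^2 * U^C[r, c]^2`, normalized to `P^C = Q^C /
#' ||Q^C||`; summarizes where across channels the model concentrates its
#' energy.
#'
#' @inheritParams delayPower
#' @return non-negative C-vector
#' @export
channelPower <- function(filter, normalization = c("euclidean", "sum")) {
  .factorPower(filter@channelFactors, filter@alpha, match.arg(normalization))
}

#' Sliding word-context windows of a stream
#'
#' Helper to build the context corpus for [topContexts()]: all contiguous
#' `width`-word windows of a word stream, as strings.
#'
#' @param stream a [WordStream-class]
#' @param width words per context (default 5)
#' @return character vector of contexts (length `max(0, S - width + 1)`)
#' @export
contextWindows <- function(stream, width = 5L) {
  S <- length(stream@words)
  if (S < width) return(character(0))
  vapply(seq_len(S - width + 1L), function(i)
    paste(stream@words[i:(i + width - 1L)], collapse = " "), character(1))
}
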