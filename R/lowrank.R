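#' Construct a CP filter
#'
#' @param delayFactors R x D matrix
#' @param embedFactors R x N matrix
#' @param channelFactors R x C matrix
#' @param alpha length-R scales (default 1)
#' @param normalized whether the factor rows are unit-norm with alpha >= 0
#' @return a [CPFilter-class]
#' @export
cpFilter <- function(delayFactors, embedFactors, channelFactors,
                     alpha = rep(1, nrow(delayFactors)),
                     normalized = FALSE) {
  new("CPFilter", delayFactors = as.matrix(delayFactors),
      embedFactors = as.matrix(embedFactors),
      channelFactors = as.matrix(channelFactors),
      alpha = as.numeric(alpha), normalized = isTRUE(normalized))
}

#' Expand a CP filter to its dense tensor
#'
#' Materializes F[d, n, c] = sum_r alpha_r U^D[r, d] U^E[r, n] U^C[r, c].
#'
#' @param filter a [CPFilter-class]
#' @return a [FullFilter-class]
#' @export
cpExpand <- function(filter) {
  D <- nDelays(filter); N <- embedDim(filter); C <- nChannels(filter)
  F <- array(0, dim = c(D, N, C))
  for (r in seq_len(filterRank(filter))) {
    F <- F + filter@alpha[r] *
      outer(outer(filter@delayFactors[r, ], filter@embedFactors[r, ]),
            filter@channelFactors[r, ])
  }
  new("FullFilter", weights = F)
}

# Per-component event scores s[j, r] = alpha_r * <U^E_r, E_j> and the R x T
# component weight matrix W[r, t]; shared by prediction, gradients and the
# interpretation module.
.cpEventScores <- function(filter, series) {
  s <- series@embeddings %*% t(filter@embedFactors)
  s * rep(filter@alpha, each = nrow(s))
}

.cpWeightMatrix <- function(filter, series, s = .cpEventScores(filter, series)) {
  T <- series@nSamples
  R <- filterRank(filter)
  D <- nDelays(filter)
  Wt <- matrix(0, T, R)           # transposed (T x R) for cache-friendly ops
  tau <- series@onsets
  if (length(tau) == 0L) return(Wt)
  UD <- filter@delayFactors
  for (d in 0:(D - 1L)) {
    rows <- tau + d + 1L
    ok <- rows <= T
    if (!any(ok)) break
    Wt[rows[ok], ] <- Wt[rows[ok], ] +
      s[ok, , drop = FALSE] * rep(UD[, d + 1L], each = sum(ok))
  }
  Wt
}

#' @describeIn predictSeries factorized forward prediction with a CP filter;
#'   equals dense expansion followed by the triple-sum convolution, at cost
#'   proportional to events x R x (N + D + C)
#' @export
setMethod("predictSeries", signature("CPFilter", "SparseEmbeddingSeries"),
  function(filter, series) {
    if (ncol(series@embeddings) != embedDim(filter))
      stop("embedding dimension does not match filter")
    Wt <- .cpWeightMatrix(filter, series)
    Wt %*% filter@channelFactors
  })

#' Factorized forward prediction (function form)
#'
#' @param filter a [CPFilter-class]
#' @param series a [SparseEmbeddingSeries-class]
#' @return T x C matrix
#' @export
predictCP <- function(filter, series) predictSeries(filter, series)

#' Training loss of a CP filter
#'
#' Mean squared prediction error over all stories, samples and channels, plus
#' a ridge penalty on the entries of the *expanded* filter tensor:
#' `L = mean((pred - M)^2) + (1/(C*D*N)) * sum_c lambda_c * sum_{d,n} F[d,n,c]^2`.
#' The penalty is evaluated in factorized form through the factor Gram
#' matrices, never by materializing F.
#'
#' @param filter a [CPFilter-class]
#' @param seriesList list of [SparseEmbeddingSeries-class]
#' @param recordings list of [StoryRecording-class] (or T x C matrices)
#' @param ridgePenalty scalar or per-channel lambda (default 0.1)
#' @param penaltyOn `"expanded"` (the loss as defined) or `"factors"`
#'   (penalize factor entries directly; provided as an alternative, not the
#'   default)
#' @return scalar loss
#' @export
cpLoss <- function(filter, seriesList, recordings, ridgePenalty = 0.1,
                   penaltyOn = c("expanded", "factors")) {
  penaltyOn <- match.arg(penaltyOn)
  if (is(seriesList, "SparseEmbeddingSeries")) seriesList <- list(seriesList)
  if (!is.list(recordings)) recordings <- list(recordings)
  mats <- lapply(recordings, function(r)
    if (is(r, "StoryRecording")) r@signal else r)
  sse <- 0; ntot <- 0
  for (i in seq_along(seriesList)) {
    pred <- predictSeries(filter, seriesList[[i]])
    if (!all(dim(pred) == dim(mats[[i]])))
      stop("recording dimensions do not match prediction")
    sse <- sse + sum((pred - mats[[i]])^2)
    ntot <- ntot + length(pred)
  }
  D <- nDelays(filter); N <- embedDim(filter); C <- nChannels(filter)
  lambda <- rep(ridgePenalty, length.out = C)
  UDs <- filter@delayFactors * filter@alpha
  pen <- if (penaltyOn == "expanded") {
    GC <- filter@channelFactors %*% (lambda * t(filter@channelFactors))
    sum(tcrossprod(UDs) * tcrossprod(filter@embedFactors) * GC) / (C * D * N)
  } else {
    mean(lambda) * (sum(UDs^2) + sum(filter@embedFactors^2) +
                    sum(filter@channelFactors^2)) / (C * D * N)
  }
  sse / ntot + pen
}

#' Training configuration for the low-rank fit
#'
#' Defaults follow the reference optimization recipe: Adam with learning rate
#' 5e-3, mini-batches of 300,000 contiguous time samples (effectively
#' full-batch on desk-scale data), uniform ridge penalty 0.1 on the expanded
#' tensor, small random Gaussian initialization, and stopping when the
#' relative full-data loss change stays below `convergenceTol` across a
#' 5-evaluation patience window.
#'
#' @param learningRate Adam step size.
#' @param batchSize time samples per mini-batch.
#' @param ridgePenalty uniform ridge penalty on the expanded tensor.
#' @param maxEpochs epoch cap.
#' @param convergenceTol relative loss-change tolerance.
#' @param patience evaluations the tolerance must hold across.
#' @param initSd sd of the Gaussian factor initialization.
#' @param penaltyOn `"expanded"` or `"factors"` (see [cpLoss()]).
#' @param seed RNG seed for initialization and batch order.
#' @return list of class `TrainConfig`
#' @export
trainConfig <- function(learningRate = 5e-3, batchSize = 300000L,
                        ridgePenalty = 0.1, maxEpochs = 2000L,
                        convergenceTol = 1e-6, patience = 5L,
                        initSd = 0.1, penaltyOn = "expanded", seed = 1L) {
  if (learningRate <= 0) stop("learningRate must be positive")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (ridgePenalty < 0) stop("ridgePenalty must be >= 0")
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 ridgePenalty = ridgePenalty,
                 maxEpochs = as.integer(maxEpochs),
                 convergenceTol = convergenceTol,
                 patience = as.integer(patience),
                 initSd = initSd,
                 penaltyOn = match.arg(penaltyOn, c("expanded", "factors")),
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# loss + factor gradients over one contiguous row range of one story.
# tau 0-based onsets, E event embeddings, M T x C signal; range [t0, t1] 1-based.
.cpBatchGrad <- function(UD, UE, UC, tau, E, M, t0, t1) {
  R <- nrow(UD); D <- ncol(UD); C <- ncol(UC)
  keep <- tau >= (t0 - D) & tau <= (t1 - 1L)   # events touching the range
  tau <- tau[keep]
  E <- E[keep, , drop = FALSE]
  nb <- t1 - t0 + 1L
  s <- E %*% t(UE)                              # J x R (alpha folded in)
  Wt <- matrix(0, nb, R)
  for (d in 0:(D - 1L)) {
    g <- tau + d + 1L
    ok <- g >= t0 & g <= t1
    if (any(ok))
      Wt[g[ok] - t0 + 1L, ] <- Wt[g[ok] - t0 + 1L, ] +
        s[ok, , drop = FALSE] * rep(UD[, d + 1L], each = sum(ok))
  }
  res <- Wt %*% UC - M[t0:t1, , drop = FALSE]
  sc <- 2 / (nb * C)
  gUC <- sc * crossprod(Wt, res)
  G <- res %*% t(UC)                            # nb x R
  gUD <- matrix(0, R, D)
  A <- matrix(0, nrow(E), R)
  for (d in 0:(D - 1L)) {
    g <- tau + d + 1L
    ok <- g >= t0 & g <= t1
    if (any(ok)) {
      Grow <- G[g[ok] - t0 + 1L, , drop = FALSE]
      gUD[, d + 1L] <- colSums(s[ok, , drop = FALSE] * Grow)
      A[ok, ] <- A[ok, ] + Grow * rep(UD[, d + 1L], each = sum(ok))
    }
  }
  list(gUD = sc * gUD, gUE = sc * crossprod(A, E), gUC = gUC,
       sse = sum(res^2), n = nb * C)
}

#' Fit a low-rank CP filter by stochastic gradient descent
#'
#' Optimizes the three factor matrices jointly with Adam on the ridge-
#' regularized MSE loss. Factors are *not* norm-constrained during fitting;
#' call [cpNormalize()] afterwards to pull the scales out. Mini-batches are
#' contiguous time blocks (the convolution couples neighboring samples), in
#' an order reshuffled each epoch. Training stops at `maxEpochs` or when the
#' relative change of the full-data loss stays below `convergenceTol` over a
#' patience window. Deterministic given `cfg$seed`.
#'
#' @param seriesList list of [SparseEmbeddingSeries-class] (training stories)
#' @param recordings list of matching [StoryRecording-class] or T x C
#'   matrices
#' @param rank number of components R
#' @param nDelays number of filter delays D
#' @param cfg a [trainConfig()]
#' @return list with `filter` (unnormalized [CPFilter-class]), `lossTrace`
#'   (full loss per epoch), `epochs` and `converged`
#' @export
fitCP <- function(seriesList, recordings, rank, nDelays,
                  cfg = trainConfig()) {
  if (is(seriesList, "SparseEmbeddingSeries")) seriesList <- list(seriesList)
  if (!is.list(recordings)) recordings <- list(recordings)
  if (length(seriesList) == 0L) stop("no training data supplied")
  if (length(seriesList) != length(recordings))
    stop("one recording per series required")
  rank <- as.integer(rank)
  if (rank < 1L) stop("rank must be >= 1")
  mats <- lapply(recordings, function(r)
    if (is(r, "StoryRecording")) r@signal else r)
  N <- ncol(seriesList[[1L]]@embeddings)
  C <- ncol(mats[[1L]])
  D <- as.integer(nDelays)
  for (i in seq_along(seriesList)) {
    if (seriesList[[i]]@nSamples != nrow(mats[[i]]) ||
        ncol(seriesList[[i]]@embeddings) != N || ncol(mats[[i]]) != C)
      stop(sprintf("dimension mismatch between series and recording %d", i))
  }
  lambda <- cfg$ridgePenalty
  rsc <- 2 * lambda / (C * D * N)
  withSeed(cfg$seed, {
    UD <- matrix(stats::rnorm(rank * D, sd = cfg$initSd), rank, D)
    UE <- matrix(stats::rnorm(rank * N, sd = cfg$initSd), rank, N)
    UC <- matrix(stats::rnorm(rank * C, sd = cfg$initSd), rank, C)
    m <- list(UD = UD * 0, UE = UE * 0, UC = UC * 0)
    v <- m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    # contiguous batch plan: (story, t0, t1) triples
    batches <- do.call(rbind, lapply(seq_along(mats), function(i) {
      T <- nrow(mats[[i]])
      starts <- seq(1L, T, by = cfg$batchSize)
      cbind(i, starts, pmin(starts + cfg$batchSize - 1L, T))
    }))
    step <- 0L
    trace <- numeric(cfg$maxEpochs)
    converged <- FALSE
    epoch <- 0L
    for (epoch in seq_len(cfg$maxEpochs)) {
      ord <- if (nrow(batches) > 1L) sample.int(nrow(batches))
             else 1L
      epochSSE <- 0; epochN <- 0
      for (b in ord) {
        i <- batches[b, 1L]
        gr <- .cpBatchGrad(UD, UE, UC, seriesList[[i]]@onsets,
                           seriesList[[i]]@embeddings, mats[[i]],
                           batches[b, 2L], batches[b, 3L])
        epochSSE <- epochSSE + gr$sse
        epochN <- epochN + gr$n
        if (cfg$penaltyOn == "expanded") {
          GD <- tcrossprod(UD); GE <- tcrossprod(UE); GC <- tcrossprod(UC)
          gr$gUD <- gr$gUD + rsc * (GE * GC) %*% UD
          gr$gUE <- gr$gUE + rsc * (GD * GC) %*% UE
          gr$gUC <- gr$gUC + rsc * (GD * GE) %*% UC
        } else {
          gr$gUD <- gr$gUD + rsc * UD
          gr$gUE <- gr$gUE + rsc * UE
          gr$gUC <- gr$gUC + rsc * UC
        }
        step <- step + 1L
        grads <- list(UD = gr$gUD, UE = gr$gUE, UC = gr$gUC)
        for (nm in names(grads)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grads[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grads[[nm]]^2
          upd <- cfg$learningRate * (m[[nm]] / (1 - b1^step)) /
            (sqrt(v[[nm]] / (1 - b2^step)) + eps)
          if (nm == "UD") UD <- UD - upd
          else if (nm == "UE") UE <- UE - upd
          else UC <- UC - upd
        }
      }
      pen <- if (cfg$penaltyOn == "expanded") {
        sum(tcrossprod(UD) * tcrossprod(UE) * tcrossprod(UC)) *
          lambda / (C * D * N)
      } else {
        lambda * (sum(UD^2) + sum(UE^2) + sum(UC^2)) / (C * D * N)
      }
      loss <- epochSSE / epochN + pen
      if (!is.finite(loss))
        stop(sprintf("low-rank fit diverged at epoch %d (non-finite loss)",
                     epoch))
      trace[epoch] <- loss
      if (epoch > max(cfg$patience, 20L)) {
        prev <- trace[epoch - cfg$patience]
        if (abs(prev - loss) / max(abs(loss), 1e-12) < cfg$convergenceTol) {
          converged <- TRUE
          break
        }
      }
    }
    list(filter = cpFilter(UD, UE, UC, alpha = rep(1, rank),
                           normalized = FALSE),
         lossTrace = trace[seq_len(epoch)],
         epochs = epoch,
         converged = converged)
  })
}

#' Normalize a CP filter
#'
#' Pulls the scale out of the factors: every factor row is rescaled to unit
#' Euclidean norm and alpha becomes the product of the removed norms times
#' the prior alpha. Signs are fixed so alpha >= 0, absorbing any flip into
#' the channel factor. The expanded tensor is unchanged.
#'
#' @param filter a [CPFilter-class]
#' @return normalized [CPFilter-class]
#' @export
cpNormalize <- function(filter) {
  nd <- sqrt(rowSums(filter@delayFactors^2))
  ne <- sqrt(rowSums(filter@embedFactors^2))
  nc <- sqrt(rowSums(filter@channelFactors^2))
  if (any(nd == 0 | ne == 0 | nc == 0))
    stop("degenerate component(s) with a zero factor row: ",
         paste(which(nd == 0 | ne == 0 | nc == 0), collapse = ", "))
  a <- filter@alpha * nd * ne * nc
  UC <- filter@channelFactors / nc
  flip <- a < 0
  a[flip] <- -a[flip]
  UC[flip, ] <- -UC[flip, , drop = FALSE]
  cpFilter(filter@delayFactors / nd, filter@embedFactors / ne, UC,
           alpha = a, normalized = TRUE)
}

#' Drop components from a CP filter
#'
#' @param filter a [CPFilter-class]
#' @param drop integer indices of components to remove (by zeroing alpha)
#' @return a [CPFilter-class] with the same rank and zeroed scales
#' @export
cpDropComponents <- function(filter, drop) {
  a <- filter@alpha
  a[drop] <- 0
  new("CPFilter", delayFactors = filter@delayFactors,
      embedFactors = filter@embedFactors,
      channelFactors = filter@channelFactors,
      alpha = a, normalized = FALSE)
}

#' Leave-one-out component influence
#'
#' Influence of component r is the drop in mean CCnorm when r is excluded
#' from the prediction: `meanCCnorm(all) - meanCCnorm(without r)`. When
#' removing the only component leaves a constant-zero prediction, its
#' correlation is defined as 0.
#'
#' @param filter a normalized [CPFilter-class]
#' @param series [SparseEmbeddingSeries-class] of the held-out story
#' @param repeats [RepeatSet-class] of the held-out story
#' @param floor noise-ceiling clamp floor (default 0.2)
#' @return data.frame with columns `component`, `alpha`, `influence`, sorted
#'   by decreasing influence (ties kept in component order)
#' @export
looInfluence <- function(filter, series, repeats, floor = 0.2) {
  R <- filterRank(filter)
  cm <- ccMax(repeats, floor = floor)
  full <- mean(ccNorm(predictSeries(filter, series), repeats, cm$ccmax))
  infl <- vapply(seq_len(R), function(r) {
    if (filter@alpha[r] == 0) return(0)
    sub <- cpDropComponents(filter, r)
    full - mean(ccNorm(predictSeries(sub, series), repeats, cm$ccmax))
  }, numeric(1))
  out <- data.frame(component = seq_len(R), alpha = filter@alpha,
                    influence = infl)
  out[order(-out$influence, out$component), ]
}

#' Match estimated CP components to reference components
#'
#' The CP parameterization is identifiable only up to component permutation
#' and paired sign flips, so any recovery comparison needs an alignment
#' rule: components are matched greedily by absolute channel-factor
#' correlation, and signs are aligned per mode.
#'
#' @param est,ref normalized [CPFilter-class] objects of equal rank
#' @return data.frame with one row per reference component: matched index and
#'   absolute factor correlations for the delay, embedding and channel modes,
#'   plus the matched alpha
#' @export
matchComponents <- function(est, ref) {
  R <- filterRank(ref)
  stopifnot(filterRank(est) == R)
  cm <- abs(stats::cor(t(est@channelFactors), t(ref@channelFactors)))
  avail <- rep(TRUE, R)
  out <- data.frame(ref = seq_len(R), est = NA_integer_,
                    corDelay = NA_real_, corEmbed = NA_real_,
                    corChannel = NA_real_, alphaEst = NA_real_)
  # greedy: repeatedly take the largest remaining correlation
  cmWork <- cm
  for (k in seq_len(R)) {
    idx <- which(cmWork == max(cmWork), arr.ind = TRUE)[1L, ]
    e <- idx[["row"]]; r <- idx[["col"]]
    out$est[r] <- e
    out$corDelay[r] <- abs(safeCor(est@delayFactors[e, ],
                                   ref@delayFactors[r, ]))
    out$corEmbed[r] <- abs(safeCor(est@embedFactors[e, ],
                                   ref@embedFactors[r, ]))
    out$corChannel[r] <- cm[e, r]
    out$alphaEst[r] <- est@alpha[e]
    cmWork[e, ] <- -Inf
    cmWork[, r] <- -Inf
  }
  out
}
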