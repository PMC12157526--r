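#' Ridge configuration for the full-rank baseline
#'
#' @param penaltyGrid positive penalties, sorted ascending. The default is an
#'   exponential grid of 8 values spanning 1e-3 .. 1e4.
#' @param nFolds sequential cross-validation folds (default 6).
#' @param perChannel choose the penalty independently per channel.
#' @return list of class `RidgeConfig`
#' @export
ridgeConfig <- function(penaltyGrid = 10^seq(-3, 4, length.out = 8),
                        nFolds = 6L, perChannel = TRUE) {
  if (length(penaltyGrid) == 0L || any(penaltyGrid <= 0))
    stop("penaltyGrid must be non-empty and positive")
  if (is.unsorted(penaltyGrid))
    stop("penaltyGrid must be sorted ascending")
  if (nFolds < 2L) stop("nFolds must be >= 2")
  structure(list(penaltyGrid = penaltyGrid, nFolds = as.integer(nFolds),
                 perChannel = isTRUE(perChannel)),
            class = "RidgeConfig")
}

#' Sequential cross-validation folds within stories
#'
#' Partitions each story into `nFolds` contiguous equal-length blocks (the
#' remainder goes to the last block); fold k is the union of block k across
#' stories. Contiguity respects the temporal correlation the convolution
#' induces, keeping training and validation segments distinct in time.
#'
#' @param storyLengths integer vector of story lengths in samples
#' @param nFolds number of folds
#' @return integer vector (one fold id in 1..nFolds per sample, stories
#'   concatenated in order)
#' @export
sequentialFolds <- function(storyLengths, nFolds) {
  nFolds <- as.integer(nFolds)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (any(storyLengths < nFolds))
    stop("every story must be longer than the number of folds")
  unlist(lapply(storyLengths, function(T) {
    base <- T %/% nFolds
    sizes <- rep(base, nFolds)
    sizes[nFolds] <- sizes[nFolds] + T %% nFolds
    rep(seq_len(nFolds), times = sizes)
  }), use.names = FALSE)
}

# one SVD, solutions along the whole lambda path
.ridgePath <- function(X, Y, lambdas) {
  sv <- svd(X, nu = min(dim(X)), nv = min(dim(X)))
  UtY <- crossprod(sv$u, Y)            # k x C
  lapply(lambdas, function(lam) {
    shrink <- sv$d / (sv$d^2 + lam)
    sv$v %*% (shrink * UtY)
  })
}

# reshape a (D*N) x C coefficient matrix (delay-major columns in the design)
# into the D x N x C filter array
.coefToFilter <- function(W, D, N) {
  C <- ncol(W)
  aperm(array(W, dim = c(N, D, C)), c(2L, 1L, 3L))
}

#' Fit the full-rank ridge baseline
#'
#' Per-channel ridge regression of the recording on the lagged design, with
#' the penalty chosen per channel by sequential K-fold cross-validation over
#' an exponential grid, minimizing mean validation MSE. The final filter is
#' refit on all training data at each channel's chosen penalty. Solved in
#' closed form via one SVD per fold, reused across the whole penalty grid.
#'
#' @param design T x (D*N) lagged design matrix (see [laggedDesign()])
#' @param response T x C recording matrix, rows aligned with `design`
#' @param nDelays,embedDimN the D and N that produced the design (used to
#'   reshape coefficients into the filter tensor)
#' @param cfg a [ridgeConfig()]
#' @param folds optional precomputed fold ids (see [sequentialFolds()]);
#'   defaults to treating `design` as a single story
#' @return list with `filter` ([FullFilter-class]), `lambda` (per-channel
#'   chosen penalties) and `cvMSE` (grid x channel mean validation MSE)
#' @export
fitRidge <- function(design, response, nDelays, embedDimN,
                     cfg = ridgeConfig(),
                     folds = sequentialFolds(nrow(design), cfg$nFolds)) {
  if (nrow(design) != nrow(response))
    stop("design and response must have aligned rows")
  if (length(folds) != nrow(design))
    stop("fold assignment must cover every sample")
  grid <- cfg$penaltyGrid
  C <- ncol(response)
  cvSSE <- matrix(0, length(grid), C)
  cvN <- numeric(length(grid))
  for (k in sort(unique(folds))) {
    val <- folds == k
    Ws <- .ridgePath(design[!val, , drop = FALSE],
                     response[!val, , drop = FALSE], grid)
    for (g in seq_along(grid)) {
      resid <- response[val, , drop = FALSE] -
        design[val, , drop = FALSE] %*% Ws[[g]]
      cvSSE[g, ] <- cvSSE[g, ] + colSums(resid^2)
    }
    cvN <- cvN + sum(val)
  }
  cvMSE <- cvSSE / cvN
  best <- if (cfg$perChannel) apply(cvMSE, 2L, which.min)
          else rep(which.min(rowMeans(cvMSE)), C)
  lambda <- grid[best]
  Wfull <- .ridgePath(design, response, grid[sort(unique(best))])
  W <- matrix(0, ncol(design), C)
  for (i in seq_along(sort(unique(best)))) {
    g <- sort(unique(best))[i]
    W[, best == g] <- Wfull[[i]][, best == g, drop = FALSE]
  }
  list(filter = new("FullFilter",
                    weights = .coefToFilter(W, nDelays, embedDimN)),
       lambda = lambda, cvMSE = cvMSE)
}

#' Ridge-less (ordinary least squares) full-rank fit
#'
#' Used for control residualization. Falls back to the minimum-norm
#' pseudo-inverse solution with a warning when the design is rank-deficient.
#'
#' @inheritParams fitRidge
#' @return list with `filter` ([FullFilter-class]) and `coef`
#'   ((D*N) x C coefficient matrix)
#' @export
fitOLS <- function(design, response, nDelays, embedDimN) {
  if (nrow(design) != nrow(response))
    stop("design and response must have aligned rows")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    warning("rank-deficient design: using minimum-norm pseudo-inverse solution")
    sv <- svd(design)
    pos <- sv$d > max(dim(design)) * .Machine$double.eps * sv$d[1L]
    W <- sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * crossprod(sv$u[, pos, drop = FALSE], response))
  } else {
    W <- qr.coef(qrX, response)
  }
  W <- as.matrix(W)
  list(filter = new("FullFilter",
                    weights = .coefToFilter(W, nDelays, embedDimN)),
       coef = W)
}

#' @describeIn predictSeries forward prediction with a dense filter,
#'   exploiting event sparsity (cost scales with the number of word events)
#' @export
setMethod("predictSeries", signature("FullFilter", "SparseEmbeddingSeries"),
  function(filter, series) {
    W <- filter@weights
    D <- dim(W)[1L]; N <- dim(W)[2L]; C <- dim(W)[3L]
    if (ncol(series@embeddings) != N)
      stop("embedding dimension does not match filter")
    T <- series@nSamples
    pred <- matrix(0, T, C)
    if (length(series@onsets) == 0L) return(pred)
    E <- series@embeddings
    tau <- series@onsets
    for (d in 0:(D - 1L)) {
      rows <- tau + d + 1L
      ok <- rows <= T
      if (!any(ok)) break
      Fd <- matrix(W[d + 1L, , ], N, C)
      contrib <- E[ok, , drop = FALSE] %*% Fd
      pred[rows[ok], ] <- pred[rows[ok], ] + contrib
    }
    pred
  })

#' Forward prediction from a dense filter (function form)
#'
#' @param filter a [FullFilter-class]
#' @param series a [SparseEmbeddingSeries-class]
#' @return T x C matrix
#' @export
predictFull <- function(filter, series) predictSeries(filter, series)
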