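#' Construct a repeat set
#'
#' @param repeats n_rep x T x C array, or list of T x C matrices
#' @param rateHz sampling rate
#' @return a [RepeatSet-class]
#' @export
repeatSet <- function(repeats, rateHz = 50) {
  if (is.list(repeats)) {
    d <- dim(repeats[[1L]])
    arr <- array(0, dim = c(length(repeats), d[1L], d[2L]))
    for (k in seq_along(repeats)) arr[k, , ] <- repeats[[k]]
    repeats <- arr
  }
  new("RepeatSet", repeats = repeats, rateHz = rateHz)
}

#' Noise ceiling (CCmax) from repeated presentations
#'
#' Per channel, with y_n the n-th repeat and n_rep repeats, signal power is
#' estimated as
#' `SP = (Var_t(sum_n y_n) - sum_n Var_t(y_n)) / (n_rep * (n_rep - 1))`
#' and the ceiling as `CCmax = sqrt(SP / Var_t(mean_n y_n))`: the maximum
#' correlation any noiseless model of the repeat-shared signal could reach
#' against the repeat mean. Channels whose estimate is non-finite,
#' non-positive under the square root, or below `floor` are clamped to
#' `floor` (default 0.2) and flagged.
#'
#' @param repeats a [RepeatSet-class]
#' @param floor minimum admissible ceiling (clamp value)
#' @return list with `ccmax` (C-vector) and `clamped` (logical C-vector)
#' @export
ccMax <- function(repeats, floor = 0.2) {
  y <- repeats@repeats
  nRep <- dim(y)[1L]
  C <- dim(y)[3L]
  ccmax <- numeric(C)
  clamped <- logical(C)
  for (c in seq_len(C)) {
    yc <- t(y[, , c])                         # T x n_rep
    sp <- (stats::var(rowSums(yc)) - sum(apply(yc, 2L, stats::var))) /
      (nRep * (nRep - 1))
    vm <- stats::var(rowMeans(yc))
    val <- if (vm > 0 && sp > 0) sqrt(sp / vm) else NaN
    if (!is.finite(val) || val < floor) {
      ccmax[c] <- floor
      clamped[c] <- TRUE
    } else {
      ccmax[c] <- val
    }
  }
  list(ccmax = ccmax, clamped = clamped)
}

#' Ceiling-normalized correlation (CCnorm)
#'
#' Per channel: the Pearson correlation between the prediction and the mean
#' response over repeats, divided by the channel's noise ceiling. A channel
#' with zero prediction variance gets CCnorm 0.
#'
#' @param prediction T x C matrix, time-aligned with the repeats
#' @param repeats a [RepeatSet-class]
#' @param ccmax per-channel ceiling (defaults to [ccMax()] with floor 0.2)
#' @return C-vector of CCnorm values
#' @export
ccNorm <- function(prediction, repeats, ccmax = ccMax(repeats)$ccmax) {
  y <- repeats@repeats
  if (nrow(prediction) != dim(y)[2L] || ncol(prediction) != dim(y)[3L])
    stop("prediction must be T x C aligned with the repeats")
  C <- ncol(prediction)
  vapply(seq_len(C), function(c) {
    ybar <- colMeans(y[, , c])
    safeCor(ybar, prediction[, c]) / ccmax[c]
  }, numeric(1))
}

#' Evaluate a model prediction against a repeat set
#'
#' Convenience wrapper producing a full [EvalReport-class].
#'
#' @inheritParams ccNorm
#' @param floor ceiling clamp floor
#' @param clampedOnly if TRUE, mean CCnorm is restricted to channels whose
#'   ceiling was *not* clamped; default averages all channels
#' @return an [EvalReport-class]
#' @export
evaluateModel <- function(prediction, repeats, floor = 0.2,
                          clampedOnly = FALSE) {
  cm <- ccMax(repeats, floor = floor)
  cn <- ccNorm(prediction, repeats, cm$ccmax)
  keep <- if (clampedOnly) !cm$clamped else rep(TRUE, length(cn))
  new("EvalReport", ccmax = cm$ccmax, ccnorm = cn,
      meanCCnorm = mean(cn[keep]), clamped = cm$clamped)
}

#' Excess noise ceiling over post-word-onset windows
#'
#' For each latency window k (default: 100 ms windows spanning 0..800 ms, so
#' 8 windows of 5 samples at 50 Hz), the samples t whose lag t - tau to some
#' word onset tau falls in the window are concatenated into a subsampled
#' series, CCmax is computed on that subset, and the whole-series CCmax is
#' subtracted. Positive excess in a window means the signal is more
#' predictable at that latency than on average.
#'
#' @param repeats a [RepeatSet-class]
#' @param onsets 0-based word-onset samples
#' @param windowMs window width in ms (must divide into whole samples)
#' @param maxLagMs maximum post-onset lag covered
#' @param rateHz sampling rate
#' @param floor ceiling clamp floor
#' @param attribution `"all"`: a sample belongs to every window it falls in
#'   for any word in lag range (words closer than `maxLagMs` overlap);
#'   `"nearest"`: each sample is attributed only to the nearest preceding
#'   word
#' @return windows x C matrix of excess CCmax, with window start times (ms)
#'   as rownames
#' @export
excessCCmax <- function(repeats, onsets, windowMs = 100, maxLagMs = 800,
                        rateHz = repeats@rateHz, floor = 0.2,
                        attribution = c("all", "nearest")) {
  attribution <- match.arg(attribution)
  wSamp <- windowMs * rateHz / 1000
  maxSamp <- maxLagMs * rateHz / 1000
  if (abs(wSamp - round(wSamp)) > 1e-9 || abs(maxSamp - round(maxSamp)) > 1e-9)
    stop("window and max lag must be whole numbers of samples at this rate")
  wSamp <- as.integer(round(wSamp))
  maxSamp <- as.integer(round(maxSamp))
  nWin <- maxSamp %/% wSamp
  T <- dim(repeats@repeats)[2L]
  C <- dim(repeats@repeats)[3L]
  whole <- ccMax(repeats, floor = floor)$ccmax
  if (attribution == "nearest") {
    # lag to nearest preceding onset, per sample
    lastOnset <- rep(NA_integer_, T)
    idx <- sort(onsets) + 1L
    lastOnset[idx] <- idx - 1L
    filled <- cummax(ifelse(is.na(lastOnset), -1L, lastOnset))
    lag <- (seq_len(T) - 1L) - filled
    lag[filled < 0L] <- NA_integer_
  }
  out <- matrix(NA_real_, nWin, C,
                dimnames = list(seq(0, by = windowMs, length.out = nWin),
                                NULL))
  for (k in seq_len(nWin)) {
    lo <- (k - 1L) * wSamp
    hi <- k * wSamp - 1L
    sel <- if (attribution == "all") {
      s <- unique(unlist(lapply(lo:hi, function(d) onsets + d)))
      sort(s[s >= 0L & s < T]) + 1L
    } else {
      which(!is.na(lag) & lag >= lo & lag <= hi)
    }
    if (length(sel) < 3L)
      stop(sprintf("window %d (%d-%d ms) selects too few samples", k,
                   (k - 1L) * windowMs, k * windowMs))
    sub <- new("RepeatSet",
               repeats = repeats@repeats[, sel, , drop = FALSE],
               rateHz = rateHz)
    out[k, ] <- ccMax(sub, floor = floor)$ccmax - whole
  }
  out
}

#' PCA of the excess-CCmax matrix over channels
#'
#' Decomposes the windows x channels excess matrix into principal components:
#' per-component latency timecourses (scores over windows) and channel
#' loadings.
#'
#' @param excess windows x C matrix (see [excessCCmax()])
#' @param nComp components to return (default 2)
#' @return list with `timecourses` (windows x nComp scores), `loadings`
#'   (C x nComp) and `explainedVarianceRatio`
#' @export
excessPCA <- function(excess, nComp = 2L) {
  if (nrow(excess) < 2L) stop("need at least 2 windows")
  pc <- stats::prcomp(excess, center = TRUE, scale. = FALSE)
  nComp <- min(nComp, ncol(pc$rotation))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(timecourses = pc$x[, seq_len(nComp), drop = FALSE],
       loadings = pc$rotation[, seq_len(nComp), drop = FALSE],
       explainedVarianceRatio = evr)
}

#' Bootstrap comparison of two models' per-channel CCnorm
#'
#' Resamples channels with replacement and reports the fraction of bootstrap
#' mean differences (a - b) that are <= 0: a small value supports a > b.
#'
#' @param ccnormA,ccnormB per-channel CCnorm vectors of the two models
#' @param nBoot bootstrap draws
#' @param seed RNG seed
#' @return one-sided p-value
#' @export
bootstrapCompare <- function(ccnormA, ccnormB, nBoot = 10000L, seed = 1L) {
  if (length(ccnormA) != length(ccnormB))
    stop("CCnorm vectors must have equal length")
  if (nBoot < 100L)
    warning("fewer than 100 bootstrap draws: p-value will be coarse")
  d <- ccnormA - ccnormB
  C <- length(d)
  withSeed(seed, {
    boot <- vapply(seq_len(nBoot),
                   function(i) mean(d[sample.int(C, C, replace = TRUE)]),
                   numeric(1))
    mean(boot <= 0)
  })
}

#' Permutation test of a model against chance
#'
#' Builds the null by circularly shifting the prediction in time relative to
#' the data by random offsets of at least `blockLen` samples (preserving the
#' prediction's autocorrelation; a zero shift is never in the null). The
#' statistic is mean CCnorm over channels; the p-value uses the add-one
#' convention `p = (1 + #{null >= observed}) / (nPerm + 1)`.
#'
#' @param prediction T x C prediction matrix
#' @param repeats a [RepeatSet-class]
#' @param nPerm number of random shifts
#' @param blockLen minimum shift in samples
#' @param seed RNG seed
#' @param floor ceiling clamp floor
#' @return list with `p`, `observed` and `null` (the null statistics)
#' @export
permutationTest <- function(prediction, repeats, nPerm = 1000L,
                            blockLen = 50L, seed = 1L, floor = 0.2) {
  T <- nrow(prediction)
  if (T <= 2L * blockLen)
    stop("series too short for the requested minimum shift")
  cm <- ccMax(repeats, floor = floor)$ccmax
  obs <- mean(ccNorm(prediction, repeats, cm))
  withSeed(seed, {
    shifts <- sample(seq.int(blockLen, T - blockLen), nPerm, replace = TRUE)
    null <- vapply(shifts, function(s) {
      shifted <- prediction[c((s + 1L):T, 1L:s), , drop = FALSE]
      mean(ccNorm(shifted, repeats, cm))
    }, numeric(1))
    list(p = (1 + sum(null >= obs)) / (nPerm + 1), observed = obs,
         null = null)
  })
}
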