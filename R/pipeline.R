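#' Run the end-to-end synthetic workflow
#'
#' Simulates (or loads) a dataset, z-scores the training recordings, reduces
#' embeddings by PCA fit on training stories only, fits the full-rank ridge
#' baseline and a sweep of low-rank CP models, evaluates everything on the
#' held-out repeated story, optionally residualizes against binary event
#' controls and refits, and writes all artifacts (JSON reports, CSV matrices)
#' to `outDir`. The held-out story never enters any training fold. Every
#' artifact records the configuration and seed it was produced under.
#'
#' @param cfg a [SimConfig-class] (used when `dataset` is NULL)
#' @param outDir output directory
#' @param ranks ranks to sweep (default 1, 2, 3, 5)
#' @param dataset optional pre-built [StoryDataset-class]; defaults to
#'   `simulateDataset(cfg)`
#' @param pcaVariance PCA variance threshold (default 0.95)
#' @param ridgeCfg a [ridgeConfig()]
#' @param trainCfg a [trainConfig()] template; the seed is offset per rank
#' @param residualizeControls also run the event-feature residualization
#'   branch and refit at the best rank
#' @param nTopContexts most-activating contexts to report per component
#' @param verbose log one line per stage
#' @return (invisibly) list with the fitted models, evaluation table and
#'   paths of written artifacts
#' @export
runPipeline <- function(cfg, outDir, ranks = c(1L, 2L, 3L, 5L),
                        dataset = NULL, pcaVariance = 0.95,
                        ridgeCfg = ridgeConfig(),
                        trainCfg = trainConfig(seed = cfg@seed),
                        residualizeControls = FALSE,
                        nTopContexts = 5L, verbose = TRUE) {
  log <- function(...) if (verbose) message(sprintf(...))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(dataset)) {
    log("simulate: %d stories, seed %d", cfg@nStories, cfg@seed)
    dataset <- simulateDataset(cfg)
  }
  D <- cfg@nDelays

  # --- normalization + PCA (train stories only) ---
  trainRecs <- lapply(dataset@stories, function(s) zscoreRecording(s$recording))
  trainEmb <- do.call(rbind, lapply(dataset@stories,
                                    function(s) s$embeddings@embeddings))
  reducer <- fitPCA(trainEmb, pcaVariance)
  log("pca: %d -> %d dims (threshold %.2f)", ncol(trainEmb), reducer@k,
      pcaVariance)
  trainSeries <- lapply(dataset@stories, function(s)
    buildSeries(s$stream, applyPCA(reducer, s$embeddings)))
  testSeries <- buildSeries(dataset@testStory$stream,
                            applyPCA(reducer, dataset@testStory$embeddings))
  repeats <- dataset@testStory$repeats

  # --- full-rank ridge baseline ---
  design <- do.call(rbind, lapply(trainSeries, laggedDesign, nDelays = D))
  response <- do.call(rbind, lapply(trainRecs, function(r) r@signal))
  folds <- sequentialFolds(vapply(trainSeries, function(s) s@nSamples,
                                  integer(1)), ridgeCfg$nFolds)
  full <- fitRidge(design, response, D, reducer@k, ridgeCfg, folds)
  fullEval <- evaluateModel(predictSeries(full$filter, testSeries), repeats)
  log("full-rank ridge: mean CCnorm %.4f", meanCCnorm(fullEval))

  # --- rank sweep ---
  sweep <- lapply(ranks, function(R) {
    tc <- trainCfg
    tc$seed <- deriveSeed(trainCfg$seed, R)
    fit <- fitCP(trainSeries, trainRecs, rank = R, nDelays = D, cfg = tc)
    filt <- cpNormalize(fit$filter)
    ev <- evaluateModel(predictSeries(filt, testSeries), repeats)
    log("rank %d: mean CCnorm %.4f (%d epochs)", R, meanCCnorm(ev),
        fit$epochs)
    list(rank = R, filter = filt, eval = ev, epochs = fit$epochs,
         lossTrace = fit$lossTrace)
  })
  evalTab <- data.frame(
    model = c("fullrank", paste0("rank", ranks)),
    meanCCnorm = c(meanCCnorm(fullEval),
                   vapply(sweep, function(s) meanCCnorm(s$eval), numeric(1))))

  best <- sweep[[which.max(evalTab$meanCCnorm[-1L])]]
  infl <- looInfluence(best$filter, testSeries, repeats)
  corpus <- unlist(lapply(dataset@stories, function(s)
    contextWindows(s$stream, 5L)))
  corpusEmb <- do.call(rbind, lapply(dataset@stories, function(s) {
    e <- applyPCA(reducer, s$embeddings)@embeddings
    S <- nrow(e)
    if (S < 5L) return(NULL)
    # context embedding: the embedding of the window's last word
    e[5:S, , drop = FALSE]
  }))
  ctx <- topContexts(best$filter, corpus, corpusEmb, k = nTopContexts)

  # --- artifacts ---
  paths <- list()
  meta <- list(seed = cfg@seed,
               config = jsonlite::fromJSON(jsonlite::toJSON(
                 list(nStories = cfg@nStories,
                      samplesPerStory = cfg@samplesPerStory,
                      nChannels = cfg@nChannels, embedDim = cfg@embedDim,
                      nDelays = cfg@nDelays, rank = cfg@rank,
                      noiseSd = cfg@noiseSd, nRepeats = cfg@nRepeats,
                      pcaVariance = pcaVariance, ranks = ranks),
                 auto_unbox = TRUE)))
  report <- c(meta, list(
    pcaDims = reducer@k,
    evaluation = evalTab,
    bestRank = best$rank,
    influence = infl,
    lambda = full$lambda,
    delayPower = delayPower(best$filter),
    channelPower = channelPower(best$filter)))
  paths$report <- file.path(outDir, "report.json")
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths$evaluation <- file.path(outDir, "evaluation.csv")
  data.table::fwrite(evalTab, paths$evaluation)
  paths$contexts <- file.path(outDir, "top_contexts.csv")
  data.table::fwrite(ctx, paths$contexts)
  for (s in sweep) {
    p <- file.path(outDir, sprintf("cpfilter_rank%02d.csv", s$rank))
    writeCPFilter(s$filter, p)
    paths[[sprintf("filter_rank%d", s$rank)]] <- p
  }

  out <- list(dataset = dataset, reducer = reducer, fullrank = full,
              fullEval = fullEval, sweep = sweep, evaluation = evalTab,
              influence = infl, contexts = ctx, paths = paths)

  if (residualizeControls) {
    log("residualize: event controls, joint fit")
    ctrlTrain <- lapply(dataset@stories, function(s)
      buildControlDesign(NULL, s$stream))
    ctrlTest <- buildControlDesign(NULL, dataset@testStory$stream)
    nRep <- dim(repeats@repeats)[1L]
    allRecs <- c(trainRecs, lapply(seq_len(nRep), function(k)
      new("StoryRecording", signal = repeats@repeats[k, , ],
          rateHz = repeats@rateHz, zscored = FALSE,
          storyId = paste0("test_rep", k))))
    allCtrl <- c(ctrlTrain, rep(list(ctrlTest), nRep))
    rr <- residualize(allRecs, allCtrl)
    residTrain <- rr$residuals[seq_along(trainRecs)]
    residReps <- repeatSet(lapply(rr$residuals[-seq_along(trainRecs)],
                                  function(r) r@signal),
                           rateHz = repeats@rateHz)
    tc <- trainCfg
    tc$seed <- deriveSeed(trainCfg$seed, 999L)
    refit <- fitCP(trainSeries, residTrain, rank = best$rank, nDelays = D,
                   cfg = tc)
    refilt <- cpNormalize(refit$filter)
    rEval <- evaluateModel(predictSeries(refilt, testSeries), residReps)
    log("residual refit rank %d: mean CCnorm %.4f", best$rank,
        meanCCnorm(rEval))
    out$residual <- list(filter = refilt, eval = rEval,
                         delayPower = delayPower(refilt),
                         channelPower = channelPower(refilt))
  }
  invisible(out)
}
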