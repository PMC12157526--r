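# write a numeric matrix as CSV at %.17g so doubles round-trip bit-exactly
.writeMatrixCSV <- function(m, path) {
  ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  dt <- data.table::as.data.table(ch)
  data.table::setnames(dt, paste0("V", seq_len(ncol(m))))
  data.table::fwrite(dt, path, quote = FALSE)
}

#' Write a dataset to a directory container
#'
#' One directory per dataset: a `dataset.json` sidecar (schema version,
#' configuration, story index, z-scoring state) plus per-story CSV matrices
#' for the recording, the word table (word, onset, flags) and the embedding
#' matrix; repeats of the held-out story are stored one CSV per repeat.
#'
#' @param dataset a [StoryDataset-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema = "tensorTRF-dataset-v1",
               nStories = length(dataset@stories),
               storyIds = vapply(dataset@stories,
                                 function(s) s$stream@storyId, character(1)),
               hasTest = length(dataset@testStory) > 0L)
  if (is(dataset@config, "SimConfig")) {
    cfg <- dataset@config
    meta$config <- list(
      nStories = cfg@nStories, samplesPerStory = cfg@samplesPerStory,
      nChannels = cfg@nChannels, embedDim = cfg@embedDim,
      nDelays = cfg@nDelays, rank = cfg@rank,
      meanWordGap = cfg@meanWordGap, noiseSd = cfg@noiseSd,
      nRepeats = cfg@nRepeats, seed = cfg@seed,
      embedDecay = cfg@embedDecay, alpha = cfg@alpha, rateHz = cfg@rateHz)
  }
  writeStory <- function(story, name) {
    st <- story$stream
    zs <- if (!is.null(story$recording)) story$recording@zscored else FALSE
    data.table::fwrite(
      data.frame(word = st@words, onset = st@onsets,
                 sentence_start = as.integer(st@sentenceStart),
                 sentence_end = as.integer(st@sentenceEnd)),
      file.path(dir, paste0(name, "_words.csv")))
    .writeMatrixCSV(story$embeddings@embeddings,
                    file.path(dir, paste0(name, "_embeddings.csv")))
    if (!is.null(story$recording))
      .writeMatrixCSV(story$recording@signal,
                      file.path(dir, paste0(name, "_recording.csv")))
    list(id = st@storyId, nSamples = st@nSamples, zscored = zs,
         contextLen = story$embeddings@contextLen,
         provenance = story$embeddings@provenance)
  }
  meta$stories <- lapply(seq_along(dataset@stories), function(i)
    writeStory(dataset@stories[[i]], sprintf("story%03d", i)))
  if (meta$hasTest) {
    ts <- dataset@testStory
    meta$test <- writeStory(list(stream = ts$stream,
                                 embeddings = ts$embeddings), "test")
    reps <- ts$repeats@repeats
    meta$test$nRepeats <- dim(reps)[1L]
    meta$test$rateHz <- ts$repeats@rateHz
    for (k in seq_len(dim(reps)[1L]))
      .writeMatrixCSV(reps[k, , ],
                      file.path(dir, sprintf("test_repeat%02d.csv", k)))
  }
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset from a directory container
#'
#' Validates the schema and per-story alignment (onsets within range, one
#' embedding row per word); failures name the offending story and field.
#'
#' @param dir dataset directory written by [writeDataset()]
#' @return a [StoryDataset-class]
#' @export
readDataset <- function(dir) {
  metaPath <- file.path(dir, "dataset.json")
  if (!file.exists(metaPath)) stop("no dataset.json in ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$schema, "tensorTRF-dataset-v1"))
    stop("unrecognized dataset schema: ", meta$schema)
  readStory <- function(info, name, withRecording = TRUE) {
    words <- data.table::fread(file.path(dir, paste0(name, "_words.csv")),
                               data.table = FALSE)
    emb <- as.matrix(data.table::fread(
      file.path(dir, paste0(name, "_embeddings.csv")), data.table = FALSE))
    if (nrow(emb) != nrow(words))
      stop(sprintf("story '%s': embedding rows (%d) do not match words (%d)",
                   info$id, nrow(emb), nrow(words)))
    if (nrow(words) > 0L &&
        (min(words$onset) < 0L || max(words$onset) >= info$nSamples))
      stop(sprintf("story '%s': field 'onset' outside [0, %d)",
                   info$id, info$nSamples))
    stream <- new("WordStream", words = as.character(words$word),
                  onsets = as.integer(words$onset),
                  sentenceStart = as.logical(words$sentence_start),
                  sentenceEnd = as.logical(words$sentence_end),
                  storyId = info$id, nSamples = as.integer(info$nSamples))
    out <- list(stream = stream,
                embeddings = new("EmbeddingSet", embeddings = emb,
                                 contextLen = as.integer(info$contextLen),
                                 provenance = info$provenance))
    if (withRecording) {
      rec <- as.matrix(data.table::fread(
        file.path(dir, paste0(name, "_recording.csv")), data.table = FALSE))
      if (nrow(rec) != info$nSamples)
        stop(sprintf("story '%s': field 'recording' has %d rows, expected %d",
                     info$id, nrow(rec), info$nSamples))
      out$recording <- new("StoryRecording", signal = unname(rec),
                           rateHz = meta$config$rateHz %||% 50,
                           zscored = isTRUE(info$zscored), storyId = info$id)
    }
    out
  }
  storiesMeta <- meta$stories
  if (is.data.frame(storiesMeta))
    storiesMeta <- split(storiesMeta, seq_len(nrow(storiesMeta)))
  stories <- lapply(seq_along(storiesMeta), function(i)
    readStory(as.list(storiesMeta[[i]]), sprintf("story%03d", i)))
  test <- list()
  if (isTRUE(meta$hasTest)) {
    info <- as.list(meta$test)
    test <- readStory(info, "test", withRecording = FALSE)
    reps <- lapply(seq_len(info$nRepeats), function(k)
      unname(as.matrix(data.table::fread(
        file.path(dir, sprintf("test_repeat%02d.csv", k)),
        data.table = FALSE))))
    test$repeats <- repeatSet(reps, rateHz = info$rateHz %||% 50)
  }
  cfg <- NULL
  if (!is.null(meta$config)) {
    mc <- meta$config
    cfg <- simConfig(nStories = mc$nStories,
                     samplesPerStory = mc$samplesPerStory,
                     nChannels = mc$nChannels, embedDim = mc$embedDim,
                     nDelays = mc$nDelays, rank = mc$rank,
                     meanWordGap = mc$meanWordGap, noiseSd = mc$noiseSd,
                     nRepeats = mc$nRepeats, seed = mc$seed,
                     embedDecay = mc$embedDecay, alpha = mc$alpha,
                     rateHz = mc$rateHz)
  }
  new("StoryDataset", stories = stories, testStory = test,
      truth = NULL, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a word-timing transcript
#'
#' TSV with columns `word`, `onset_seconds`, `sentence_start`,
#' `sentence_end`; onsets are converted to samples at the given rate.
#'
#' @param path TSV path
#' @param rateHz recording sampling rate
#' @param nSamples recording length in samples (onsets must fall inside)
#' @param storyId identifier for the resulting stream
#' @return a [WordStream-class]
#' @export
readTranscript <- function(path, rateHz = 50, nSamples, storyId = basename(path)) {
  tab <- data.table::fread(path, data.table = FALSE)
  need <- c("word", "onset_seconds", "sentence_start", "sentence_end")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("transcript is missing column(s): ", paste(miss, collapse = ", "))
  onsets <- as.integer(round(tab$onset_seconds * rateHz))
  new("WordStream", words = as.character(tab$word), onsets = onsets,
      sentenceStart = as.logical(tab$sentence_start),
      sentenceEnd = as.logical(tab$sentence_end),
      storyId = storyId, nSamples = as.integer(nSamples))
}

#' Write a CP filter to CSV
#'
#' Long format: one row per (component, mode, index) with full-precision
#' values, plus alpha rows (index 0) and a header comment-free layout that
#' [readCPFilter()] inverts exactly.
#'
#' @param filter a [CPFilter-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeCPFilter <- function(filter, path) {
  long <- rbind(
    data.frame(component = seq_len(filterRank(filter)), mode = "alpha",
               index = 0L, value = sprintf("%.17g", filter@alpha)),
    .factorLongChr(filter@delayFactors, "delay"),
    .factorLongChr(filter@embedFactors, "embedding"),
    .factorLongChr(filter@channelFactors, "channel"))
  long$normalized <- filter@normalized
  data.table::fwrite(long, path, quote = FALSE)
  invisible(path)
}

.factorLongChr <- function(m, mode) {
  data.frame(component = rep(seq_len(nrow(m)), ncol(m)),
             mode = mode,
             index = rep(seq_len(ncol(m)), each = nrow(m)),
             value = sprintf("%.17g", as.vector(m)))
}

#' Read a CP filter written by [writeCPFilter()]
#'
#' @param path CSV path
#' @return a [CPFilter-class]
#' @export
readCPFilter <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE,
                           colClasses = list(character = "value"))
  val <- as.numeric(tab$value)
  grab <- function(mode) {
    rows <- tab$mode == mode
    R <- max(tab$component[rows])
    matrix(val[rows], R, sum(rows) / R)
  }
  cpFilter(grab("delay"), grab("embedding"), grab("channel"),
           alpha = val[tab$mode == "alpha"],
           normalized = isTRUE(tab$normalized[1]))
}
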