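# internal helpers

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stream seed below 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %%
               .Machine$integer.max)
}

# Unit-norm rows of a matrix; errors on zero rows.
unitRows <- function(m, what = "factor") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stop(sprintf("degenerate %s: zero row(s) %s", what,
                 paste(which(nrm == 0), collapse = ", ")))
  m / nrm
}

# Pearson correlation that returns 0 (with optional message) when either
# vector has zero variance.
safeCor <- function(x, y, quiet = TRUE) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (!quiet)
      message("zero-variance input: correlation defined as 0")
    return(0)
  }
  stats::cor(x, y)
}

stopifnot_dim <- function(ok, msg) {
  if (!ok) stop(msg, call. = FALSE)
}
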