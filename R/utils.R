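# Internal helpers: argument checking, seeded RNG streams, small conveniences.

assert_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer, got %s", name, format(x)), call. = FALSE)
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a root seed and a stream index to a seed below 2^31, so that
#' independent components (one per sample, per replicate cohort, ...) can be
#' regenerated individually without sharing RNG state.
#'
#' @param seed integer root seed.
#' @param stream non-negative integer stream index.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  s <- (s * 48271 + as.double(stream) * 8191 + 12820163) %% m
  as.integer(s)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random DNA strings of fixed length.
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
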