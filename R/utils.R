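#' @include AllClasses.R
NULL

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Positions (1-based) of residues not in the standard alphabet; integer(0)
# if clean.
nonstandard_positions <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  which(!(chars %in% AA_ALPHABET20))
}

assert_standard <- function(sequence, what = "sequence") {
  bad <- nonstandard_positions(sequence)
  if (length(bad))
    stop(what, " contains nonstandard residue '",
         substr(sequence, bad[1], bad[1]), "' at position ", bad[1],
         call. = FALSE)
  invisible(TRUE)
}

# Truncated rolling mean: mean of x over [i-h, i+h] clipped to [1, n].
rolling_mean_truncated <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
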