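# Independent oracles used across the suite. Each reimplements a quantity
# from first principles (dynamic programming, explicit entropy sums, pair
# counting) without touching the package's own code paths.

# Needleman-Wunsch global alignment identity: match 1, mismatch 0, linear
# gap -1; identity = matches / alignment columns along one optimal
# traceback (diagonal preferred at ties).
nw_identity_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                             S[i, j + 1] - 1,
                             S[i + 1, j] - 1)
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j])
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  matches / cols
}

# Information gain in bits by explicit entropy sums over the same
# equal-width binning contract.
ig_oracle <- function(x, labels, bins = 10L) {
  ent <- function(v) {
    p <- table(v) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  rng <- range(x)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, length(x))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    bin <- findInterval(x, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  hy <- ent(labels)
  hyx <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    hyx <- hyx + mean(sel) * ent(labels[sel])
  }
  hy - hyx
}

# AUC by O(n^2) concordance counting: ties count half.
auc_oracle <- function(scores, truth) {
  pos <- which(as.logical(truth))
  neg <- which(!as.logical(truth))
  tot <- 0
  for (i in pos)
    for (j in neg)
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# A random standard-alphabet sequence under a local seed.
random_sequence <- function(n, seed = NULL) {
  draw <- function() paste(sample(mitocompart::AA_ALPHABET20, n,
                                  replace = TRUE), collapse = "")
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw()
}
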