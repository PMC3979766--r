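# deterministic fixtures shared across the suite

# G well-separated spherical Gaussian blobs in d dimensions
makeBlobs <- function(n = 60, G = 2, d = 2, sep = 10, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(0, G, d)
  for (g in seq_len(G)) centers[g, 1:min(2, d)] <-
    sep * c(cos(2 * pi * g / G), sin(2 * pi * g / G))[1:min(2, d)]
  labels <- rep(seq_len(G), length.out = n)
  x <- centers[labels, , drop = FALSE] + matrix(rnorm(n * d, sd = sd), n, d)
  rownames(x) <- sprintf("b%03d", seq_len(n))
  list(x = x, labels = labels, centers = centers)
}

# O(n^2) brute-force pair counting over all object pairs
bruteForcePairCounts <- function(truth, pred) {
  n <- length(truth)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    st <- truth[i] == truth[j]
    sp <- pred[i] == pred[j]
    if (st && sp) tp <- tp + 1L
    else if (!st && sp) fp <- fp + 1L
    else if (st && !sp) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}
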