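#' @include core.R
NULL

# ---------------------------------------------------------------------------
# Synthetic benchmark generators. Each returns list(x = matrix with row ids,
# labels = integer ground truth). All randomness comes from R's global RNG;
# pass `seed` (or call set.seed()) for reproducibility.
# ---------------------------------------------------------------------------

.idRows <- function(x, prefix) {
  rownames(x) <- sprintf("%s%04d", prefix, seq_len(nrow(x)))
  x
}

#' Simulate QPSK constellation data
#'
#' Symbols are drawn uniformly from the four unit-energy constellation
#' points (+-1/sqrt(2), +-1/sqrt(2)) and perturbed by white Gaussian noise
#' with per-dimension variance `10^(-snrDb/10) / 2` (the Es/N0 convention
#' with unit symbol energy). Viewed as a mixture, this is a 4-component
#' spherical Gaussian benchmark.
#'
#' @param n number of samples (default 512).
#' @param snrDb signal-to-noise ratio in dB (default 15).
#' @param seed optional integer seed.
#' @return list with `x` (n x 2 matrix) and `labels` (symbol index 1..4).
#' @examples
#' sim <- simulateQPSK(n = 64, seed = 1)
#' table(sim$labels)
#' @export
simulateQPSK <- function(n = 512L, snrDb = 15, seed = NULL) {
  stopifnot(n >= 4, is.finite(snrDb))
  if (!is.null(seed)) set.seed(seed)
  corners <- matrix(c(1, 1, -1, 1, -1, -1, 1, -1), ncol = 2, byrow = TRUE) / sqrt(2)
  labels <- sample.int(4L, n, replace = TRUE)
  sigma <- sqrt(10^(-snrDb / 10) / 2)
  x <- corners[labels, , drop = FALSE] + matrix(stats::rnorm(2 * n, sd = sigma), n, 2)
  list(x = .idRows(x, "s"), labels = labels)
}

#' Simulate a finite Gaussian mixture
#'
#' Component membership is multinomial in `weights`; points are drawn from
#' the member's Gaussian. The default is the overlapping 3-component
#' bivariate demonstration: equal weights, collinear means two units apart
#' on one axis, and a shared diagonal covariance at double the scale of the
#' classic version (diag(4, 0.4)).
#'
#' @param n number of samples (default 900).
#' @param weights mixing probabilities.
#' @param means list of component mean vectors.
#' @param covariances list of component covariance matrices.
#' @param seed optional integer seed.
#' @return list with `x` and `labels`.
#' @export
simulateGMM <- function(n = 900L,
                        weights = rep(1 / 3, 3),
                        means = list(c(0, -2), c(0, 0), c(0, 2)),
                        covariances = rep(list(diag(c(4, 0.4))), 3),
                        seed = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-9,
            length(weights) == length(means),
            length(weights) == length(covariances))
  if (!is.null(seed)) set.seed(seed)
  d <- length(means[[1L]])
  chols <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    if (all(S == 0)) return(matrix(0, nrow(S), ncol(S)))  # degenerate: points at the mean
    tryCatch(chol(S), error = function(e)
      stop("component covariance is not positive semi-definite"))
  })
  labels <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  z <- matrix(stats::rnorm(n * d), n, d)
  x <- matrix(0, n, d)
  for (m in seq_along(weights)) {
    idx <- which(labels == m)
    if (length(idx))
      x[idx, ] <- z[idx, , drop = FALSE] %*% chols[[m]] +
        rep(means[[m]], each = length(idx))
  }
  list(x = .idRows(x, "s"), labels = labels)
}

#' Simulate state-based gene-expression data
#'
#' A hierarchical model of condition-grouped expression: each cluster draws
#' a size from a floored Poisson, partitions the sample axis into four
#' contiguous periods (a uniform random composition, each period non-empty),
#' draws a period-level template value from N(0, templateSd^2), a per-sample
#' template from N(template, sampleSd^2), per-gene values from
#' N(sample template, geneSd^2), and finally adds N(0, noiseSd^2) noise.
#'
#' @param k number of clusters (default 11).
#' @param sizeMean Poisson mean of cluster sizes (default 60; floor 10).
#' @param mSamples number of samples/columns (default 20; at least 4).
#' @param templateSd,sampleSd,geneSd hierarchy scales (defaults 1.5, 0.5,
#'   0.5).
#' @param noiseSd additive noise standard deviation (default 0).
#' @param seed optional integer seed.
#' @return list with `x` (genes x samples) and `labels`.
#' @export
simulateS1 <- function(k = 11L, sizeMean = 60, mSamples = 20L,
                       templateSd = 1.5, sampleSd = 0.5, geneSd = 0.5,
                       noiseSd = 0, seed = NULL) {
  stopifnot(k >= 2, sizeMean > 0,
            templateSd >= 0, sampleSd >= 0, geneSd >= 0, noiseSd >= 0)
  if (mSamples < 4L) stop("cannot form 4 expression periods with fewer than 4 samples")
  if (!is.null(seed)) set.seed(seed)
  blocks <- vector("list", k)
  labels <- integer(0)
  for (c in seq_len(k)) {
    size <- max(10L, stats::rpois(1L, sizeMean))
    cuts <- sort(sample.int(mSamples - 1L, 3L))
    periodOf <- findInterval(seq_len(mSamples) - 1L, c(0L, cuts)) # 1..4
    template <- stats::rnorm(4L, 0, templateSd)[periodOf]
    tSample <- stats::rnorm(mSamples, template, sampleSd)
    g <- matrix(stats::rnorm(size * mSamples, rep(tSample, each = size), geneSd),
                size, mSamples)
    if (noiseSd > 0)
      g <- g + matrix(stats::rnorm(size * mSamples, 0, noiseSd), size, mSamples)
    blocks[[c]] <- g
    labels <- c(labels, rep(c, size))
  }
  x <- do.call(rbind, blocks)
  list(x = .idRows(x, "g"), labels = labels)
}

#' Simulate periodic (cell-cycle style) gene-expression data
#'
#' Cyclic expression for gene g of cluster c at time point j (j = 0..m-1):
#' `x = (lam + thetaMag * u) * sin(2 pi j / 8 + omega_c + thetaPhase * v)`,
#' with u, v independent standard normal draws per gene and time point, a
#' period of 8 samples, and equally spaced cluster phases
#' `omega_c = 2 pi c / k`. The two theta parameters jointly set the noise
#' power: one perturbs the amplitude, the other the phase.
#'
#' @param g number of genes (default 500; must be divisible by `k`).
#' @param m number of samples (default 24).
#' @param k number of clusters (default 5).
#' @param lam sinusoid amplitude (default 3).
#' @param thetaMag amplitude-noise scale (default 0.1).
#' @param thetaPhase phase-noise scale (default 0.1).
#' @param seed optional integer seed.
#' @return list with `x` (g x m) and `labels`.
#' @export
simulateS2 <- function(g = 500L, m = 24L, k = 5L, lam = 3,
                       thetaMag = 0.1, thetaPhase = 0.1, seed = NULL) {
  stopifnot(g %% k == 0, m >= 8)
  if (!is.null(seed)) set.seed(seed)
  perCluster <- g %/% k
  labels <- rep(seq_len(k), each = perCluster)
  omega <- 2 * pi * labels / k
  j <- matrix(rep(seq_len(m) - 1L, each = g), g, m)
  u <- matrix(stats::rnorm(g * m), g, m)
  v <- matrix(stats::rnorm(g * m), g, m)
  x <- (lam + thetaMag * u) * sin(2 * pi * j / 8 + omega + thetaPhase * v)
  list(x = .idRows(x, "g"), labels = labels)
}
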