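#' @include core.R AllGenerics.R
NULL

#' Free parameters per mixture component
#'
#' `N`, the number of parameters each component carries: d mean coordinates
#' plus d(d+1)/2 (full), d (diagonal) or 1 (spherical) covariance parameters.
#' Half of `N` is also the annihilation support threshold of the modified
#' component-wise EM.
#'
#' @param d feature dimension.
#' @param covStructure covariance-structure tag.
#' @return integer parameter count.
#' @examples
#' nParamsPerComponent(2, "full")      # 5
#' nParamsPerComponent(38, "diagonal") # 76
#' @export
nParamsPerComponent <- function(d, covStructure = c("full", "diagonal", "spherical")) {
  covStructure <- match.arg(covStructure)
  stopifnot(d >= 1)
  as.integer(switch(covStructure,
    full      = d + d * (d + 1) / 2,
    diagonal  = 2 * d,
    spherical = d + 1
  ))
}

#' @rdname messageLength
#' @param mixture a [MixtureModel-class] (for the matrix method).
#' @export
setMethod("messageLength", "matrix", function(object, mixture, ...) {
  .messageLength(object, mixture)
})

.messageLength <- function(x, mix) {
  alive <- mix@weights > 0
  knz <- sum(alive)
  if (knz < 1L) stop("mixture has no surviving component")
  n <- nrow(x)
  N <- nParamsPerComponent(ncol(x), mix@covStructure)
  ll <- .mixtureLogLik(x, mix)
  if (!is.finite(ll)) stop("non-finite mixture log-likelihood")
  (N / 2) * sum(log(n * mix@weights[alive] / 12)) +
    (knz / 2) * log(n / 12) + knz * (N + 1) / 2 - ll
}

.mixtureLogLik <- function(x, mix) {
  ld <- .componentLogDensities(x, mix)
  lw <- sweep(ld, 2L, log(mix@weights), "+")
  lw[, mix@weights <= 0] <- -Inf
  sum(.logRowSumExp(lw))
}

#' Refit a hard partition as a Gaussian mixture
#'
#' Bridges a hard partition to the message-length criterion: component m has
#' weight n_m / n and the Gaussian fit of its members. Singleton clusters
#' cannot support a fit and are first merged into the cluster with the
#' nearest centroid (with a message); the resolved labels are returned with
#' the mixture.
#'
#' @param x data matrix.
#' @param labels contiguous integer partition.
#' @param covStructure covariance structure (default: full for d <= 3,
#'   diagonal otherwise).
#' @param varFloorFrac per-dimension variance floor for the cluster fits as
#'   a fraction of the global variance (default 0.001), so that scoring is
#'   on the same footing as the EM fits and tiny clusters cannot degenerate
#'   into density spikes.
#' @return list with `mixture` ([MixtureModel-class]) and `labels` (after
#'   any singleton resolution).
#' @export
partitionToMixture <- function(x, labels, covStructure = NULL,
                               varFloorFrac = 0.001) {
  x <- .checkDataMatrix(x)
  if (is.null(covStructure)) covStructure <- .defaultCovStructure(ncol(x))
  varFloor <- varFloorFrac * apply(x, 2L, stats::var) * (nrow(x) - 1) / nrow(x)
  labels <- as.integer(labels)
  # a cluster must carry at least as many members as the support bar the
  # annihilating EM applies — or its parameter estimates are meaningless
  # and its density fit degenerates into a spike; under-supported clusters
  # are absorbed into the nearest
  minSize <- as.integer(ceiling(.supportBar(
    nParamsPerComponent(ncol(x), covStructure))))
  repeat {
    K <- max(labels)
    sizes <- tabulate(labels, K)
    if (all(sizes >= minSize) || K == 1L) break
    s <- which(sizes < minSize)[1L]
    cent <- t(vapply(seq_len(K),
                     function(c) colMeans(x[labels == c, , drop = FALSE]),
                     numeric(ncol(x))))
    d2 <- rowSums((cent - rep(cent[s, ], each = K))^2)
    d2[s] <- Inf
    tgt <- which.min(d2)
    message("partitionToMixture: merging under-supported cluster ", s,
            " (", sizes[s], " members) into nearest cluster ", tgt)
    labels[labels == s] <- tgt
    labels <- match(labels, sort(unique(labels)))
  }
  K <- max(labels)
  fits <- lapply(seq_len(K), function(c)
    fitClusterGaussian(x, which(labels == c), covStructure, varFloor))
  mix <- MixtureModel(
    weights = vapply(fits, `[[`, numeric(1), "weight"),
    means = vapply(fits, `[[`, numeric(ncol(x)), "mean"),
    covariances = lapply(fits, `[[`, "covariance"),
    covStructure = covStructure
  )
  list(mixture = mix, labels = labels)
}

#' Select the minimum-message-length candidate
#'
#' Returns the candidate with the smallest message length; ties go to the
#' smaller number of clusters, then to the earlier recording.
#'
#' @param cands non-empty list of candidates (each with `messageLength` and
#'   `knz`), as recorded by [runSmart1()]/[runSmart2()].
#' @return the winning candidate.
#' @export
selectBest <- function(cands) {
  if (length(cands) < 1L) stop("empty candidate list")
  Ls <- vapply(cands, function(cc) cc$messageLength, numeric(1))
  ks <- vapply(cands, function(cc) as.integer(cc$knz), integer(1))
  best <- order(Ls, ks, seq_along(cands))[1L]
  cands[[best]]
}
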