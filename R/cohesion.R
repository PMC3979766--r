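#' @include core.R
NULL

#' Fit a Gaussian to one cluster
#'
#' Mean = member centroid; covariance = member covariance (maximum-likelihood
#' denominator), constrained by the structure tag and ridge-regularized;
#' weight = cluster fraction of the dataset.
#'
#' @param x data matrix.
#' @param members integer indices of the cluster's rows (at least 2).
#' @param covStructure `"full"`, `"diagonal"` or `"spherical"`.
#' @param varFloor optional per-dimension variance floor (see
#'   [regularizeCovariance()]).
#' @return list with `weight`, `mean`, `covariance`.
#' @export
fitClusterGaussian <- function(x, members,
                               covStructure = c("full", "diagonal", "spherical"),
                               varFloor = NULL) {
  covStructure <- match.arg(covStructure)
  if (length(members) < 2L)
    stop("cannot fit a Gaussian to fewer than 2 members")
  xm <- x[members, , drop = FALSE]
  mu <- colMeans(xm)
  ctr <- xm - rep(mu, each = nrow(xm))
  S <- crossprod(ctr) / nrow(xm)
  S <- regularizeCovariance(.structureCovariance(S, covStructure), varFloor = varFloor)
  list(weight = length(members) / nrow(x), mean = mu, covariance = S)
}

#' Cohesion between two fitted clusters
#'
#' A density-based similarity: for each object x in the union of the two
#' clusters, the per-object similarity is the normalized minimum density
#' `s(x) = 2 min(p_i(x), p_j(x)) / (p_i(x) + p_j(x))` under the two fitted
#' Gaussians, and the cohesion is the mean of s over the union. It is
#' symmetric, lies in (0, 1], equals 1 when the two densities coincide, and
#' vanishes (to a 1e-300 floor) for well-separated clusters. Computed in log
#' space to survive underflow.
#'
#' @param ci,cj fitted cluster Gaussians (see [fitClusterGaussian()]).
#' @param membersI,membersJ row indices of the two clusters.
#' @param x data matrix.
#' @return cohesion value in (0, 1].
#' @export
cohesion <- function(ci, cj, membersI, membersJ, x) {
  u <- x[c(membersI, membersJ), , drop = FALSE]
  la <- gaussianLogPdf(u, ci$mean, ci$covariance)
  lb <- gaussianLogPdf(u, cj$mean, cj$covariance)
  # s = 2 min(a,b)/(a+b) = 2 / (1 + exp(|log a - log b|))
  s <- 2 / (1 + exp(pmin(abs(la - lb), 700)))
  s <- pmax(s, 1e-300)
  mean(s)
}

#' Max-vs-median cohesion merging pass
#'
#' Repeatedly computes all pairwise cluster cohesions and, while there are
#' at least 3 pairs and the maximum cohesion is at least `gamma` times the
#' median cohesion, considers merging the pair with the maximal cohesion.
#' The nominated merge is accepted only if it shortens the two-part message
#' length of the partition's Gaussian refit — the same criterion that
#' ultimately selects the clustering — so near-duplicate clusters collapse
#' while merely-touching ones stay apart; the pass stops at the first
#' rejected merge. With fewer than 3 pairs the median is not robust (for
#' one pair it equals the maximum) and no merge is attempted, which keeps
#' K = 2 partitions from always collapsing.
#'
#' Clusters with fewer than 2 members are given the pooled within-cluster
#' covariance for their density fit, since a single point determines no
#' spread of its own.
#'
#' @param labels contiguous integer partition.
#' @param x data matrix.
#' @param gamma merge threshold ratio (> 1; default 20).
#' @param covStructure covariance structure for the cluster fits (default:
#'   full for d <= 3, diagonal otherwise).
#' @return list with `labels` (possibly merged, contiguous) and `merges`
#'   (number of merges performed).
#' @export
mergePass <- function(labels, x, gamma = 20,
                      covStructure = NULL) {
  stopifnot(gamma > 1)
  if (is.null(covStructure)) covStructure <- .defaultCovStructure(ncol(x))
  labels <- as.integer(labels)
  merges <- 0L
  repeat {
    K <- max(labels)
    if (K < 2L || K * (K - 1L) / 2L < 3L) break
    fits <- .fitAllClusters(x, labels, covStructure)
    pairs <- utils::combn(K, 2L)
    coh <- apply(pairs, 2L, function(pr) {
      cohesion(fits[[pr[1L]]], fits[[pr[2L]]],
               which(labels == pr[1L]), which(labels == pr[2L]), x)
    })
    # between well-separated clusters every cohesion is round-off noise;
    # ratios of such values are meaningless
    if (max(coh) <= .Machine$double.eps) break
    if (max(coh) < gamma * stats::median(coh)) break
    pr <- pairs[, which.max(coh)]
    trial <- labels
    trial[trial == pr[2L]] <- pr[1L]
    trial <- match(trial, sort(unique(trial)))
    Lcur <- suppressMessages(
      .messageLength(x, partitionToMixture(x, labels, covStructure)$mixture))
    Ltrial <- suppressMessages(
      .messageLength(x, partitionToMixture(x, trial, covStructure)$mixture))
    if (Ltrial < Lcur) {
      labels <- trial
      merges <- merges + 1L
    } else break
  }
  list(labels = labels, merges = merges)
}

# fit a Gaussian to every cluster; singletons get the pooled covariance
.fitAllClusters <- function(x, labels, covStructure) {
  K <- max(labels)
  varFloor <- 0.001 * apply(x, 2L, stats::var) * (nrow(x) - 1) / nrow(x)
  sizes <- tabulate(labels, K)
  pooled <- NULL
  if (any(sizes < 2L)) {
    dev <- x
    for (c in seq_len(K)) {
      mem <- which(labels == c)
      dev[mem, ] <- x[mem, , drop = FALSE] -
        rep(colMeans(x[mem, , drop = FALSE]), each = length(mem))
    }
    pooled <- regularizeCovariance(
      .structureCovariance(crossprod(dev) / nrow(x), covStructure))
  }
  lapply(seq_len(K), function(c) {
    mem <- which(labels == c)
    if (length(mem) >= 2L) {
      fitClusterGaussian(x, mem, covStructure, varFloor)
    } else {
      list(weight = length(mem) / nrow(x),
           mean = colMeans(x[mem, , drop = FALSE]),
           covariance = pooled)
    }
  })
}
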