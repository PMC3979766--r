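#' @include core.R
NULL

.checkPartitions <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("partitions have different lengths (", length(truth), " vs ",
         length(pred), ")")
  list(truth = as.integer(factor(truth)), pred = as.integer(factor(pred)))
}

#' Pair-confusion counts of two partitions
#'
#' Counts the C(n, 2) object pairs that are co-clustered in both partitions
#' (`tp`), only in the prediction (`fp`), only in the truth (`fn`), or in
#' neither (`tn`), via the contingency table. Shared basis of the adjusted
#' Rand and Jaccard indices.
#'
#' @param truth,pred equal-length label vectors.
#' @return named list `tp`, `fp`, `fn`, `tn`.
#' @export
pairCounts <- function(truth, pred) {
  p <- .checkPartitions(truth, pred)
  tab <- table(p$truth, p$pred)
  tp <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  n <- length(p$truth)
  list(tp = tp, fp = sumB - tp, fn = sumA - tp,
       tn = choose(n, 2) - sumA - sumB + tp)
}

#' Adjusted Rand index
#'
#' Chance-adjusted pair agreement (Hubert-Arabie): 1 for identical
#' partitions up to relabeling, 0 in expectation for independent random
#' partitions, possibly negative.
#'
#' @param truth,pred equal-length label vectors.
#' @return ARI value.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1))   # 1
#' @export
adjustedRandIndex <- function(truth, pred) {
  p <- .checkPartitions(truth, pred)
  tab <- table(p$truth, p$pred)
  sumij <- sum(choose(tab, 2))
  sumA <- sum(choose(rowSums(tab), 2))
  sumB <- sum(choose(colSums(tab), 2))
  expected <- sumA * sumB / choose(length(p$truth), 2)
  denom <- (sumA + sumB) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in pairs
  (sumij - expected) / denom
}

#' Normalized mutual information
#'
#' `I(U; V) / sqrt(H(U) H(V))` with natural-log entropies, in [0, 1].
#' If either partition has zero entropy the value is 1 when the partitions
#' are identical (both single-cluster) and 0 otherwise.
#'
#' @param truth,pred equal-length label vectors.
#' @return NMI value.
#' @export
normalizedMutualInformation <- function(truth, pred) {
  p <- .checkPartitions(truth, pred)
  n <- length(p$truth)
  tab <- table(p$truth, p$pred) / n
  pu <- rowSums(tab); pv <- colSums(tab)
  hu <- -sum(pu * log(pu))
  hv <- -sum(pv * log(pv))
  if (hu == 0 || hv == 0)
    return(as.numeric(hu == 0 && hv == 0))
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pu, pv)[nz]))
  min(max(mi / sqrt(hu * hv), 0), 1)
}

#' Jaccard index over object pairs
#'
#' `tp / (tp + fp + fn)` from [pairCounts()]; when no pair is co-clustered
#' in either partition (all-singletons) the 0/0 case is defined as 1.
#'
#' @param truth,pred equal-length label vectors.
#' @return Jaccard value in [0, 1].
#' @export
jaccardIndex <- function(truth, pred) {
  pc <- pairCounts(truth, pred)
  denom <- pc$tp + pc$fp + pc$fn
  if (denom == 0) return(1)
  pc$tp / denom
}

#' Mean silhouette index
#'
#' Mean over objects of `(b - a) / max(a, b)` with `a` the mean
#' within-cluster distance and `b` the smallest mean distance to another
#' cluster (Euclidean); members of singleton clusters score 0. Requires at
#' least two clusters.
#'
#' @param x data matrix.
#' @param labels contiguous integer partition with K >= 2.
#' @return mean silhouette width.
#' @export
silhouetteIndex <- function(x, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(labels, stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Calinski-Harabasz index
#'
#' The variance-ratio criterion
#' `(traceB / (K - 1)) / (traceW / (n - K))`; perfectly collapsed clusters
#' (zero within-cluster scatter) give `Inf`.
#'
#' @param x data matrix.
#' @param labels contiguous integer partition with 2 <= K < n.
#' @return CH value.
#' @export
calinskiHarabasz <- function(x, labels) {
  labels <- as.integer(labels)
  K <- length(unique(labels))
  n <- nrow(x)
  if (K < 2L || n <= K)
    stop("Calinski-Harabasz requires 2 <= K < n")
  grand <- colMeans(x)
  W <- 0; B <- 0
  for (c in unique(labels)) {
    xc <- x[labels == c, , drop = FALSE]
    mu <- colMeans(xc)
    W <- W + sum((xc - rep(mu, each = nrow(xc)))^2)
    B <- B + nrow(xc) * sum((mu - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (K - 1)) / (W / (n - K))
}

#' Correct selection rate
#'
#' The fraction of replicate runs whose selected number of clusters equals
#' the generating truth, reported as a percentage.
#'
#' @param kHats integer vector of selected cluster counts, one per run.
#' @param kTrue the true number of clusters.
#' @return percentage in [0, 100].
#' @examples
#' correctSelectionRate(c(4, 4, 5, 3), 4)   # 50
#' @export
correctSelectionRate <- function(kHats, kTrue) {
  if (length(kHats) < 1L) stop("empty run list")
  100 * mean(kHats == kTrue)
}
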