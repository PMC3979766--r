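#' @include core.R
NULL

# ---------------------------------------------------------------------------
# One-prototype-take-one-cluster (OPTOC) competitive learning.
#
# Each prototype P carries two auxiliary vectors: the asymptotic property
# vector (APV) A, which defines a shrinking dynamic neighbourhood around P and
# whose distance to P signals convergence, and the distant property vector
# (DPV) D, which drifts towards patterns far from P and seeds new prototypes
# at splits. The state is a plain list; orchestration lives in runSmart1().
# ---------------------------------------------------------------------------

#' Initialize an OPTOC learner
#'
#' Places the first prototype at a uniformly chosen data row, its APV at the
#' data row farthest from it, and its DPV at the prototype; the dataset
#' radius (max distance from the centroid) is stored for the relative
#' convergence test.
#'
#' @param x numeric matrix (objects x features), n >= 2.
#' @return OPTOC state: list with elements `prototypes`, `apv`, `dpv`
#'   (each a list of length-d vectors), `apvCount`, `dpvCount`, `dataScale`.
#' @seealso [optocEpoch()], [optocConverged()], [optocSplit()]
#' @export
optocInit <- function(x) {
  x <- .checkDataMatrix(x)
  p <- x[sample.int(nrow(x), 1L), ]
  dist2 <- rowSums((x - rep(p, each = nrow(x)))^2)
  a <- x[which.max(dist2), ]
  centroid <- colMeans(x)
  dataScale <- sqrt(max(rowSums((x - rep(centroid, each = nrow(x)))^2)))
  if (dataScale <= 0) dataScale <- 1  # all rows identical; any scale works
  list(prototypes = list(p), apv = list(a), dpv = list(p),
       apvCount = 0L, dpvCount = 0L, dataScale = dataScale)
}

#' One online OPTOC learning epoch
#'
#' Presents every data row once, in a freshly randomized order. For input X
#' with winner prototype i (nearest by Euclidean distance): X is a neighbour
#' when `|X - P_i| <= |A_i - P_i|`; neighbours pull the APV towards them with
#' a 1/n running-average step; the winner prototype always moves towards X
#' with rate `(|A_i - P_i| / (|X - P_i| + |A_i - P_i|))^2`, so patterns
#' outside the dynamic neighbourhood contribute less; non-neighbours at
#' least as far as the current DPV drag the DPV outward.
#'
#' @param state OPTOC state from [optocInit()].
#' @param x data matrix.
#' @return updated state.
#' @export
optocEpoch <- function(state, x) {
  K <- length(state$prototypes)
  ord <- sample.int(nrow(x))
  # property-vector averages are windowed per epoch: restarting the
  # counters lets the APV track the current (shrinking) neighbourhood
  # instead of staying anchored to the first epoch's global average
  res <- .optocEpochCpp(x, ord,
                        do.call(rbind, state$prototypes),
                        do.call(rbind, state$apv),
                        do.call(rbind, state$dpv),
                        rep(0L, K),
                        rep(0L, K))
  state$prototypes <- lapply(seq_len(K), function(k) res$P[k, ])
  state$apv <- lapply(seq_len(K), function(k) res$A[k, ])
  state$dpv <- lapply(seq_len(K), function(k) res$D[k, ])
  state$apvCount <- res$nA
  state$dpvCount <- res$nD
  # a wide-open neighbourhood that nevertheless contains no pattern stalls
  # the learner (a prototype parked in an empty region between clusters);
  # re-anchor such an APV at the nearest pattern so the neighbourhood always
  # holds at least one. Neighbourhoods already at the convergence scale are
  # left alone.
  gaps <- vapply(seq_len(K), function(k)
    sqrt(sum((state$apv[[k]] - state$prototypes[[k]])^2)), numeric(1))
  dead <- which(res$nA == 0L & gaps > 0.005 * state$dataScale)
  if (length(dead)) {
    d2 <- .crossDist2(x, res$P[dead, , drop = FALSE])
    for (i in seq_along(dead))
      state$apv[[dead[i]]] <- x[which.min(d2[, i]), ]
  }
  state
}

#' OPTOC convergence test
#'
#' A prototype has converged when its APV has collapsed onto it relative to
#' the dataset radius: `|A_i - P_i| / dataScale <= eps` for every i. The
#' threshold is a relative, data-independent number; the default used
#' throughout is 0.005.
#'
#' @param state OPTOC state.
#' @param eps relative threshold in (0, 1).
#' @return `TRUE` when every prototype passes the test.
#' @export
optocConverged <- function(state, eps = 0.005) {
  stopifnot(eps > 0, eps < 1)
  gaps <- mapply(function(a, p) sqrt(sum((a - p)^2)),
                 state$apv, state$prototypes)
  all(gaps / state$dataScale <= eps)
}

#' Hard nearest-prototype assignment
#'
#' Labels each row by its nearest prototype (Euclidean; ties go to the lower
#' prototype index) and re-compacts labels to contiguous 1..K, dropping
#' prototypes that own no points.
#'
#' @param x data matrix.
#' @param state OPTOC state (or a list with element `prototypes`).
#' @return integer label vector with attribute `"kept"` giving the indices
#'   of the prototypes that own at least one point.
#' @export
assignNearest <- function(x, state) {
  P <- do.call(rbind, state$prototypes)
  d2 <- .crossDist2(x, P)
  raw <- max.col(-d2, ties.method = "first")
  kept <- sort(unique(raw))
  labels <- match(raw, kept)
  attr(labels, "kept") <- kept
  labels
}

# squared Euclidean distances between rows of x (n x d) and rows of p (K x d)
.crossDist2 <- function(x, p) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(p))) +
    outer(rep(1, nrow(x)), rowSums(p^2)) - 2 * tcrossprod(x, p)
  d2[d2 < 0] <- 0
  d2
}

#' Split the cluster with the largest variance
#'
#' Identifies the cluster maximizing the mean squared member-to-prototype
#' distance (clusters with fewer than 2 members are ineligible) and appends
#' one new prototype seeded at that cluster's DPV (or, if the DPV never
#' learned, at the member farthest from the prototype). All prototypes keep
#' their positions but their APVs are reset to the farthest member of their
#' own cluster and both counters restart at zero, so the next learning phase
#' re-learns from scratch.
#'
#' @param state OPTOC state.
#' @param x data matrix.
#' @param labels current nearest-prototype assignment (see [assignNearest()];
#'   label c must correspond to `state$prototypes[[c]]`).
#' @return updated state with one more prototype.
#' @export
optocSplit <- function(state, x, labels) {
  K <- length(state$prototypes)
  msd <- rep(-Inf, K)
  for (c in seq_len(K)) {
    mem <- which(labels == c)
    if (length(mem) >= 2L)
      msd[c] <- mean(rowSums((x[mem, , drop = FALSE] -
                                rep(state$prototypes[[c]], each = length(mem)))^2))
  }
  if (all(!is.finite(msd))) stop("nothing to split: no cluster has 2 or more members")
  cstar <- which.max(msd)
  mem <- which(labels == cstar)
  xm <- x[mem, , drop = FALSE]
  if (state$dpvCount[cstar] > 0L) {
    newP <- state$dpv[[cstar]]
  } else {
    far <- which.max(rowSums((xm - rep(state$prototypes[[cstar]], each = nrow(xm)))^2))
    newP <- xm[far, ]
  }
  newA <- xm[which.max(rowSums((xm - rep(newP, each = nrow(xm)))^2)), ]

  # reset every existing unit for re-learning: APV -> farthest own member
  for (c in seq_len(K)) {
    mem_c <- which(labels == c)
    if (length(mem_c) > 0L) {
      xc <- x[mem_c, , drop = FALSE]
      far <- which.max(rowSums((xc - rep(state$prototypes[[c]], each = nrow(xc)))^2))
      state$apv[[c]] <- xc[far, ]
    }
    state$dpv[[c]] <- state$prototypes[[c]]
  }
  state$prototypes <- c(state$prototypes, list(newP))
  state$apv <- c(state$apv, list(newA))
  state$dpv <- c(state$dpv, list(newP))
  state$apvCount <- c(rep(0L, K), 0L)
  state$dpvCount <- c(rep(0L, K), 0L)
  state
}

# drop prototypes (by index) from a state, e.g. those owning no points
.subsetState <- function(state, keep) {
  state$prototypes <- state$prototypes[keep]
  state$apv <- state$apv[keep]
  state$dpv <- state$dpv[keep]
  state$apvCount <- state$apvCount[keep]
  state$dpvCount <- state$dpvCount[keep]
  state
}
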