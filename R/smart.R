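#' @include optoc.R cohesion.R cem2.R mml.R
NULL

#' Configuration for the splitting-while-merging loop
#'
#' Validates and assembles the run configuration. The two loop-level
#' parameters, the cohesion merge ratio `gamma` and the merge budget `mMax`,
#' are neutral: they are not tied to any particular dataset, and the
#' selected number of clusters is insensitive to `mMax` over a wide range.
#'
#' @param eps OPTOC relative convergence threshold, in (0, 1); default 0.005.
#' @param gamma cohesion max-vs-median merge ratio (> 1); default 20.
#' @param mMax maximum cumulative number of merges before the loop stops
#'   (>= 1); default 5.
#' @param covStructure `"full"`, `"diagonal"`, `"spherical"`, or `NULL` to
#'   pick full for d <= 3 and diagonal otherwise.
#' @param tol relative message-length tolerance for component-wise EM;
#'   default 1e-5.
#' @param maxSweeps maximum EM sweeps per learning phase; default 500.
#' @param maxEpochs maximum OPTOC epochs per learning phase; default 500.
#' @param varFloorFrac per-dimension variance floor for the mixture M-steps,
#'   as a fraction of the global per-dimension variance (default 0.001);
#'   guards against components degenerating onto a handful of points.
#' @param graceSweeps number of EM sweeps a freshly injected component is
#'   exempt from annihilation (default 5), long enough to recentre on and
#'   expand over the structure near its seed; splits that fail to shorten
#'   the message length are undone afterwards regardless. Larger values
#'   (around 20) let a far-seeded newcomer migrate across heavily
#'   overlapping, anisotropic mixtures at some risk of retaining
#'   sample-level sub-structure in well-separated clusters.
#' @param seed optional integer seed applied at the start of a run.
#' @param verbose 0 (quiet), 1 (phase progress) or 2 (adds the split/merge
#'   trajectory).
#' @return validated configuration list.
#' @export
smartConfig <- function(eps = 0.005, gamma = 20, mMax = 5L,
                        covStructure = NULL, tol = 1e-5,
                        maxSweeps = 500L, maxEpochs = 500L,
                        varFloorFrac = 0.001, graceSweeps = 5L,
                        seed = NULL, verbose = 0L) {
  stopifnot(eps > 0, eps < 1, gamma > 1, mMax >= 1,
            tol >= 0, maxSweeps >= 1, maxEpochs >= 1, varFloorFrac >= 0)
  if (!is.null(covStructure))
    covStructure <- match.arg(covStructure, c("full", "diagonal", "spherical"))
  list(eps = eps, gamma = gamma, mMax = as.integer(mMax),
       covStructure = covStructure, tol = tol,
       maxSweeps = as.integer(maxSweeps), maxEpochs = as.integer(maxEpochs),
       varFloorFrac = varFloorFrac, graceSweeps = as.integer(graceSweeps),
       seed = seed, verbose = as.integer(verbose))
}

.say <- function(cfg, level, ...) {
  if (cfg$verbose >= level) message("[smart] ", ...)
}

.makeCandidate <- function(x, labels, covStructure) {
  pm <- partitionToMixture(x, labels, covStructure)
  list(labels = pm$labels, mixture = pm$mixture,
       knz = max(pm$labels),
       messageLength = .messageLength(x, pm$mixture))
}

.smartResult <- function(x, cands, traj, method, cfg) {
  best <- selectBest(cands)
  new("SmartResult",
      labels = as.integer(best$labels),
      mixture = best$mixture,
      messageLength = best$messageLength,
      candidates = cands,
      trajectory = traj,
      method = method,
      config = cfg)
}

#' SMART I: competitive-learning splitting-while-merging
#'
#' Starts from a single OPTOC prototype and loops: learn (online epochs
#' until the APV-based relative convergence test passes), assign each object
#' to its nearest prototype, run the max-vs-median cohesion merging pass,
#' record the partition (with its Gaussian refit and message length) as a
#' candidate, then split the cluster with the largest variance — until the
#' cumulative number of merges reaches `mMax` or nothing is splittable. The
#' candidate with the minimum message length is returned.
#'
#' @param x numeric matrix (objects x features, n >= 4) or data.frame.
#' @param config configuration from [smartConfig()].
#' @param ... used to override individual [smartConfig()] fields.
#' @return a [SmartResult-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
#' res <- runSmart1(x, smartConfig(seed = 1))
#' numClusters(res)
#' @export
runSmart1 <- function(x, config = smartConfig(), ...) {
  cfg <- utils::modifyList(config, list(...))
  x <- .checkDataMatrix(x)
  if (nrow(x) < 4L) stop("need at least 4 objects")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  covStructure <- if (is.null(cfg$covStructure))
    .defaultCovStructure(ncol(x)) else cfg$covStructure

  state <- optocInit(x)
  cands <- list()
  traj <- data.frame()
  mergesTotal <- 0L
  oneAfterCollapse <- FALSE
  iter <- 0L
  bestL <- Inf
  sinceImprove <- 0L
  repeat {
    iter <- iter + 1L
    # Task 2: learn until every prototype's APV collapses onto it
    epochs <- 0L
    while (!optocConverged(state, cfg$eps) && epochs < cfg$maxEpochs) {
      state <- optocEpoch(state, x)
      epochs <- epochs + 1L
    }
    if (!optocConverged(state, cfg$eps))
      warning("OPTOC learning stopped at the epoch cap (", cfg$maxEpochs,
              ") without meeting the convergence threshold")
    labels <- assignNearest(x, state)
    state <- .subsetState(state, attr(labels, "kept"))
    attr(labels, "kept") <- NULL

    # Task 3: cohesion merging
    mp <- mergePass(labels, x, cfg$gamma, covStructure)
    if (mp$merges > 0L) {
      # rebuild the prototype set: untouched clusters keep their learned
      # prototype, merged clusters are represented by the union centroid
      K <- max(mp$labels)
      newState <- state
      newState <- .subsetState(newState, seq_len(K))
      for (c in seq_len(K)) {
        mem <- which(mp$labels == c)
        src <- unique(labels[mem])
        if (length(src) == 1L && all(which(labels == src) %in% mem)) {
          newState$prototypes[[c]] <- state$prototypes[[src]]
          newState$apv[[c]] <- state$apv[[src]]
          newState$dpv[[c]] <- state$dpv[[src]]
          newState$apvCount[c] <- state$apvCount[src]
          newState$dpvCount[c] <- state$dpvCount[src]
        } else {
          cent <- colMeans(x[mem, , drop = FALSE])
          newState$prototypes[[c]] <- cent
          newState$apv[[c]] <- cent
          newState$dpv[[c]] <- cent
          newState$apvCount[c] <- 0L
          newState$dpvCount[c] <- 0L
        }
      }
      state <- newState
      mergesTotal <- mergesTotal + mp$merges
    }
    labels <- mp$labels

    cands[[length(cands) + 1L]] <- .makeCandidate(x, labels, covStructure)
    kNow <- max(cands[[length(cands)]]$labels)
    traj <- rbind(traj, data.frame(iteration = iter, k = kNow,
                                   messageLength = cands[[length(cands)]]$messageLength,
                                   merges = mergesTotal))
    .say(cfg, 2L, "iteration ", iter, ": k = ", kNow,
         ", merges so far = ", mergesTotal)

    if (mergesTotal >= cfg$mMax) break
    # stagnation stop: the merge budget bounds unproductive merging; the
    # same tolerance is applied to unproductive splitting — when 2*mMax
    # successive iterations fail to improve the best message length the
    # search has exhausted its budget
    L <- cands[[length(cands)]]$messageLength
    if (L < bestL - 1e-9) { bestL <- L; sinceImprove <- 0L } else {
      sinceImprove <- sinceImprove + 1L
      if (sinceImprove >= 2L * cfg$mMax) break
    }
    if (iter >= cfg$mMax + 40L) {   # safety cap against non-termination
      warning("splitting-while-merging loop stopped at the iteration cap")
      break
    }
    if (kNow == 1L) {
      # oscillation guard: one more split after a collapse to a single
      # cluster; a second collapse terminates
      if (oneAfterCollapse) break
      oneAfterCollapse <- TRUE
    }
    splitState <- tryCatch(optocSplit(state, x, labels), error = function(e) NULL)
    if (is.null(splitState)) break  # nothing splittable: stop early
    state <- splitState
  }
  .smartResult(x, cands, traj, "smart1", cfg)
}

#' SMART II: finite-mixture splitting-while-merging
#'
#' Records the single-Gaussian (k = 1) fit as the first candidate, then
#' starts a two-component mixture at two distinct random data rows with the
#' global covariance, and loops: run modified component-wise EM (learning
#' and merging — each weight annihilation is a merge), record the surviving
#' mixture and its hard partition as a candidate, and, while the cumulative
#' merge count is below `mMax`, inject a deterministic new component at the
#' data row farthest from all surviving means. The candidate with the
#' minimum message length wins.
#'
#' @inheritParams runSmart1
#' @return a [SmartResult-class].
#' @examples
#' sim <- simulateQPSK(n = 256, snrDb = 15, seed = 7)
#' res <- runSmart2(sim$x, smartConfig(seed = 7))
#' numClusters(res)
#' @export
runSmart2 <- function(x, config = smartConfig(), ...) {
  cfg <- utils::modifyList(config, list(...))
  x <- .checkDataMatrix(x)
  if (nrow(x) < 4L) stop("need at least 4 objects")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  covStructure <- if (is.null(cfg$covStructure))
    .defaultCovStructure(ncol(x)) else cfg$covStructure
  n <- nrow(x); d <- ncol(x)

  cands <- list(.makeCandidate(x, rep(1L, n), covStructure))
  traj <- data.frame(iteration = 0L, k = 1L,
                     messageLength = cands[[1L]]$messageLength, merges = 0L)

  # k = 2 start: two distinct random rows, global covariance, equal weights
  idx <- sample.int(n, 2L)
  globalCov <- regularizeCovariance(
    .structureCovariance(stats::cov(x) * (n - 1) / n, covStructure))
  mix <- MixtureModel(c(0.5, 0.5), t(x[idx, , drop = FALSE]),
                      list(globalCov, globalCov), covStructure)

  # degeneracy guard for the EM fits: per-dimension variance floor at a
  # small fraction of the global variance
  varFloor <- cfg$varFloorFrac * apply(x, 2L, stats::var) * (n - 1) / n

  mergesTotal <- 0L
  iter <- 0L
  failedSites <- integer(0)
  lastSite <- NA_integer_
  kPrev <- 2L
  repeat {
    iter <- iter + 1L
    res <- tryCatch(cem2(x, mix, cfg$tol, cfg$maxSweeps,
                         protect = if (iter > 1L) length(mix@weights) else integer(0),
                         protectSweeps = cfg$graceSweeps,
                         varFloor = varFloor),
                    error = function(e) {
                      if (conditionMessage(e) == "all components annihilated") NULL
                      else stop(e)
                    })
    if (is.null(res)) {
      .say(cfg, 1L, "all components annihilated; falling back to recorded candidates")
      break
    }
    mergesTotal <- mergesTotal + res$merges
    cand <- .hardCandidate(x, res$mixture, res$responsibilities)
    cands[[length(cands) + 1L]] <- cand
    traj <- rbind(traj, data.frame(iteration = iter, k = cand$knz,
                                   messageLength = cand$messageLength,
                                   merges = mergesTotal))
    .say(cfg, 2L, "iteration ", iter, ": k = ", cand$knz,
         ", merges so far = ", mergesTotal)

    # splitting-while-merging acceptance: a split that fails to shorten the
    # description is undone — the surviving newcomer re-merges (one merge),
    # the working state reverts, and its seed site is barred
    accepted <- TRUE
    if (iter > 1L && cand$messageLength >= prevCand$messageLength) {
      accepted <- FALSE
      if (res$merges == 0L) mergesTotal <- mergesTotal + 1L
      res <- prevRes
      cand <- prevCand
      .say(cfg, 2L, "split rejected (message length did not improve); ",
           "merges so far = ", mergesTotal)
    }
    prevRes <- res
    prevCand <- cand

    if (mergesTotal >= cfg$mMax) break
    if (iter >= cfg$mMax + 40L) {   # safety cap against non-termination
      warning("splitting-while-merging loop stopped at the iteration cap")
      break
    }
    # a failed injection marks its seed site so the next attempt probes a
    # different region of the data
    if (!is.na(lastSite) && (!accepted || cand$knz <= kPrev)) {
      failedSites <- c(failedSites, lastSite)
    } else {
      failedSites <- integer(0)
    }
    kPrev <- cand$knz
    mix <- splitInject(x, res$mixture, exclude = failedSites)
    lastSite <- attr(mix, "site")
  }
  .smartResult(x, cands, traj, "smart2", cfg)
}

# hard-assign by maximum responsibility. Components whose hard occupancy
# falls below the N/2 support bar (the same bar the annihilating weight
# update applies to soft support) cannot stand as clusters: they are pruned
# from the mixture, their weight redistributed, and their points reassigned,
# so the candidate's cluster count equals its label count and no component
# is scored on a handful of points.
.hardCandidate <- function(x, mix, w) {
  minSize <- as.integer(ceiling(.supportBar(
    nParamsPerComponent(ncol(x), mix@covStructure))))
  repeat {
    raw <- max.col(w, ties.method = "first")
    occ <- tabulate(raw, ncol(w))
    kept <- which(occ >= minSize)
    if (length(kept) == 0L) kept <- which.max(occ)
    if (length(kept) == ncol(w)) break
    wts <- mix@weights[kept]
    mix <- MixtureModel(wts / sum(wts),
                        mix@means[, kept, drop = FALSE],
                        mix@covariances[kept],
                        mix@covStructure)
    w <- w[, kept, drop = FALSE]
    w <- w / rowSums(w)
    if (length(kept) == 1L) break
  }
  raw <- max.col(w, ties.method = "first")
  kept <- sort(unique(raw))
  labels <- match(raw, kept)
  if (length(kept) < ncol(w)) {
    wts <- mix@weights[kept]
    mix <- MixtureModel(wts / sum(wts),
                        mix@means[, kept, drop = FALSE],
                        mix@covariances[kept],
                        mix@covStructure)
  }
  list(labels = as.integer(labels), mixture = mix,
       knz = length(kept), messageLength = .messageLength(x, mix))
}
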