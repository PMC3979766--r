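#' @include core.R mml.R
NULL

# ---------------------------------------------------------------------------
# Modified component-wise EM (CEM2) for finite Gaussian mixtures: components
# are updated one at a time, and a Dirichlet-type prior on the mixing weights
# turns the weight M-step into max(0, sum(w) - N/2) / (...), which annihilates
# components whose expected support falls below half their parameter count.
# Annihilations are the merge events of the splitting-while-merging loop.
# ---------------------------------------------------------------------------

#' E-step: conditional membership probabilities
#'
#' `w[i, m] = alpha_m p(y_i | theta_m) / sum_j alpha_j p(y_i | theta_j)`,
#' computed in log space; rows sum to 1 and annihilated components get zero
#' columns. If every surviving density underflows for some row, that row is
#' assigned uniformly over the survivors with a warning.
#'
#' @param x data matrix.
#' @param mixture a [MixtureModel-class] with at least one surviving
#'   component.
#' @return n x k responsibility matrix.
#' @export
eStep <- function(x, mixture) {
  alive <- mixture@weights > 0
  if (!any(alive)) stop("mixture has no surviving component")
  lw <- sweep(.componentLogDensities(x, mixture), 2L,
              log(mixture@weights), "+")
  lw[, !alive] <- -Inf
  mx <- apply(lw, 1L, max)
  bad <- !is.finite(mx)
  if (any(bad)) {
    warning("density underflow for ", sum(bad),
            " row(s); assigning them uniformly over surviving components")
    lw[bad, alive] <- 0
    mx[bad] <- 0
  }
  w <- exp(lw - mx)
  w / rowSums(w)
}

#' Annihilating mixing-weight update
#'
#' The Dirichlet-prior M-step for the mixing weights:
#' `alpha_m = max(0, S_m - B) / sum_j max(0, S_j - B)` with `S_m` the
#' expected support (column sum of the responsibilities) and
#' `B = max(N/2, 12)`. A component whose expected support falls below the
#' bar is annihilated (weight exactly 0): below half its parameter count the
#' estimates could not be accurate with so few effective samples, and below
#' 12 — the quantization constant of the message-length criterion — the
#' per-component code length turns negative, so retaining such components
#' would let the criterion reward arbitrarily small ones.
#'
#' @param w responsibility matrix from [eStep()].
#' @param nParams `N`, the per-component parameter count
#'   (see [nParamsPerComponent()]).
#' @return weight vector summing to 1, with zeros for annihilated components.
#' @export
updateMixingWeights <- function(w, nParams) {
  .annihilatingUpdate(w, nParams, integer(0))
}

# Dirichlet-prior weight update with an optional component exempt from the
# support subtraction (the grace period of a freshly injected component)
.annihilatingUpdate <- function(w, nParams, protect) {
  s <- colSums(w)
  num <- pmax(0, s - .supportBar(nParams))
  if (length(protect)) num[protect] <- pmax(s[protect], 1e-12)
  if (sum(num) <= 0)
    stop("all components annihilated")
  num / sum(num)
}

# minimum expected support a component must retain: below N/2 its parameter
# estimates are not identifiable; below 12 (the quantization constant of the
# message-length criterion) the per-component code length turns negative, so
# the criterion would reward arbitrarily small components
.supportBar <- function(nParams) max(nParams / 2, 12)

#' M-step for one component
#'
#' Responsibility-weighted mean and covariance (about the weighted mean),
#' constrained by the structure tag and ridge-regularized.
#'
#' @param x data matrix.
#' @param w responsibility column for the component (length n, effective
#'   weight at least 2).
#' @param covStructure covariance-structure tag.
#' @param varFloor optional per-dimension variance floor (see
#'   [regularizeCovariance()]).
#' @return list with `mean` and `covariance`.
#' @export
mStepComponent <- function(x, w, covStructure = c("full", "diagonal", "spherical"),
                           varFloor = NULL) {
  covStructure <- match.arg(covStructure)
  sw <- sum(w)
  if (sw < 2)
    stop("insufficient support for component M-step (effective weight < 2)")
  mu <- colSums(x * w) / sw
  ctr <- x - rep(mu, each = nrow(x))
  S <- crossprod(ctr * sqrt(w)) / sw
  list(mean = mu,
       covariance = regularizeCovariance(.structureCovariance(S, covStructure),
                                         varFloor = varFloor))
}

#' Run modified component-wise EM
#'
#' Sweeps over the surviving components; on component m's turn the
#' responsibilities are recomputed, the annihilating weight update is
#' applied, and (if m survives) its mean and covariance are refit. Sweeps
#' stop when the relative change in message length falls below `tol` or
#' after `maxSweeps`. Each annihilated component counts as one merge.
#'
#' @param x data matrix.
#' @param mixture starting [MixtureModel-class].
#' @param tol relative message-length convergence tolerance (default 1e-5).
#' @param maxSweeps maximum number of sweeps (default 500).
#' @param protect optional index of a component exempt from annihilation
#'   during the first convergence phase (the grace period given to a freshly
#'   injected component, see [splitInject()]; a far-seeded newcomer needs
#'   many sweeps to migrate to the structure it should capture, and the
#'   support-subtracting weight prior would otherwise extinguish it in
#'   transit). Once the protected run converges the exemption is dropped and
#'   the sweeps continue to a second convergence; deaths in either phase
#'   count as merges.
#' @param protectTol relative tolerance ending the protected phase (default
#'   1e-7); tighter than `tol` because the migration of a far-seeded
#'   component crosses long, nearly flat stretches of the objective.
#' @param protectSweeps maximum number of sweeps the exemption lasts
#'   (default `Inf`, i.e. until the protected phase converges). The
#'   splitting-while-merging driver uses a single exempt sweep, just long
#'   enough for a far-seeded newcomer to recentre on its responsibility
#'   basin before the weight prior judges it.
#' @param varFloor optional per-dimension variance floor applied in every
#'   M-step; prevents components from degenerating into density spikes on a
#'   few points.
#' @return list with `mixture` (survivors only), `trace` (data.frame of
#'   sweep, message length, surviving component count, annihilations in the
#'   sweep), `merges` (total annihilation events) and `responsibilities`
#'   (n x k_nz matrix for the surviving components).
#' @export
cem2 <- function(x, mixture, tol = 1e-5, maxSweeps = 500L, protect = integer(0),
                 protectTol = 1e-7, protectSweeps = Inf, varFloor = NULL) {
  x <- .checkDataMatrix(x)
  mix <- mixture
  N <- nParamsPerComponent(ncol(x), mix@covStructure)
  merges <- 0L
  Lprev <- .messageLength(x, mix)
  trace <- data.frame(sweep = 0L, messageLength = Lprev,
                      knz = sum(mix@weights > 0), annihilations = 0L)
  for (sw in seq_len(maxSweeps)) {
    annThisSweep <- 0L
    for (m in seq_along(mix@weights)) {
      if (mix@weights[m] <= 0) next
      w <- eStep(x, mix)
      alphaNew <- .annihilatingUpdate(w, N, protect)
      died <- which(alphaNew <= 0 & mix@weights > 0)
      if (length(died)) {
        annThisSweep <- annThisSweep + length(died)
        merges <- merges + length(died)
      }
      mix@weights <- alphaNew
      if (mix@weights[m] > 0) {
        sm <- sum(w[, m])
        if (m %in% protect && sm < 2) {
          # too weak to refit the covariance; keep the mean drifting so the
          # protected newcomer can still migrate towards unexplained structure
          if (sm > 0) mix@means[, m] <- colSums(x * w[, m]) / sm
          next
        }
        fit <- mStepComponent(x, w[, m], mix@covStructure, varFloor)
        mix@means[, m] <- fit$mean
        mix@covariances[[m]] <- fit$covariance
      }
    }
    L <- .messageLength(x, mix)
    trace <- rbind(trace, data.frame(sweep = sw, messageLength = L,
                                     knz = sum(mix@weights > 0),
                                     annihilations = annThisSweep))
    if (length(protect) && sw >= protectSweeps) protect <- integer(0)
    thr <- if (length(protect)) protectTol else tol
    if (abs(L - Lprev) < thr * abs(Lprev)) {
      if (length(protect)) { protect <- integer(0); Lprev <- L; next }
      Lprev <- L
      break
    }
    Lprev <- L
  }
  alive <- which(mix@weights > 0)
  out <- MixtureModel(mix@weights[alive],
                      mix@means[, alive, drop = FALSE],
                      mix@covariances[alive],
                      mix@covStructure)
  list(mixture = out, trace = trace, merges = merges,
       responsibilities = eStep(x, out))
}

#' Deterministic split: inject one component
#'
#' The new component's mean is the data row farthest (Euclidean) from its
#' closest surviving component mean; its covariance is the element-wise
#' average of the surviving covariances; the newcomer takes weight
#' `1/(k+1)` and the survivors are rescaled by `1 - 1/(k+1)`. If the chosen
#' row coincides with an existing mean it is nudged by 1e-6 of the dataset
#' radius.
#'
#' @param x data matrix.
#' @param mixture current [MixtureModel-class] (survivors only).
#' @param exclude optional row indices barred from seeding (sites whose
#'   neighbourhood already failed to support a component; the
#'   splitting-while-merging driver probes elsewhere on the next attempt).
#'   Rows within squared Mahalanobis distance d (under the averaged
#'   covariance) of an excluded site are skipped; if that empties the pool
#'   the exclusion is ignored.
#' @return mixture with one additional component.
#' @export
splitInject <- function(x, mixture, exclude = integer(0)) {
  alive <- mixture@weights > 0
  mu <- mixture@means[, alive, drop = FALSE]
  k <- ncol(mu)
  d2 <- .crossDist2(x, t(mu))
  minD <- apply(d2, 1L, min)
  covsA <- mixture@covariances[alive]
  avgCovA <- Reduce(`+`, covsA) / length(covsA)
  keep <- rep(TRUE, nrow(x))
  if (length(exclude)) {
    # exclusion ball: squared Mahalanobis distance below d, the expected
    # squared distance of a point from its own component's centre
    Si <- solve(avgCovA)
    for (e in exclude) {
      ctr <- sweep(x, 2L, x[e, ])
      keep[rowSums((ctr %*% Si) * ctr) < nrow(avgCovA)] <- FALSE
    }
    if (!any(keep)) keep <- rep(TRUE, nrow(x))
  }
  pick <- which(keep)[which.max(minD[keep])]
  newMean <- x[pick, ]
  if (min(colSums((mu - newMean)^2)) < 1e-24) {
    centroid <- colMeans(x)
    scale <- sqrt(max(rowSums((x - rep(centroid, each = nrow(x)))^2)))
    message("splitInject: new mean coincides with an existing one; perturbing")
    newMean <- newMean + 1e-6 * max(scale, 1)
  }
  wNew <- 1 / (k + 1)
  out <- MixtureModel(
    weights = c(mixture@weights[alive] * (1 - wNew), wNew),
    means = cbind(mu, newMean),
    covariances = c(covsA, list(avgCovA)),
    covStructure = mixture@covStructure
  )
  attr(out, "site") <- pick
  out
}
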