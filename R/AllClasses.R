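#' MixtureModel: a finite Gaussian mixture
#'
#' Container for a k-component multivariate Gaussian mixture: mixing
#' weights, component means, component covariance matrices, and the
#' covariance-structure tag that constrains the fits.
#'
#' @slot weights numeric vector of mixing probabilities (length k, sums to 1;
#'   annihilated components keep their slot with weight 0).
#' @slot means d x k numeric matrix; column m is the mean of component m.
#' @slot covariances list of k d x d symmetric positive-definite matrices.
#' @slot covStructure one of `"full"`, `"diagonal"`, `"spherical"`.
#'
#' @seealso [partitionToMixture()], [cem2()], [messageLength()]
#' @exportClass MixtureModel
setClass("MixtureModel",
  representation(
    weights      = "numeric",
    means        = "matrix",
    covariances  = "list",
    covStructure = "character"
  )
)

setValidity("MixtureModel", function(object) {
  k <- length(object@weights)
  msg <- character()
  if (k < 1L) msg <- c(msg, "mixture needs at least one component")
  if (ncol(object@means) != k) msg <- c(msg, "means must have one column per component")
  if (length(object@covariances) != k) msg <- c(msg, "one covariance per component required")
  if (any(object@weights < -1e-12) || abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (!object@covStructure %in% c("full", "diagonal", "spherical"))
    msg <- c(msg, "covStructure must be full, diagonal or spherical")
  d <- nrow(object@means)
  ok <- vapply(object@covariances, function(S) is.matrix(S) && all(dim(S) == d), logical(1))
  if (!all(ok)) msg <- c(msg, "covariances must be d x d matrices")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureModel
#'
#' @param weights mixing probabilities (length k).
#' @param means d x k matrix of component means (or a length-d vector for k = 1).
#' @param covariances list of k covariance matrices.
#' @param covStructure covariance-structure tag.
#' @return A [MixtureModel-class] object.
#' @examples
#' MixtureModel(1, matrix(0, 2, 1), list(diag(2)), "full")
#' @export
MixtureModel <- function(weights, means, covariances,
                         covStructure = c("full", "diagonal", "spherical")) {
  covStructure <- match.arg(covStructure)
  if (!is.matrix(means)) means <- matrix(means, ncol = length(weights))
  new("MixtureModel", weights = as.numeric(weights), means = means,
      covariances = covariances, covStructure = covStructure)
}

#' SmartResult: the outcome of a splitting-while-merging run
#'
#' Holds the selected clustering (labels, refitted mixture, message length),
#' every candidate recorded during the split/merge loop, and the loop
#' trajectory.
#'
#' Each candidate is a list with elements `labels` (contiguous integer
#' partition), `mixture` ([MixtureModel-class]), `knz` (number of clusters)
#' and `messageLength` (nats).
#'
#' @slot labels integer vector; selected hard partition (contiguous 1..K).
#' @slot mixture [MixtureModel-class] of the selected candidate.
#' @slot messageLength message length of the selected candidate, in nats.
#' @slot candidates list of recorded candidates, in recording order.
#' @slot trajectory data.frame logging the loop (iteration, k, message
#'   length, cumulative merges).
#' @slot method `"smart1"` or `"smart2"`.
#' @slot config the configuration list used (see [smartConfig()]).
#'
#' @exportClass SmartResult
setClass("SmartResult",
  representation(
    labels        = "integer",
    mixture       = "MixtureModel",
    messageLength = "numeric",
    candidates    = "list",
    trajectory    = "data.frame",
    method        = "character",
    config        = "list"
  )
)

setValidity("SmartResult", function(object) {
  msg <- character()
  K <- max(object@labels)
  if (!all(sort(unique(object@labels)) == seq_len(K)))
    msg <- c(msg, "labels must be contiguous 1..K")
  if (!is.finite(object@messageLength))
    msg <- c(msg, "message length must be finite")
  if (length(object@candidates) < 1L)
    msg <- c(msg, "at least one candidate must be recorded")
  if (length(msg)) msg else TRUE
})
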