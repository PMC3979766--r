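#' @include AllClasses.R
NULL

#' Two-part minimum-message-length score
#'
#' For a data matrix and a fitted mixture, computes the two-part code length
#' (nats): a parameter part charging each surviving component
#' `(N/2) log(n alpha_m / 12)` plus `(k_nz/2) log(n/12) + k_nz (N+1)/2`,
#' and a data part equal to minus the mixture log-likelihood. Components
#' with zero weight are excluded. For a [SmartResult-class], returns the
#' message length of the selected candidate.
#'
#' @param object numeric matrix (objects x features) or a
#'   [SmartResult-class].
#' @param ... further arguments; for the matrix method, `mixture` (a
#'   [MixtureModel-class]).
#' @return message length in nats.
#' @examples
#' x <- matrix(c(-1, 0, 1), ncol = 1)
#' mix <- partitionToMixture(x, rep(1L, 3), "full")$mixture
#' messageLength(x, mix)
#' @export
setGeneric("messageLength", function(object, ...) standardGeneric("messageLength"))

#' @rdname SmartResult-class
#' @param object,x a `SmartResult`.
#' @export
setGeneric("clusterLabels", function(object, ...) standardGeneric("clusterLabels"))

#' @rdname SmartResult-class
#' @export
setGeneric("numClusters", function(object, ...) standardGeneric("numClusters"))

#' @rdname SmartResult-class
#' @export
setGeneric("candidates", function(object, ...) standardGeneric("candidates"))

#' @rdname SmartResult-class
#' @export
setGeneric("trajectory", function(object, ...) standardGeneric("trajectory"))

#' @rdname SmartResult-class
#' @export
setGeneric("mixtureModel", function(object, ...) standardGeneric("mixtureModel"))

#' @rdname MixtureModel-class
#' @param object,x a `MixtureModel`.
#' @export
setGeneric("mixtureWeights", function(object, ...) standardGeneric("mixtureWeights"))

#' @rdname MixtureModel-class
#' @export
setGeneric("mixtureMeans", function(object, ...) standardGeneric("mixtureMeans"))

#' @rdname MixtureModel-class
#' @export
setGeneric("mixtureCovariances", function(object, ...) standardGeneric("mixtureCovariances"))

#' @rdname MixtureModel-class
#' @export
setGeneric("covStructure", function(object, ...) standardGeneric("covStructure"))

#' @rdname MixtureModel-class
#' @export
setGeneric("numComponents", function(object, ...) standardGeneric("numComponents"))
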