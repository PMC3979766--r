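#' @include AllGenerics.R
NULL

#' @rdname MixtureModel-class
#' @export
setMethod("mixtureWeights", "MixtureModel", function(object, ...) object@weights)

#' @rdname MixtureModel-class
#' @export
setMethod("mixtureMeans", "MixtureModel", function(object, ...) object@means)

#' @rdname MixtureModel-class
#' @export
setMethod("mixtureCovariances", "MixtureModel", function(object, ...) object@covariances)

#' @rdname MixtureModel-class
#' @export
setMethod("covStructure", "MixtureModel", function(object, ...) object@covStructure)

#' @rdname MixtureModel-class
#' @param countZero if `TRUE` count annihilated (zero-weight) components too.
#' @export
setMethod("numComponents", "MixtureModel", function(object, countZero = FALSE, ...) {
  if (countZero) length(object@weights) else sum(object@weights > 0)
})

setMethod("show", "MixtureModel", function(object) {
  k <- length(object@weights)
  knz <- sum(object@weights > 0)
  cat(sprintf("MixtureModel: %d component(s) (%d with positive weight), d = %d, %s covariance\n",
              k, knz, nrow(object@means), object@covStructure))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
  invisible(NULL)
})

#' @rdname SmartResult-class
#' @export
setMethod("clusterLabels", "SmartResult", function(object, ...) object@labels)

#' @rdname SmartResult-class
#' @export
setMethod("numClusters", "SmartResult", function(object, ...) max(object@labels))

#' @rdname SmartResult-class
#' @export
setMethod("candidates", "SmartResult", function(object, ...) object@candidates)

#' @rdname SmartResult-class
#' @export
setMethod("trajectory", "SmartResult", function(object, ...) object@trajectory)

#' @rdname SmartResult-class
#' @export
setMethod("mixtureModel", "SmartResult", function(object, ...) object@mixture)

#' @rdname messageLength
#' @export
setMethod("messageLength", "SmartResult", function(object, ...) object@messageLength)

setMethod("show", "SmartResult", function(object) {
  cat(sprintf("SmartResult (%s): %d cluster(s) selected from %d candidate(s)\n",
              object@method, max(object@labels), length(object@candidates)))
  cat(sprintf("  message length: %.3f nats\n", object@messageLength))
  ks <- vapply(object@candidates, function(cc) cc$knz, integer(1))
  Ls <- vapply(object@candidates, function(cc) cc$messageLength, numeric(1))
  cat("  candidates (k: length):",
      paste(sprintf("%d: %.1f", ks, Ls), collapse = ", "), "\n")
  cat("  cluster sizes:", paste(tabulate(object@labels), collapse = " "), "\n")
  invisible(NULL)
})
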