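#' @include AllClasses.R
NULL

# ridge factor applied after every covariance estimate; keeps fits positive
# definite for small clusters in high dimension
.EPS_REG <- 1e-6

#' Standardize the rows of an expression matrix
#'
#' Scales each row (gene profile) to zero mean and unit sample standard
#' deviation (denominator n - 1). Row names are preserved. Constant rows are
#' an error because they carry no profile shape to standardize.
#'
#' @param x numeric matrix (objects x features) with at least 2 rows.
#' @return matrix of the same shape, each row with mean 0 and sd 1.
#' @examples
#' standardizeRows(matrix(1:6, 2, 3, byrow = TRUE))
#' @export
standardizeRows <- function(x) {
  x <- .checkDataMatrix(x)
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  bad <- !is.finite(s) | s <= 0
  if (any(bad)) {
    ids <- rownames(x)[bad]
    if (is.null(ids)) ids <- which(bad)
    stop("zero-variance row(s) cannot be standardized: ",
         paste(utils::head(ids, 5L), collapse = ", "))
  }
  (x - mu) / s
}

# validate an objects x features matrix; coerce data.frame, require finite
# entries, n >= 2, d >= 1, unique row ids when present
.checkDataMatrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("data must be a numeric matrix (objects in rows)")
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop("data must have at least 2 rows and 1 column")
  if (!all(is.finite(x)))
    stop("data contains non-finite entries")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x)))
    stop("duplicate row identifiers: ",
         paste(utils::head(unique(rownames(x)[duplicated(rownames(x))]), 5L),
               collapse = ", "))
  x
}

#' Multivariate Gaussian log-density
#'
#' Log of the multivariate normal density, evaluated via the Cholesky factor
#' of the covariance. `x` may be a single length-d vector or an n x d matrix
#' (one value per row).
#'
#' @param x numeric vector (length d) or n x d matrix of evaluation points.
#' @param mean length-d mean vector.
#' @param covariance d x d symmetric positive-definite matrix.
#' @return log-density value(s).
#' @examples
#' gaussianLogPdf(0, 0, matrix(1))      # -0.5 * log(2 * pi)
#' @export
gaussianLogPdf <- function(x, mean, covariance) {
  if (!is.matrix(covariance)) covariance <- as.matrix(covariance)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  d <- length(mean)
  R <- tryCatch(chol(covariance),
                error = function(e)
                  stop("singular covariance: regularize it (e.g. with ",
                       "regularizeCovariance()) before evaluating the density"))
  logdet <- 2 * sum(log(diag(R)))
  z <- backsolve(R, t(x) - mean, transpose = TRUE)
  q <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + logdet + q)
}

#' Ridge-regularize a covariance estimate
#'
#' Adds `eps * mean(diag(S)) * I` to the estimate (with the ridge floored at
#' `eps` when the diagonal is all zero, as happens for clusters of identical
#' points), guaranteeing positive definiteness. An optional per-dimension
#' variance floor lifts deficient diagonal entries to `varFloor`, which
#' blocks the classic EM degeneracy of a component collapsing onto a handful
#' of near-coincident points (adding to the diagonal preserves positive
#' definiteness).
#'
#' @param S symmetric covariance estimate.
#' @param eps ridge factor (default 1e-6).
#' @param varFloor optional length-d vector (or scalar) of minimum diagonal
#'   variances.
#' @return regularized covariance.
#' @export
regularizeCovariance <- function(S, eps = .EPS_REG, varFloor = NULL) {
  S <- (S + t(S)) / 2
  ridge <- eps * mean(diag(S))
  if (!is.finite(ridge) || ridge <= 0) ridge <- eps
  S <- S + diag(ridge, nrow(S))
  if (!is.null(varFloor))
    S <- S + diag(pmax(0, varFloor - diag(S)), nrow(S))
  S
}

# impose the covariance-structure tag on a raw estimate
.structureCovariance <- function(S, covStructure) {
  switch(covStructure,
    full      = S,
    diagonal  = diag(diag(S), nrow(S)),
    spherical = diag(mean(diag(S)), nrow(S)),
    stop("unknown covariance structure: ", covStructure)
  )
}

# default structure: full covariance for low-d demonstrations, diagonal for
# gene-expression dimensionality
.defaultCovStructure <- function(d) if (d <= 3L) "full" else "diagonal"

# log-density of every row of x under every mixture component -> n x k matrix
# (columns of annihilated components are left at -Inf)
.componentLogDensities <- function(x, mix) {
  n <- nrow(x)
  k <- length(mix@weights)
  out <- matrix(-Inf, n, k)
  for (m in seq_len(k)) {
    if (mix@weights[m] > 0)
      out[, m] <- gaussianLogPdf(x, mix@means[, m], mix@covariances[[m]])
  }
  out
}

# numerically stable row-wise log-sum-exp
.logRowSumExp <- function(lw) {
  mx <- apply(lw, 1L, max)
  mx + log(rowSums(exp(lw - mx)))
}
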