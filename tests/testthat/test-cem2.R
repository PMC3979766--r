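mixFromBlobs <- function(blobs, covStructure = "full") {
  partitionToMixture(blobs$x, blobs$labels, covStructure)$mixture
}

test_that("E-step responsibilities are normalized and prior-weighted", {
  x <- matrix(c(0, 0), 1, 2)
  x <- rbind(x, c(10, 10))  # second row keeps n >= 2
  mk <- function(w) MixtureModel(w, cbind(c(-1, 0), c(1, 0)),
                                 rep(list(diag(2)), 2), "full")
  # equidistant point, equal weights -> (1/2, 1/2)
  w <- eStep(x, mk(c(0.5, 0.5)))
  expect_equal(w[1, ], c(0.5, 0.5))
  expect_equal(rowSums(w), c(1, 1))
  # equal densities, unequal priors -> prior split
  w2 <- eStep(x, mk(c(0.8, 0.2)))
  expect_equal(w2[1, ], c(0.8, 0.2))
  # an annihilated component gets a zero column
  mix0 <- MixtureModel(c(1, 0), cbind(c(0, 0), c(5, 5)),
                       rep(list(diag(2)), 2), "full")
  w3 <- eStep(x, mix0)
  expect_equal(w3[, 2], c(0, 0))
  expect_equal(rowSums(w3), c(1, 1))
})

test_that("the annihilating weight update applies the max(0, support - N/2) rule", {
  w <- rbind(matrix(0, 0, 2))
  # column sums (50, 3) with N = 10 -> numerators (45, 0) -> (1, 0)
  w1 <- matrix(0, 53, 2); w1[1:50, 1] <- 1; w1[51:53, 2] <- 1
  expect_equal(updateMixingWeights(w1, 10), c(1, 0))
  # symmetric supports stay symmetric
  w2 <- matrix(0.5, 60, 2)
  expect_equal(updateMixingWeights(w2, 10), c(0.5, 0.5))
  # both below threshold -> error
  w3 <- matrix(0, 8, 2); w3[1:4, 1] <- 1; w3[5:8, 2] <- 1
  expect_error(updateMixingWeights(w3, 10), "annihilated")
})

test_that("component M-step reduces to weighted mean and structured covariance", {
  x <- rbind(c(0, 0), c(2, 0), c(5, 5), c(7, 9))
  w <- c(1, 1, 0, 0)
  f <- mStepComponent(x, w, "full")
  expect_equal(f$mean, c(1, 0))
  # uniform weights give the global centroid
  fu <- mStepComponent(x, rep(1, 4), "full")
  expect_equal(fu$mean, colMeans(x))
  # spherical tag: covariance is (mean per-dimension variance) * I
  set.seed(51)
  z <- matrix(rnorm(40, sd = c(1, 3)), 20, 2, byrow = TRUE)
  fs <- mStepComponent(z, rep(1, 20), "spherical")
  expect_equal(fs$covariance[1, 1], fs$covariance[2, 2])
  expect_equal(fs$covariance[1, 2], 0)
  expect_error(mStepComponent(x, c(0.5, 0.4, 0, 0), "full"), "insufficient")
})

test_that("cem2 prunes a redundant component on single-Gaussian data", {
  set.seed(52)
  x <- matrix(rnorm(300), 150, 2)
  # k = 2 start at two data rows with the global covariance
  gc0 <- regularizeCovariance(cov(x) * 149 / 150)
  mix <- MixtureModel(c(0.5, 0.5), t(x[c(1, 80), ]), list(gc0, gc0), "full")
  r <- cem2(x, mix)
  expect_lte(numComponents(r$mixture), 2L)
  # the k = 1 fit achieves a lower message length than the k = 2 start
  pm1 <- partitionToMixture(x, rep(1L, 150), "full")
  expect_lt(messageLength(x, pm1$mixture),
            messageLength(x, mix))
})

test_that("cem2 recovers well-separated components without merging", {
  blobs <- makeBlobs(n = 200, G = 4, d = 2, sep = 12, sd = 1, seed = 53)
  r <- cem2(blobs$x, mixFromBlobs(blobs))
  expect_equal(numComponents(r$mixture), 4L)
  expect_equal(r$merges, 0L)
  got <- mixtureMeans(r$mixture)
  for (g in 1:4) {
    d2 <- colSums((got - blobs$centers[g, ])^2)
    expect_lt(sqrt(min(d2)), 0.5)  # within half a within-blob sd of truth
  }
})

test_that("message length is non-increasing across annihilating sweeps", {
  blobs <- makeBlobs(n = 120, G = 3, d = 2, sep = 8, seed = 54)
  r <- cem2(blobs$x, mixFromBlobs(blobs))
  L <- r$trace$messageLength
  expect_true(all(diff(L) <= 1e-8 * abs(L[-length(L)])))
})

test_that("tol = 0 with maxSweeps = 1 performs exactly one sweep", {
  blobs <- makeBlobs(n = 40, G = 2, seed = 55)
  r <- cem2(blobs$x, mixFromBlobs(blobs), tol = 0, maxSweeps = 1L)
  expect_equal(max(r$trace$sweep), 1L)
})

test_that("a component with support below N/2 is annihilated within one sweep", {
  set.seed(56)
  x <- matrix(rnorm(400), 200, 2)
  # third component parked far away: expected support ~ 0 < N/2
  gc0 <- regularizeCovariance(cov(x))
  mix <- MixtureModel(c(0.45, 0.45, 0.1),
                      cbind(x[1, ], x[100, ], c(50, 50)),
                      list(gc0, gc0, gc0), "full")
  r <- cem2(x, mix, tol = 0, maxSweeps = 1L)
  expect_gte(r$merges, 1L)
  expect_lte(numComponents(r$mixture), 2L)
})

test_that("weights sum to one after every recorded update", {
  blobs <- makeBlobs(n = 100, G = 3, sep = 6, seed = 57)
  r <- cem2(blobs$x, mixFromBlobs(blobs))
  expect_equal(sum(mixtureWeights(r$mixture)), 1, tolerance = 1e-9)
  expect_equal(rowSums(r$responsibilities), rep(1, 100), tolerance = 1e-9)
})

test_that("splitInject seeds the farthest object with averaged covariance", {
  x <- matrix(c(0, 1, 9, 10, 25), ncol = 1,
              dimnames = list(sprintf("r%d", 1:5), NULL))
  mix <- MixtureModel(c(0.5, 0.5), matrix(c(0, 10), 1, 2),
                      list(matrix(1), matrix(3)), "full")
  out <- splitInject(x, mix)
  expect_equal(length(mixtureWeights(out)), 3L)
  expect_equal(mixtureMeans(out)[, 3], 25, ignore_attr = TRUE)
  expect_equal(mixtureCovariances(out)[[3]], matrix(2))
  expect_equal(mixtureWeights(out), c(0.5 * 2 / 3, 0.5 * 2 / 3, 1 / 3))
  # k = 1 newcomer takes weight 1/2
  m1 <- MixtureModel(1, matrix(0), list(matrix(1)), "full")
  out1 <- splitInject(x, m1)
  expect_equal(mixtureWeights(out1), c(0.5, 0.5))
})
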