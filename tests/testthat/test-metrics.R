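test_that("adjusted Rand index matches hand-computed and boundary cases", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # invariance under relabeling of either side
  set.seed(1)
  a <- sample(3, 40, TRUE); b <- sample(4, 40, TRUE)
  perm <- sample(4)
  expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(a, perm[b]))
  expect_error(adjustedRandIndex(1:3, 1:4), "length")
})

test_that("ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:5) {
    a <- sample(4, 60, TRUE); b <- sample(3, 60, TRUE)
    expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("NMI handles independence, identity and degenerate partitions", {
  expect_equal(normalizedMutualInformation(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(normalizedMutualInformation(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(normalizedMutualInformation(c(1, 1, 2, 2), rep(1, 4)), 0)
  expect_equal(normalizedMutualInformation(rep(1, 4), rep(2, 4)), 1)
})

test_that("NMI agrees with an independently coded evaluation", {
  # oracle: explicit double loop over the contingency cells, natural logs,
  # geometric-mean normalization
  nmiOracle <- function(a, b) {
    n <- length(a)
    ua <- sort(unique(a)); ub <- sort(unique(b))
    mi <- 0
    for (i in ua) for (j in ub) {
      pij <- sum(a == i & b == j) / n
      if (pij > 0)
        mi <- mi + pij * log(pij / ((sum(a == i) / n) * (sum(b == j) / n)))
    }
    ha <- -sum(vapply(ua, function(i) {
      p <- sum(a == i) / n; p * log(p)
    }, numeric(1)))
    hb <- -sum(vapply(ub, function(j) {
      p <- sum(b == j) / n; p * log(p)
    }, numeric(1)))
    mi / sqrt(ha * hb)
  }
  set.seed(3)
  for (i in 1:5) {
    a <- sample(4, 80, TRUE); b <- sample(5, 80, TRUE)
    expect_equal(normalizedMutualInformation(a, b), nmiOracle(a, b),
                 tolerance = 1e-9)
  }
})

test_that("Jaccard index over pairs matches enumeration and conventions", {
  expect_equal(jaccardIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(jaccardIndex(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.25)
  expect_equal(jaccardIndex(1:4, 4:1), 1)  # all singletons: 0/0 := 1
})

test_that("pair counts agree exactly with O(n^2) brute force", {
  set.seed(7)
  for (i in 1:4) {
    n <- sample(30:120, 1)
    a <- sample(5, n, TRUE); b <- sample(4, n, TRUE)
    pc <- pairCounts(a, b)
    bf <- bruteForcePairCounts(a, b)
    expect_identical(as.integer(unlist(pc)), as.integer(unlist(bf)))
    expect_equal(pc$tp + pc$fp + pc$fn + pc$tn, choose(n, 2))
  }
})

test_that("silhouette matches the hand-evaluated two-cluster example", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(silhouetteIndex(x, labels),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-12)
  expect_error(silhouetteIndex(x, rep(1, 4)), "2 clusters")
})

test_that("Calinski-Harabasz matches the hand-evaluated example and flags W = 0", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinskiHarabasz(x, c(1, 1, 2, 2)), 200)
  x0 <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_identical(calinskiHarabasz(x0, c(1, 1, 2, 2)), Inf)
  expect_error(calinskiHarabasz(x, rep(1, 4)), "requires")
})

test_that("silhouette and CH agree with independent references on random data", {
  skip_if_not_installed("mclust")
  set.seed(9)
  blobs <- makeBlobs(n = 40, G = 3, d = 2, sep = 6, seed = 9)
  # reference silhouette via cluster:: directly on a fresh distance object
  ref <- mean(cluster::silhouette(blobs$labels, dist(blobs$x))[, 3])
  expect_equal(silhouetteIndex(blobs$x, blobs$labels), ref, tolerance = 1e-9)
  # CH cross-check from scatter matrices computed a second way
  x <- blobs$x; lab <- blobs$labels
  tot <- sum(scale(x, scale = FALSE)^2)
  W <- sum(sapply(unique(lab), function(c)
    sum(scale(x[lab == c, , drop = FALSE], scale = FALSE)^2)))
  K <- length(unique(lab)); n <- nrow(x)
  expect_equal(calinskiHarabasz(x, lab),
               ((tot - W) / (K - 1)) / (W / (n - K)), tolerance = 1e-9)
})

test_that("correct selection rate is a percentage of exact matches", {
  expect_equal(correctSelectionRate(c(4, 4, 4, 4), 4), 100)
  expect_equal(correctSelectionRate(c(4, 4, 5, 3), 4), 50)
  expect_error(correctSelectionRate(integer(0), 4), "empty")
})
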