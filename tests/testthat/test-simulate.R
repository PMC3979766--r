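test_that("QPSK generator honors the constellation and noise law", {
  # noiseless limit: every point sits exactly on a corner
  sim0 <- simulateQPSK(n = 40, snrDb = 300, seed = 1)
  corners <- matrix(c(1, 1, -1, 1, -1, -1, 1, -1), ncol = 2, byrow = TRUE) / sqrt(2)
  expect_equal(sim0$x, corners[sim0$labels, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  # moment check: empirical noise variance within 5% of sigma^2 at n = 1e4
  sim <- simulateQPSK(n = 10000, snrDb = 15, seed = 2)
  resid <- sim$x - corners[sim$labels, ]
  expect_equal(mean(resid^2), 10^(-1.5) / 2, tolerance = 0.05)
  # symbols are uniform over the four corners
  expect_gt(chisq.test(table(sim$labels))$p.value, 1e-6)
  # per-label means approach the corners
  for (l in 1:4) {
    mu <- colMeans(sim$x[sim$labels == l, ])
    expect_lt(sqrt(sum((mu - corners[l, ])^2)), 0.02)
  }
})

test_that("GMM generator respects weights and degenerate covariances", {
  sim <- simulateGMM(n = 50, weights = c(1, 0, 0), seed = 3)
  expect_true(all(sim$labels == 1))
  simz <- simulateGMM(n = 20, weights = c(0.5, 0.5),
                      means = list(c(0, 0), c(5, 5)),
                      covariances = rep(list(diag(0, 2)), 2), seed = 4)
  mns <- rbind(c(0, 0), c(5, 5))
  expect_equal(simz$x, mns[simz$labels, ], tolerance = 1e-12, ignore_attr = TRUE)
  # law of large numbers on the mixing proportions
  big <- simulateGMM(n = 30000, seed = 5)
  expect_true(all(abs(tabulate(big$labels) / 30000 - 1 / 3) < 0.01))
  expect_error(simulateGMM(n = 10, weights = 1, means = list(c(0, 0)),
                           covariances = list(matrix(c(1, 2, 2, 1), 2))),
               "positive")
})

test_that("state-based generator produces 4-level piecewise-constant profiles when noiseless", {
  sim <- simulateS1(k = 3, sizeMean = 12, mSamples = 12, templateSd = 1.5,
                    sampleSd = 0, geneSd = 0, noiseSd = 0, seed = 6)
  for (c in 1:3) {
    block <- sim$x[sim$labels == c, , drop = FALSE]
    # all genes of the cluster share one profile
    expect_equal(max(apply(block, 2, function(col) diff(range(col)))), 0)
    # the shared profile has at most 4 distinct levels, in contiguous runs
    lv <- rle(block[1, ])$values
    expect_lte(length(unique(block[1, ])), 4)
    expect_lte(length(lv), 4)
  }
})

test_that("state-based generator sizes follow the floored Poisson law", {
  sim <- simulateS1(k = 5, sizeMean = 11, mSamples = 8, seed = 7)
  sizes <- tabulate(sim$labels)
  expect_true(all(sizes >= 10))
  expect_equal(sum(sizes), nrow(sim$x))
  expect_error(simulateS1(mSamples = 3), "4 expression periods")
})

test_that("periodic generator reproduces the noiseless cyclic model exactly", {
  sim <- simulateS2(g = 10, m = 24, k = 5, lam = 3, thetaMag = 0, thetaPhase = 0,
                    seed = 8)
  j <- 0:23
  for (g in c(1, 5, 10)) {
    omega <- 2 * pi * sim$labels[g] / 5
    expect_equal(sim$x[g, ], 3 * sin(2 * pi * j / 8 + omega), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(abs(sim$x) <= 3 + 1e-12))
  # period 8: values repeat every 8 samples
  expect_equal(sim$x[, 1:8], sim$x[, 9:16], ignore_attr = TRUE)
})

test_that("phase noise degrades within-cluster coherence monotonically", {
  wcc <- function(theta) {
    r <- numeric(25)
    for (i in 1:25) {
      sim <- simulateS2(g = 40, k = 4, thetaMag = 0.1, thetaPhase = theta,
                        seed = 100 + i)
      cors <- unlist(lapply(1:4, function(c) {
        cc <- cor(t(sim$x[sim$labels == c, ]))
        cc[upper.tri(cc)]
      }))
      r[i] <- mean(cors)
    }
    mean(r)
  }
  expect_gt(wcc(0.1), wcc(1.0))
})

test_that("generators are reproducible under a fixed seed and label-consistent", {
  a <- simulateS1(k = 3, sizeMean = 12, mSamples = 10, noiseSd = 0.2, seed = 42)
  b <- simulateS1(k = 3, sizeMean = 12, mSamples = 10, noiseSd = 0.2, seed = 42)
  expect_identical(a, b)
  for (sim in list(a, simulateQPSK(n = 50, seed = 1), simulateS2(g = 20, seed = 1))) {
    K <- max(sim$labels)
    expect_setequal(unique(sim$labels), seq_len(K))
    expect_equal(length(sim$labels), nrow(sim$x))
    expect_false(anyDuplicated(rownames(sim$x)) > 0)
  }
})
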