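#' @include smart.R simulate.R metrics.R
NULL

#' Replicate the simulation experiments
#'
#' Reruns the benchmark experiments at desk scale: generates datasets from
#' the named simulator, clusters each replicate, and tabulates the selected
#' number of clusters and agreement metrics per replicate plus aggregate
#' mean, standard deviation and correct-selection rate.
#'
#' Experiments: `"d1"` (512-point QPSK at 15 dB), `"d2"` (overlapping
#' 3-component bivariate mixture, n = 900), `"s1_sweep"` (state-based
#' expression over a noise-sd grid), `"s2_sweep"` (periodic expression over
#' a theta grid, magnitude and phase noise coupled pairwise).
#'
#' @param name one of `"d1"`, `"d2"`, `"s1_sweep"`, `"s2_sweep"`.
#' @param reps replicates per condition (default 20).
#' @param seed optional integer seed.
#' @param methods character vector among `"smart2"`, `"smart1"` (default
#'   `"smart2"`).
#' @param noiseGrid S1 noise-sd grid (default `c(0, 0.1, 0.2)`).
#' @param thetaGrid S2 theta grid, used for both magnitude and phase noise
#'   (default `c(0.1, 0.5, 1)`).
#' @param config base configuration from [smartConfig()].
#' @return list with `perRep` (one row per replicate: condition, method,
#'   kHat, ARI, NMI, JI) and `summary` (per condition and method: mean and
#'   sd of each metric, CSR in percent).
#' @export
replicateExperiment <- function(name = c("d1", "d2", "s1_sweep", "s2_sweep"),
                                reps = 20L, seed = NULL,
                                methods = "smart2",
                                noiseGrid = c(0, 0.1, 0.2),
                                thetaGrid = c(0.1, 0.5, 1),
                                config = smartConfig()) {
  name <- match.arg(name)
  stopifnot(reps >= 1, all(methods %in% c("smart1", "smart2")))
  if (!is.null(seed)) set.seed(seed)
  conditions <- switch(name,
    d1 = data.frame(condition = "snr15"),
    d2 = data.frame(condition = "base"),
    s1_sweep = data.frame(condition = sprintf("noise%.2g", noiseGrid),
                          noise = noiseGrid),
    s2_sweep = data.frame(condition = sprintf("theta%.2g", thetaGrid),
                          theta = thetaGrid)
  )
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    for (r in seq_len(reps)) {
      sim <- switch(name,
        d1 = simulateQPSK(),
        d2 = simulateGMM(),
        s1_sweep = simulateS1(noiseSd = conditions$noise[ci]),
        s2_sweep = simulateS2(thetaMag = conditions$theta[ci],
                              thetaPhase = conditions$theta[ci])
      )
      kTrue <- max(sim$labels)
      for (mth in methods) {
        res <- if (mth == "smart2") runSmart2(sim$x, config)
               else runSmart1(sim$x, config)
        lab <- clusterLabels(res)
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = name, condition = conditions$condition[ci],
          rep = r, method = mth, kTrue = kTrue, kHat = numClusters(res),
          ari = adjustedRandIndex(sim$labels, lab),
          nmi = normalizedMutualInformation(sim$labels, lab),
          ji = jaccardIndex(sim$labels, lab)
        )
      }
    }
  }
  perRep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(perRep, list(perRep$condition, perRep$method), drop = TRUE),
    function(g) data.frame(
      experiment = g$experiment[1L], condition = g$condition[1L],
      method = g$method[1L], reps = nrow(g),
      kHatMean = mean(g$kHat),
      csr = correctSelectionRate(g$kHat, g$kTrue[1L]),
      ariMean = mean(g$ari), ariSd = if (nrow(g) > 1L) stats::sd(g$ari) else NA_real_,
      nmiMean = mean(g$nmi), jiMean = mean(g$ji)
    )))
  rownames(summ) <- NULL
  list(perRep = perRep, summary = summ)
}
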