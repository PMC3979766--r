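# smartclust

Splitting-while-merging clustering with automatic model-order selection,
for gene-expression matrices and general numeric data.

## The problem and the approach

Clustering genes by expression profile usually requires the number of
clusters K in advance — which is what one actually wants to discover.
`smartclust` estimates K automatically with a splitting-while-merging (SWM)
loop: start from one cluster, split one cluster at a time, watch for merges
throughout, record every intermediate clustering, and select the final
result by a minimum-message-length (MML) criterion. The loop needs no
dataset-dependent parameters; it stops once the cumulative number of merges
reaches a small budget, on the observation that merging becomes frequent
only after the natural structure has been passed.

Two engines implement the loop:

* `runSmart2()` — a finite Gaussian mixture learned by modified
  component-wise EM. A Dirichlet-type prior turns the mixing-weight update
  into `alpha_m ∝ max(0, support_m − B)`, which *annihilates* (weight
  exactly 0) any component whose expected support falls below the bar
  `B = max(N/2, 12)` (N = parameters per component); annihilations are the
  merge events. Splits inject a component at the data row farthest from all
  surviving component means.
* `runSmart1()` — one-prototype-take-one-cluster (OPTOC) competitive
  learning with a density-based cohesion merging rule.

Every recorded candidate is scored by the two-part code length

```
L(theta, Y) = (N/2) * sum_m log(n*alpha_m/12) + (k/2) log(n/12)
              + k(N+1)/2 − log p(Y | theta)        [nats]
```

and the shortest message wins.

The package also ships generators for the four benchmark families used in
its validation suite (QPSK constellation data, an overlapping bivariate
Gaussian mixture, state-based and periodic synthetic gene expression),
external/internal validation indices (ARI, NMI, Jaccard, CSR, silhouette,
Calinski–Harabasz), TSV/CSV readers and writers, a replication harness, and
a thin command-line front end (`inst/cli/smartclust.R`).

## A worked example

```r
library(smartclust)

sim <- simulateQPSK(n = 256, snrDb = 15, seed = 7)   # 4 constellation points
res <- runSmart2(sim$x, smartConfig(seed = 7))
res
#> SmartResult (smart2): 4 cluster(s) selected from 9 candidate(s)
#>   message length: 40.410 nats
#>   candidates (k: length): 1: 565.1, 2: 428.2, 3: 180.8, 4: 40.4, 4: 40.4,
#>     4: 40.4, 4: 40.4, 4: 40.4, 4: 40.4
#>   cluster sizes: 67 76 53 60

adjustedRandIndex(sim$labels, clusterLabels(res))
#> [1] 1
```

The candidate list is the SWM trajectory: the code length collapses when
the true model order is reached (k = 4, 40.4 nats, against 180.8 at k = 3),
and the injections attempted afterwards fail to shorten the message — each
failure counts as a merge, five merges end the loop, and the shortest
candidate is returned. The selected labels recover the generating
partition exactly (adjusted Rand index 1).

Accessors: `clusterLabels()`, `numClusters()`, `messageLength()`,
`candidates()`, `trajectory()`, `mixtureModel()` (with `mixtureWeights()`,
`mixtureMeans()`, `mixtureCovariances()` on the mixture).

For gene-expression input from disk:

```r
x <- readExpressionMatrix("expr.tsv")     # rows = genes, first column = ids
x <- standardizeRows(x)                   # per-gene zero mean, unit variance
res <- runSmart2(x, smartConfig(seed = 1))
writeClusterLabels("clusters.tsv", rownames(x), clusterLabels(res))
```

## Status and caveats

Model-order recovery is exact across the validation suite's replicates for
the QPSK constellation and the periodic expression model, and ≥ 90% for the
state-based expression model at low noise. The heavily overlapping
three-component mixture is deliberately hard: the code-length optimum
genuinely sits at four components on a sizeable fraction of draws, and the
selected order is unstable there (see the vignette's *Known limitations*
for the analysis and the `graceSweeps` trade-off). The competitive-learning
engine is spherical by construction; the mixture engine is the recommended
default.
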