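# landres

Individual-based landscape genetics on raster resistance surfaces:
estimating how landscape features impede or promote gene flow, and mapping
the movement corridors those estimates imply.

## The problem and who this is for

Populations of habitat specialists in fragmented landscapes persist as
metapopulations whose connectivity depends on the matrix between patches —
roads, development, forest, water, wetlands, and the shrubby linear
corridors (roadsides, powerlines, railroads) that can function as dispersal
habitat. `landres` is for landscape geneticists who have (or simulate)
georeferenced multilocus genotypes and categorical landcover rasters and
want to:

1. estimate a resistance value for each landscape feature from the genetic
   data (univariate optimization),
2. rank a priori multivariate hypotheses about which feature combinations
   drive gene flow (mixed-model AICc), and
3. map corridors on the best surface with both least-cost-path and
   circuit-theory methods.

## The method

**Genetic distances.** Between all pairs of individuals: Rousset's *a*
(the between-individual analogue of F/(1−F), estimated from allelic
identity probabilities with a ratio-of-sums multilocus combination) and
*Dps* (1 − proportion of shared alleles). Geographic distance is
straight-line metres.

**Effective distances.** A resistance surface assigns every cell a cost;
the effective distance between two individuals is the cumulative cost of
the least-cost path (exact Dijkstra, 8-connected, edge weight = mean cell
resistance, ×√2 on diagonals).

**Univariate optimization.** Each feature is tested as a binary friction
grid — barriers at values {2, 5, 10, 25, 50, 100, 250, 500, 750, 1000}
against background 1, facilitators at 1 against background 100 — and scored
by the partial Mantel correlation of genetic with effective distance
controlling geographic distance. The selected value is the interior peak of
the r profile, or the onset of its plateau (within 1% of the maximum).

**Model ranking.** Multivariate surfaces composed from the optimized
values (barriers by cell-wise maximum, facilitator override off roads,
buffered roads as simultaneous barrier + roadside facilitator) are fitted
with maximum-likelihood population-effects (MLPE) regressions — pairs
sharing an individual have correlation ρ — and ranked by AICc and Akaike
weights against an isolation-by-distance null.

**Corridors.** Least-cost-path networks among all sampling locations,
all-to-one circuit current maps over individual nodes or focal patches,
and a divergence layer marking high-current cells that carry no LCP.

Everything is exercisable end-to-end on synthetic landscapes and genotypes;
the generators are first-class, tested code.

## Worked example

Recover a known resistance value from synthetic data and rank the surface
against the null:

```r
library(landres)
set.seed(42)
layer <- generate_barrier_bands(60, 60, n_bands = 4, seed = 42)   # truth: barrier
cells <- cbind(sample(60, 30, replace = TRUE), sample(60, 30, replace = TRUE))
truth <- build_univariate_surface(layer, "barrier", value = 100)
cd    <- cost_distance_matrix(truth, cells)
genetic    <- generate_pairwise_genetic(cd$distances, beta_true = 1,
                                        noise_sd = 0.5, rho = 0.25, seed = 1)
geographic <- dist_matrix(as.matrix(dist(cells * 30)),   # 30 m cells
                          rownames(genetic), "geographic")
trace <- optimize_univariate(layer, "barrier", genetic, geographic, cells,
                             n_perm = 999, seed = 2)
```

The optimization trace scans the candidate grid and prints, for each value,
the partial Mantel r (controlling geographic distance):

```
   value      r     p
1      2 0.4080 0.001
...
6    100 0.7818 0.001
7    250 0.7605 0.001
...
selected: 100 | rule: peak
```

The profile peaks at the generating value, 100 — an interior strict peak,
so the peak rule applies. Fitting the selected surface with MLPE and
ranking against the isolation-by-distance null:

```
          model   AICc  dAICc AICcWt
1 barrier_bands 409.05   0.00      1
2          null 910.47 501.42      0

MLPE fit 'barrier_bands'
  slope (standardized): 0.9783  [0.9436, 1.0130]
  rho: 0.2362  sigma2: 0.12278
  logLik -200.478 on 435 pairs (30 individuals), AICc 409.049
```

The slope recovers the generating effect size (1) inside its 95% interval,
ρ̂ ≈ 0.24 matches the generating shared-individual correlation (0.25), and
the surface model takes all the Akaike weight.

The whole two-step analysis — per-area optimization, univariate and
multivariate model tables, full-extent reconciliation, corridor maps —
runs from one configuration:

```r
res <- run_pipeline(list(seed = 1), "out/")   # defaults: synthetic landscape
res$multivariate_table_full                   # ranked hypothesis table
```

A thin shell wrapper is installed at `inst/scripts/landres`
(`landres run --config cfg.yaml --out out/`).

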