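---
title: "Optimizing landscape resistance surfaces from individual genetic distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing landscape resistance surfaces from individual genetic distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landres)
```

# The problem

Fragmented populations exchange genes through a landscape whose features
impede or promote movement. `landres` implements an individual-based
isolation-by-resistance analysis for such systems: every landscape feature
is hypothesised to act as a *barrier* (resistance above the background) or a
*facilitator* (resistance below it), the strength of each effect is
estimated from pairwise genetic distances between georeferenced individuals,
and the resulting multivariate resistance surface is used to map movement
corridors. The design follows the two-step scheme used in empirical
landscape genetics of early-successional specialists (e.g. shrubland
lagomorphs in a suburbanising coastal landscape): univariate optimization
first, multivariate hypothesis ranking second, corridor mapping last.

# Data model

* **Rasters** are plain matrices with a cell size in metres (default 30 m,
  the resolution of standard landcover products) and a lower-left origin;
  `NA` cells are nodata and are treated as impassable. I/O is ESRI ASCII
  grid.
* **Genotypes** are diploid microsatellite calls (default 11 loci) with
  projected sampling coordinates; I/O is GenePop plus a coordinate CSV.
* **Distance matrices** are symmetric with zero diagonals and carry their
  kind: `genetic_a` (Rousset's *a*), `genetic_dps` (1 − proportion of
  shared alleles), `geographic` (Euclidean metres) or `effective`
  (cumulative least-cost distance).

Two genetic metrics are provided because they weight allele sharing
differently: *Dps* is bounded in [0, 1] and purely descriptive, while
Rousset's *a* is the between-individual analogue of F/(1−F), may be
negative, and increases approximately linearly with distance under
isolation by distance. Rousset's *a* uses the dataset-wide average
within-individual identity per locus and a ratio-of-sums multilocus
combination; loci missing for a pair are excluded pairwise from both sums.

# Resistance surfaces

Univariate surfaces are binary friction grids: a barrier feature takes a
candidate value from the sanctioned grid {2, 5, 10, 25, 50, 100, 250, 500,
750, 1000} against a background of 1; a facilitator takes 1 against a
background of 100. Roads come in six traffic classes, one cell (30 m) wide
except class 1 (multi-lane highways), which is two cells (60 m).

Multivariate surfaces compose optimized univariate results under a fixed
precedence: background 1; barriers combine by cell-wise maximum;
facilitators then set the cells they cover to 1 except on road carriageway
cells; road buffers are applied last. Two compositional choices deserve
emphasis because the composition of overlapping optimized features is
genuinely underdetermined:

* *Precedence.* Barriers-by-maximum with facilitator override (off roads)
  is the only ordering that keeps the buffered-road construction — road
  cells at their barrier value flanked by one-cell strips of value 1 —
  expressible inside a single surface, so it is adopted globally.
* *Facilitator-only models.* A model containing only facilitators would be
  uniformly 1 against a background of 1 and hence degenerate. Such models
  are therefore built against the univariate facilitator background of 100,
  which preserves the univariate semantics and keeps the facilitator
  hypothesis set (natural, linear, all) mutually distinguishable.

The buffered-road surface encodes the dual role of roads — a perpendicular
barrier with parallel right-of-way facilitation — by giving carriageway
cells their optimized class value and every 8-adjacent non-road cell a
resistance of 1. Variants with only the maintained classes buffered versus
all classes buffered are fitted as alternative models and ranked.

# Distances on surfaces

Effective distances are exact Dijkstra shortest-path costs on the
8-connected cell graph with edge weight equal to the mean resistance of the
two end cells, times √2 for diagonal moves — the standard GIS cost-distance
semantics. Costs are reported in resistance × cell-length units: cell size
is a global factor that cancels in every downstream correlation and model
fit, so it is not multiplied in, and geographic distance is carried
separately in metres. Ties between equal-cost paths are broken
deterministically by the underlying graph library, so corridors are
reproducible across runs and platforms.

The circuit model replaces each cell pair with a resistor whose conductance
is the mean of the two cell conductances (divided by √2 on diagonals).
Systems are solved by direct sparse Cholesky factorization of the grounded
Laplacian; at the raster sizes this package targets the factorization is
exact to machine precision, deterministic, and faster than an iterative
solver, which is why no conjugate-gradient path is provided. All-to-one
maps follow the standard connectivity-software convention: each focal
element in turn is grounded while unit currents are injected at all others,
and per-cell current is accumulated as half the sum of absolute incident
branch currents. Focal patches are contracted to single super-nodes (their
internal resistors removed), and member cells inherit the super-node
current.

# Statistical machinery

**Mantel tests.** Surface support during optimization is the partial Mantel
correlation between genetic distance and effective distance, controlling
geographic distance by triangle-wise linear residualization. Permutation
inference jointly permutes rows and columns of the (residualized) predictor
matrix; p = (1 + #extreme)/(1 + n permutations), two-sided by default
(configurable), with a mandatory seed. The default permutation count in
pipeline runs is 9,999; optimization loops use fewer because selection
depends on r, not p.

**Peak/plateau selection.** For each feature the candidate grid is scanned
and the profile of partial Mantel r is summarized by one value: the global
maximum when it is an interior, strict peak; otherwise the smallest value
within 1% (relative) of the maximum — the onset of the plateau. The 1%
tolerance operationalizes "began to plateau", which has no standard numeric
definition; it is deliberately conservative, and the plateau rule exists
because absolute resistance becomes weakly identifiable once paths have
fully re-routed (see *Limitations*).

**MLPE ranking.** Model fit and ranking never use Mantel statistics.
Pairwise genetic distance is regressed on the standardized effective
distance of each candidate surface under the maximum-likelihood
population-effects covariance: observations sharing exactly one individual
have correlation ρ ∈ [0, 0.5). With Z the pair-to-individual incidence
matrix, the covariance is σ²(I + γZZᵀ), γ = ρ/(1 − 2ρ); the likelihood is
profiled over γ via the Woodbury identity and the matrix determinant lemma,
so each evaluation costs O(Nn + n³) rather than O(N³). Fits use ML (not
REML) so AICc is comparable across fixed-effect structures; k counts two
fixed effects plus ρ and σ². AICc uses the number of pairs as n, which is
anti-conservative (pairs are not independent observations) but is the
convention of the tables this machinery reproduces; ranked tables report
ΔAICc and Akaike weights and always include the isolation-by-distance null
(geographic distance as the predictor).

# The synthetic-data generators

Because the original GIS layers and genotypes are not redistributable, the
package carries first-class generators that emulate the study conditions:

* `generate_landscape()` grows blob-shaped landcover patches to target
  class proportions (defaults follow the two emulated study areas: a rural
  area with 58.8% forest and 11.2% development, and a suburban area with
  33.9% forest and 28.6% development), draws polyline roads of classes 1–6
  (class 1 two cells wide), a powerline and a railroad, and speckles ~1% of
  cells as LiDAR-detected 1–3 m vegetation.
* `generate_pairwise_genetic()` produces genetic distances directly from a
  cost matrix: μ + β·z(cost) + MLPE-correlated noise (individual effects
  give pairs sharing an individual correlation ρ). This gives exact control
  over effect size and noise for calibration tests.
* `simulate_genotypes_forward()` is the mechanistic alternative: a
  finite-island Wright–Fisher simulation with stepwise-mutating
  microsatellites and migration decaying as exp(−λ·cost), used where tests
  need real genotypes rather than distances.
* `generate_barrier_bands()` builds the value-recovery fixture: vertical
  barrier bands, most carrying one gap at a random height, every third band
  complete. Gapped bands force detours whose length depends on gap
  position rather than straight-line separation, which decorrelates cost
  distance from geographic distance; without this property the partial
  Mantel profile flattens early and high resistance values are not
  identifiable (see *Limitations*).

What the generators do **not** emulate: spatial autocorrelation of
genotypes within patches, genotyping error, null alleles, temporal
structure, or the actual geography of any real study area. Passing
calibration tests on these generators demonstrates that the machinery is
correct and well-calibrated, not that any particular real landscape meets
the model's assumptions.

# Calibration results and problem sizes

The test-suite calibration studies (re-run by `scripts/acceptance.R`) use
problem sizes chosen to exercise the estimators at full statistical
strength while keeping a desk-scale runtime: cost-distance and circuit
oracles on grids up to 12×12 and 400 cells; Mantel type-I calibration with
500 replicates of 30 individuals; resistance-value recovery on 100×100
grids with 50 individuals (within the 48–137 range of the motivating
study), signal slope 1, noise at half the signal standard deviation,
ρ = 0.25, 20 replicates per true value in {10, 100, 500}; multivariate
model recovery on 60×60 landscapes over the full preset hypothesis set with
100 replicates; and MLPE coverage with 200 replicates of 40 individuals.

# Numerical and design choices

* Snapping: individuals are assigned to the cell containing their
  coordinates; cell centres are used when converting back to coordinates.
* Supercover polyline rasterization marks every cell a segment touches
  (corners included), preventing diagonal leaks through one-cell roads.
* Overlapping road classes on one cell keep the largest resistance, with a
  message.
* Disconnected pairs yield infinite effective distance and are flagged;
  optimization skips candidate values that disconnect any pair, with a
  warning.
* ρ is constrained to [0, 0.4999]; the boundary fit ρ = 0 is compared
  explicitly against the interior optimum.
* All pipeline stages derive their seeds from the single configured seed;
  re-running a configuration is byte-identical.

# Limitations

* *Absolute-value saturation.* Once a barrier is expensive enough that all
  least-cost paths avoid it, further increases change cost distances only
  marginally; correlation-based support then plateaus and the plateau rule
  reports the onset, not the generating value. On a 100×100 background-1
  grid the maximum detour is a few hundred cost units, so values ≥500 are
  identifiable only in geometries (such as the gapped-band fixture) where
  re-routing continues across the whole candidate grid. Analyses of real
  landscapes should read optimized values as relative, not absolute.
* *Pairwise pseudo-replication.* AICc on pairs overstates sample size; the
  MLPE correlation absorbs individual-level dependence but weights are
  still sharper than the data warrant. Rankings are robust; absolute
  weights should be read cautiously.
* *Mantel controversies.* Partial Mantel tests are used only to optimize
  univariate surfaces, never to assess model fit or variable importance —
  those questions go to the MLPE/AICc machinery.
* Corridor outputs (least-cost networks, all-to-one current, and their
  divergence layer) are descriptive maps, not inferential statements.
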