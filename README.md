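# hazsense

Sensing dynamic **human activity zones (HAZs)** from mobile-phone GPS
trajectories across policy restriction phases.

During the COVID-19 pandemic, successive restriction regimes (lockdowns,
tiered rules, reopenings) reshaped where and when people were active in
cities. `hazsense` implements an explainable three-part pipeline for
quantifying that reorganisation at the level of small geospatial units
(census output areas, grid cells):

1. **Footfall detection** — stays (stationary episodes) are extracted from
   each user's GPS point sequence and aggregated to a units × days footfall
   matrix; a citywide recovery index tracks daily volume against a
   pre-pandemic benchmark.
2. **HAZ delineation** — within each restriction phase, units are clustered
   by the *shape* of their standardised daily footfall profile into ranked
   activity zones; partitions from different phases are compared with
   Pearson's contingency coefficient.
3. **Urban attribution** — a cross-validated random-forest classifier
   relates zone membership to static urban characteristics (land-use
   acreages, socio-demographic supergroup), reporting accuracy and
   normalised Gini importance.

The intended users are quantitative geographers, spatial epidemiologists and
urban analysts who need a tested, reproducible implementation of this
workflow. Real commercial GPS panels are proprietary, so the package ships a
seeded synthetic generator that plants known stays, temporal archetypes and
feature effects — every stage is validated against ground truth it can
actually know.

## The method

**Stays.** For one user's time-ordered points p_1 … p_m, a stay is a maximal
window p_i … p_j whose members all lie within d_max of the anchor p_i and
whose span t_j − t_i ≥ t_min. Defaults d_max = 50 m, t_min = 300 s (5 min).
Distances are haversine on a 6,371,000 m sphere.

**Footfall matrix.** A is m × t: A[i, j] = number of stays whose centroid
falls in unit i and whose start time falls on day j. The recovery index on
day d is 100 · total(d) / benchmark, with the benchmark the mean citywide
daily total over 2020-01-01 … 2020-02-29 (60 days).

**Standardisation and clustering.** Each row is standardised with its own
mean μ_i and *population* standard deviation σ_i (divisor t):
B[i, j] = (A[i, j] − μ_i) / σ_i. Agglomerative clustering (Ward linkage,
Euclidean distance) is run on rows of B; the cluster count n is chosen by
maximising the mean silhouette over a candidate range; labels are re-indexed
by descending raw mean daily footfall, so HAZ 0 is always the busiest zone.

**Partition agreement.** For two phases' partitions cross-tabulated over
jointly clustered units, C = √(χ² / (χ² + N)) with plain Pearson χ² — C = 0
at independence, C → 1 at strong association.

**Attribution.** Per phase, a random forest classifies zone labels from the
11-column urban design (10 land-use acreages + integer-coded supergroup);
hyper-parameters come from a 15-draw randomised search scored by stratified
10-fold CV. Gini importance I_G(v) sums each feature's impurity decrease
over all splits and trees, normalised so Σ_v I_G(v) = 1.

## Worked example

The numbered drivers under `analysis/` run the demo study — a 3×3 grid of
500 m units, 20 panel users, the packaged eight-phase restriction calendar
(2020-01-01 … 2021-02-27), four planted temporal archetypes:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_footfall.R
Rscript analysis/03_delineate_hazs.R
Rscript analysis/04_compare_phases.R
Rscript analysis/05_urban_association.R
```

Stage 2 prints:

```
detected 8614 stays from 20 users (ledger holds 8614 planted stays)
assigned 8614 stays; 0 fell outside all units
footfall matrix: 9 units x 424 days, 8614 stays total
mean rolling recovery index by phase (% of benchmark):
  Before lockdown                 101.5
  First national lockdown          37.8
  Minimal lockdown restrictions    54.2
  ...
```

Every planted stay is recovered by detection and assigned to its planted
cell (the generator's ledger is an exact oracle), and the recovery index
shows the configured collapse at the first lockdown followed by a partial
rebound. Stage 3 selects the silhouette-optimal zone count per phase; stage
4 prints the pairwise C matrix (adjacent phases agree far above unrelated
random partitions); stage 5 reports CV accuracy and the top-ranked feature
per phase. At this deliberately tiny demo scale (9 units) the attribution
stage is noisy; the frozen 40–60 unit scenarios exercised by the test suite
recover the planted feature cleanly.

The same end-to-end run is available programmatically:

```r
library(hazsense)
manifest <- run_pipeline(demo_config(seed = 1), "out/")
```

Two runs with the same seed produce byte-identical artefact hashes.

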