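---
title: "Delineating human activity zones from GPS footfall: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating human activity zones from GPS footfall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazsense)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices made where
the design was genuinely open.

## 1. The pipeline

Urban activity analysis from commercial GPS panels proceeds in three
stages, each implemented as a tested module:

1. **Stay detection** turns each user's raw point sequence into stationary
   episodes ("stays") — the behavioural unit behind a *footfall*.
2. **Zone delineation** clusters geospatial units by the temporal *shape*
   of their daily footfall within an observation period (a policy
   restriction phase), yielding human activity zones (HAZs).
3. **Attribution** asks how much of the zone structure is explainable from
   static urban characteristics, via a cross-validated classifier.

## 2. Stay detection

A stay is a maximal run of consecutive points that all remain within
`d_max` metres of the run's first point (the anchor) and whose time span is
at least `t_min` seconds. Defaults are `d_max = 50` m and `t_min = 300` s:
five minutes within a 50-metre radius is the standard operating point for
"significant visit" detection from mobile GPS, large enough to absorb
positioning jitter and short enough to catch errands.

Design choices worth recording:

* **Distance semantics.** Stay-detection literature often says "Euclidean
  distance" while supplying raw lon/lat. We use haversine on a sphere of
  radius 6,371,000 m as the default; at the 50 m scales relevant here the
  difference from a projected Euclidean distance is far below GPS noise. A
  planar (equirectangular) option is exposed for comparison, and the test
  suite checks both give identical stay sets on typical walks.
* **Anchor-based windows.** The threshold is applied between the window's
  *first* point and each candidate member, not between consecutive points.
  A consecutive-pair reading would chain slow drifts into arbitrarily long
  "stays"; the anchor reading bounds a stay's spatial extent by
  construction.
* **Failed windows advance by one point, not to the violation index** —
  otherwise a stay beginning inside a failed window would be skipped. The
  correctness of the full scan is established by equivalence with an
  exhaustive-window oracle (all `[i, j]` windows enumerated, maximal
  non-overlapping selection) on hundreds of randomised short trajectories.
* **Boundary inclusivity.** "At least `t_min`" is implemented as
  `>= t_min`, so the documented five-minute default reads literally.
* **Recording gaps.** No maximum-gap rule is applied inside a candidate
  stay; daily aggregation makes long-gap stays rare and harmless, and a
  rule here would add a parameter the downstream analysis cannot check.

## 3. Footfall aggregation and the recovery index

Stays are assigned to the unit containing their centroid. Containment uses
a crossing-number ray cast whose fixed edge convention places a centroid
lying exactly on a shared cell edge in exactly one unit — no stay is ever
double-counted between neighbours (this is asserted directly in tests).
The footfall matrix `A` counts stays per unit per calendar day; a stay
spanning midnight counts wholly on its start date (the simplest
deterministic attribution; no splitting rule is defensible at daily
resolution). Footfall counts *stays*, not unique users — two visits are
two footfalls — with a `unique_users` flag for the alternative reading.

The recovery index expresses each day's citywide total as a percentage of
the mean daily total over a benchmark window (default
2020-01-01 … 2020-02-29, 60 days of pre-pandemic behaviour). A trailing
7-day rolling mean (shorter at the series head) removes the weekly cycle.
The index is scale-invariant: panel size cancels.

## 4. Zone delineation

Within an observation period, each unit's daily series is standardised by
its own mean and **population** standard deviation (divisor `t`). This
makes clustering compare profile *shape*, not volume — a quiet suburb with
a strong weekday rhythm should cluster with a busy one. Constant
(zero-variance) rows have no defined shape and are excluded with the
sentinel label `-1` rather than imputed; at desk scales this mostly
affects all-zero units inside quiet phases.

Clustering is agglomerative with Euclidean distance on the standardised
rows. The linkage criterion was an open choice; **Ward** (`hclust`'s
`ward.D2`, the variance-minimising form correct for Euclidean distances)
is the default because it produces the variance-homogeneous, similarly
sized clusters the zone interpretation assumes; average and complete
linkage are exposed. The cluster count is selected by maximising the mean
silhouette over candidates `n = 2 … min(15, m' − 1)` (the upper default
comfortably brackets the 5–8 zones typical of city-scale runs), with ties
broken toward the smaller count. Silhouette is computed on the
standardised matrix with full pairwise distances — the same space the
clustering sees. Everything here is deterministic: repeated runs give
identical partitions.

Zone labels are then ranked by the raw mean daily footfall of member units
(label 0 = busiest). Ranking permutes labels only; membership is untouched
(tested via ARI = 1 against the unranked cut). Per-phase delineation
re-standardises within each phase slice, so a phase's zones reflect only
that phase's dynamics; consequently labels are per-partition ranks with no
cross-phase identity, and cross-phase comparison goes through the
contingency coefficient instead.

## 5. Comparing partitions across phases

Two partitions are compared by cross-tabulating jointly clustered units
(sentinel-labelled units dropped pairwise — the statistic is defined only
on units labelled in both) and computing Pearson's contingency coefficient
`C = sqrt(chi2 / (chi2 + N))` with the uncorrected chi-square. No
continuity correction is applied and no significance testing is done: `C`
is used descriptively, and small expected counts raise a warning rather
than a correction. `C` is invariant to relabelling of either partition,
zero exactly at independence, and bounded below 1.

## 6. Urban attribution

The design matrix has one row per clustered unit and 11 columns: ten
land-use acreage values and the socio-demographic supergroup
**integer-coded as a single column**. One-hot encoding would be more
orthodox for a nominal variable, but it would split the supergroup's
importance across eight columns and change the importance decomposition;
preserving the 11-column design keeps one importance value per named urban
characteristic. The flag-free default is therefore integer coding, with
the caveat documented here.

Hyper-parameter search is a **randomised search with 15 draws** over tree
count, features-per-split and minimum node size — "grid search with 15
iterations" is ambiguous, and 15 sampled configurations is the reading
that matches the iteration count; each draw is scored by stratified
k-fold CV accuracy (k = 10 by default, reduced with a warning when the
rarest class is smaller than k) on a fold assignment shared across draws.
The reported accuracy is the best configuration's mean CV accuracy,
labelled as such. Gini importance is the forest's accumulated impurity
decrease per feature, normalised to sum to exactly 1 — the invariant the
acceptance script recomputes.

Calibration properties, both tested: under label permutation the CV
accuracy concentrates at the majority-class rate (within 3 Monte-Carlo
standard errors at n = 40), and a planted mean shift of 3 noise-SD units
on one land-use column ranks that column first in importance.

## 7. What the synthetic generator emulates — and what it does not

Real commercial GPS panels are proprietary, so the generator creates data
carrying exactly the statistical structure the pipeline assumes:

* **Units** are a rectangular grid of 500 m cells laid out in a local
  metric frame and converted to WGS84, keeping nominal cell sizes
  consistent with haversine distances at London latitudes.
* **Temporal archetypes** (busy-weekday, busy-weekend, flat, recovering)
  drive per-unit-day expected stay counts:
  `lambda = base_rate × weekday/weekend multiplier × phase multiplier`,
  with Poisson counts — the simplest count model consistent with footfall
  as an aggregated count.
* **Trajectories** plant each stay as 5 points jittered within 20 m of a
  centre (strictly inside one cell) over 10 minutes; consecutive stays of
  a user are separated by transit points placed ≥ 1 km outside the grid
  and ≥ 300 m apart. Because jitter (≤ 40 m between members) is strictly
  under `d_max` and transit spacing strictly over it, the planted-stay
  ledger is an *exact* oracle: detection recovers every planted stay and
  nothing else, which the tests assert stay-for-stay.
* **Feature tables** give designated land-use columns archetype-dependent
  means; all other columns and the supergroup are archetype-independent
  noise, so attribution can only succeed through the planted effect.

Deliberately not emulated: road networks and realistic routing, home/work
anchoring, GPS outages and multipath noise, population density gradients,
device churn, and spatial contiguity of zones. Passing tests therefore
show the pipeline's inferential machinery is correct under its own
assumptions — not that those assumptions hold in any particular
commercial panel.

## 8. Study conditions and problem sizes

The packaged restriction calendar holds eight phases (2020-01-01 …
2021-02-27) with the published day counts attached as metadata. Two of the
published numbers disagree with date arithmetic — the final phase prints
51 days where its dates span 53, and the total prints 422 where the span
is 424. The dates are authoritative here; the printed counts are retained
as `days_printed` and not silently corrected.

Frozen scenario scales, chosen once as realistic desk-scale analogues:

* **Demo pipeline**: 3×3 grid, 20 users, 424 days, archetype base rates
  2–6 stays/unit/day (a 20-user panel sees a few stays per unit-day);
  ~60,000 points, ~8,600 stays; runs end-to-end in well under a minute.
* **Clustering scenarios**: 40 units / 8 weeks for the clean two-archetype
  case; 60 units / 424 days at base rates 150/90/40/60 stays/unit/day for
  the four-archetype case. The latter rates sit at the busy end of
  realistic per-unit volumes, where daily Poisson noise is 8–16% of
  level — "moderate" relative to the archetype shapes. At volumes an
  order of magnitude lower the weekday/weekend axis still separates
  cleanly but the flat and recovering archetypes blur into the noise and
  the silhouette favours coarser partitions; users analysing quiet areas
  should expect fewer, broader zones.
* **Attribution scenarios**: 40 units, two archetypes, effect size 3 on
  one of ten land-use columns at noise SD 0.5.

## 9. Known limitations

* Footfall counts visits to a unit; it carries no origin–destination or
  flow information between units.
* Daily resolution only: commuting peaks and other sub-daily structure are
  invisible by design.
* Zones are non-contiguous by construction; no spatial constraint is
  applied in clustering.
* The contingency coefficient's upper bound depends on table dimensions;
  values are comparable across pairs of similar partition sizes, which is
  how they are used here.
* Integer-coding the supergroup imposes an artificial ordering; the
  random forest is insensitive to monotone recodings but not to the
  implied adjacency. The one-hot alternative changes the importance
  decomposition, as discussed above.
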