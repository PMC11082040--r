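---
title: "Methods: canopy-height-model inventories and their accuracy assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy-height-model inventories and their accuracy assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standscan)
```

`standscan` implements a complete workflow for turning drone-photogrammetry
canopy height models (CHMs) into spatially explicit tree lists and for
assessing those lists against stem-mapped ground truth: individual-tree
detection, height–diameter allometry with prediction-bound filtering,
greedy tree matching with per-class detection rates, stand summaries, and
individuals/clumps/openings (ICO) spatial structure statistics. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic stand generator does and does not emulate.

## Tree detection from a canopy height model

A CHM is a 0.10 m grid of canopy height above ground (`chm`), built from a
height-normalized point cloud by point-to-raster gridding: each cell takes
the maximum point height falling in it (`chm_from_points()`), and cells
without points read as ground (0 m). No smoothing or pit-filling is applied;
at photogrammetric densities of thousands of points per square meter, empty
cells are negligible, and on sparser synthetic clouds the zeros are
deliberate rather than interpolated.

Treetops are variable-window local maxima (`detect_treetops()`). A cell is a
treetop if and only if its value is at least the inventory threshold
(1.37 m, breast height) and at least every other cell value within Euclidean
distance

\[ r = 0.2 \times h \]

of its center, where \(h\) is the focal cell's height in meters
(`variable_window_radius()`). Numerical choices, made where the procedure is
otherwise underdetermined:

* the window is a **circle in world distance**, not a square of pixels — the
  radius is stated in meters, so pixel geometry should not change the result
  with resolution;
* comparisons use `>=`, so flat apexes (common on rendered or saturated
  surfaces) pass; a connected plateau of equal passing cells yields a single
  treetop at its smallest `(row, col)` in scan order, which makes results
  reproducible;
* short trees whose window radius is smaller than the cell spacing are not
  pruned by neighbor comparisons — the circular window is honored exactly at
  any resolution (the coarse-grid degenerate case matters for testing; at
  0.10 m cells the window always spans several cells).

Crown segments come from a marker-controlled watershed: region growing from
the treetop markers over the inverted CHM, restricted to cells at or above
the crown threshold (default 1.37 m), via `EBImage::propagate()`
(`segment_crowns()`). Crown area is labeled-cell count times cell area.
Canopy cover is either the fraction of CHM cells at or above the threshold
(`canopy_cover_from_chm()`, the detected-side definition) or the dissolved
union of per-tree crown disks rasterized at the CHM grain
(`dissolved_crown_cover()`, the stem-map-side definition). Dissolving by
rasterization rather than exact polygon union keeps the two cover
definitions on the same 0.10 m lattice.

## Diameter estimation

Breast-height diameters are extracted by circle fitting in the 1.32–1.42 m
slice of the normalized cloud (`extract_dbh()`): slice points within 1.0 m
of the detected stem are flattened to the plane and fit with an algebraic
(Kåsa) least-squares circle refined by Gauss–Newton on geometric distance
(`fit_circle_ls()`); `dbh_cm = 200 * radius_m`. Photogrammetric slices are
full of branch returns, so three config-exposed quality gates decide whether
a fit is usable: at least 10 points, radial scatter `rms/radius <= 0.25`,
and fitted radius no larger than the search radius. Dense clutter fails the
scatter or radius gate; the residual failure mode — sparse clutter that
happens to trace a credible arc — is exactly what the next stage removes.

Extracted height–DBH pairs are filtered against the two-sided 90%
prediction bounds of a **regional** height–diameter model
(`filter_pairs_by_bounds()`). The regional model is a power law

\[ \mathrm{DBH_{cm}} = \beta_1 h^{\beta_2} \]

supplied as configuration (`power_model()`: coefficients, residual SE,
sample size, optional parameter covariance) because the inventory data
behind such models are typically not redistributable; tests use a synthetic
regional regime with residual SE 6.2 cm. Prediction intervals are t-based
with the delta-method variance by default — fitted value \(\pm\)
\(t_{(1+L)/2,\,n-2}\sqrt{\sigma^2 + g^\top \Sigma g}\) with \(g\) the
parameter gradient — and a Monte-Carlo propagation variant
(`method = "monte_carlo"`) is provided and cross-checked against the delta
method in the tests; the deterministic default keeps runs reproducible.

Surviving pairs feed a site power model (`fit_power_model()`: Gauss–Newton
from the log–log initialization, relative-change tolerance `1e-8`, at most
200 iterations, damped to keep \(\beta_1 > 0\)), which imputes DBH for all
remaining trees (`impute_missing_dbh()`, `dbh_origin = "predicted"`);
extracted values are never overwritten, so imputation is idempotent. The
defaults \(\beta_1 = 4.29\), \(\beta_2 = 0.68\), residual SD 1.20 cm are the
mean site-level values reported for treated ponderosa pine stands and keep
the synthetic data in that regime. When fewer than five pairs survive
filtering, the regional model itself imputes (`estimate_dbh()` logs the
extraction rate).

## Matching and error assessment

`match_trees()` matches detected trees to stem-mapped trees greedily:
detected trees in descending height order each claim the unmatched field
tree within 4.0 m whose height differs by less than 2.0 m, choosing the
smallest height error (ties: smaller distance, then smaller id). Tall-first
processing and the tie-breaks are declared choices — the procedure is
order-dependent in principle, so `order = "input"`/`"height_asc"` exist as
diagnostics. Unmatched detected trees are false positives, leftover field
trees false negatives; the counts always conserve
(`TP + FP =` detected trees, `TP + FN = ` field trees).

Rates are summarized per dominance class — understory below 5 m,
intermediate 5–15 m (inclusive at both ends), overstory above 15 m — with
true positives and false negatives classed by *field* height and false
positives by *detected* height, which is the only side that exists for a
spurious tree. The F-score is the harmonic mean of precision and recall and
0 when there are no true positives. Height and DBH errors are
detected-minus-field, summarized as mean error and RMSE per 5-m field-height
class with half-open lower-inclusive bins starting at 0
(`error_summary()`).

Two consequences of the 2-m height gate are worth knowing when reading
results: measured height ME/RMSE are computed on *matched pairs only*, so
heavy-tailed height noise is truncated and the reported RMSE undershoots the
generating noise; and additive height bias can push trees near the 5-m
boundary across classes, which slightly dilutes per-class rate recovery.
Both effects are visible in the package's own acceptance run and are
properties of the protocol, not bugs.

## Stand metrics and the paired-plot statistics

`stand_summary()` reports TPH, TPH of trees above 5 m, basal area
\(\sum \pi (\mathrm{dbh}/200)^2 / \mathrm{area}\), and QMD
\(\sqrt{\sum d^2 / n}\); `qmd_from_ba_tph()` inverts the identity
\(\mathrm{QMD} = 200\sqrt{\mathrm{BA}/(\pi\,\mathrm{TPH})}\).
`compare_stand_tables()` computes paired-plot error statistics with one
declared sign convention — error = detected − stem map — and averages
percent errors **per plot** (mean of ratios, not ratio of means); that
convention is what reproduces the published summary statistics of the
packaged 11-plot comparison table (`stand_comparison()`) and is applied
uniformly. The packaged table's own column mean of stem-map TPH is 279;
the accompanying narrative average of 332 does not equal any column
statistic of the table, so the package reports only fixture-derived values.

## Individuals, clumps, and openings

Clumps are maximal sets of trees chained by stem-to-stem distance at most
6 m — the spacing at which ~3 m crown radii can interlock
(`assign_clumps()`). DBSCAN with a neighborhood count of 2 reduces exactly
to connected components of the distance graph, which is how it is computed
(via `igraph`); clump ids are numbered by smallest member id for
determinism. Size classes follow the printed bounds: individual, 2–4, 5–9,
10–15, >15. Per clump, `clump_metrics()` reports percent of stand basal
area, height coefficient of variation (sample SD over mean, clumps of two
or more), and dissolved crown area; class summaries give the mean and SD of
the per-clump values, since both per-clump and per-plot aggregations are
defensible and the per-plot mean is the default reporting unit.

`opening_distribution()` evaluates the distance from every 1.0-m grid cell
center to the nearest stem and bins the plot area into 3-m bands. The top
band is open-ended `[12, Inf)` — the result table is shaped for an
open-ended final class, and an empty plot puts all mass there.

Stem-map and detected distributions are compared by one-way ANOVA per
metric and class (`one_way_anova()`, classical between/within F), with
Bonferroni adjustment `min(1, k p)` (`bonferroni_adjust()`) where `k` is
the number of class-level comparisons in the metric family: 5 for clump
counts, basal-area percent, crown area, and openings; 4 for height CV,
which has no individual class. The cap at 1 is adopted because adjusted
p-values are probabilities. Zero within-group variance with unequal means
is reported as a flagged `p = 0` boundary rather than an error.

## The synthetic stand generator

Because no stem-map or photogrammetric data ship with the package,
`generate_stem_map()` builds 1-ha stands under four treatment archetypes:

* **SGR** (small-group retention): few parents with many offspring
  (Thomas-type cluster process) for grouped large trees, plus dense sapling
  patches — high horizontal and vertical heterogeneity;
* **CT** (commercial thinning): hard-core inhibition at 4.9 m minimum
  spacing (dart throwing with rejection, capped at 10^4 attempts per tree),
  no understory — low heterogeneity;
* **FS-On / FS-Off** (free selection): clustered overstory with more
  (FS-On) or less (FS-Off) understory.

Cluster parents are drawn in a 3-SD buffered region so edge clusters spill
in and the realized density stays unbiased; heights are lognormal per
stratum, truncated at the 1.37 m inventory threshold (understory capped
below 5 m). Archetype densities are loosely calibrated to the 159–658 TPH
range of the packaged comparison table; they are *not* claimed to reproduce
any specific plot, because the published material gives treatment targets,
not spatial-process parameters.

`render_chm()` gives each tree a generalized-paraboloid crown
\(h(r) = H (1 - (r/R)^{p})\), \(p = 2\) by default; the stem cell carries
the exact apex height. This is sufficient for local-maximum detection but
is deliberately not a radiometric or photogrammetric simulation: real SfM
surfaces have pits, occlusion, and reconstruction noise that the generator
does not model, so perfect detection on well-separated synthetic stands
demonstrates correctness of the algorithm, not expected field performance.
`simulate_breast_height_slice()` places stem-circle points with radial
Gaussian noise plus uniform in-crown clutter; real slices have structured
(branch-shaped) clutter, so the clutter-rejection results are likewise a
lower bound on the difficulty of real extraction.

`perturb_to_uas()` converts a truth stand into a detector-like tree list:
per-class deletion (false negatives), positional and height jitter, and
spurious trees. Its `fp_rate_by_class` parameter is the *target measured*
false-positive rate FP/(TP+FP) — spurious counts are drawn with expectation
\(n_{\text{surv}}\, p/(1-p)\) — so generated rates can be recovered by the
matching stage and checked. Defaults are calibrated once to the error
structure reported for drone inventories of treated ponderosa pine: 61.4%
understory false positives, detection improving monotonically with height,
+0.36 m height bias with ~1.3 m total RMSE (noise SD 1.27 m), and
false-negative/false-positive rates that average near 16.8%/29.5% on a
mixed stand. Ingrowth (new 1.37–2.0 m trees at a configurable density)
emulates the multi-year lag between a field campaign and a flight.

Rate-recovery experiments in the tests and acceptance script use *sparse*
stands (1000–1200 trees on 400 m × 400 m): in a dense 1-ha stand a spurious
tree frequently falls within the 4 m/2 m gates of a deleted truth tree and
is matched to it, so measured rates drift below the generating ones — the
offsetting-error behavior known for this protocol. Sparse geometry isolates
the bookkeeping being tested.

## Problem sizes and runtime choices

The test suite verifies each stage against an independent oracle at sizes
chosen to make brute force exact and fast: 50 random rendered CHMs
(30 × 30 cells) against a per-cell local-maximum scan plus perfect recovery
on a well-separated 64-tree hectare; 500 random matching configurations
against a step-by-step greedy replay; 500 random plots against union-find
connected components; 100-seed power-model recovery at n = 500 pairs
(bias in \(\hat\beta_2\) below 0.02); prediction-interval coverage over
10^4 fresh draws (90% ± 2%); exhaustive per-grid-point opening
distributions; 2000-replicate null calibration of the ANOVA (type-I error
0.05 ± 0.01); and 30-seed end-to-end rate recovery on the sparse stand. The
full pipeline on a 1-ha stand (10^6-cell CHM) runs in well under a minute;
`run_pipeline()` writes every artifact plus a manifest, and identical
configurations reproduce byte-identical CSV/JSON outputs.

## Known limitations

* Flat terrain: clouds are assumed height-normalized; there is no ground
  model.
* The crown model is rotationally symmetric; real crowns are not, and
  watershed crown areas inherit CHM artifacts.
* The regional height–diameter model must be supplied; the package ships no
  inventory data.
* ANOVA comparisons at the plot level have whatever power n plots provide;
  with a single synthetic plot the plot-level metrics are reported as
  incomparable rather than tested.
* Greedy matching is the assessment protocol, not an optimal assignment;
  an optimal matcher would give different (never smaller) TP counts.
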