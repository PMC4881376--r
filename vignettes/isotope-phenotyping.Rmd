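---
title: "Isotope phenotyping of single cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope phenotyping of single cells: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isophene)
```

## The problem

Multi-isotope stable isotope probing (SIP) incubations amend an
environmental sample with several isotopically enriched substrates at
once — here ¹³C-acetate, ¹⁵N-ammonium and ³³S-sulfate in a sulfur-cycling
biofilm. NanoSIMS then counts seven secondary-ion masses in parallel
(¹²C⁻, ¹³C⁻, ¹⁴N¹²C⁻, ¹⁵N¹²C⁻, ³²S⁻, ³³S⁻, ³⁴S⁻) over 30 × 30 µm raster
areas, giving per-cell isotope enrichment for every cell-sized region of
interest (ROI). Because cross-feeding spreads label through the community
at different rates, the per-cell ratios form gradients rather than a
binary enriched/unenriched signal. `isophene` exploits those gradients:
it clusters cells by their joint isotope and elemental ratio profile into
*isotope phenotypes*, with no taxonomic input, and only afterwards
compares the phenotypes with FISH-derived taxon labels.

## From ion images to ratios

**Dead time.** Pulse-counting detectors are blind for a dead time τ after
each registered ion, so measured counts underestimate true arrivals. With
per-pixel rate r = counts/dwell, the corrected count is
counts / (1 − r·τ). The correction is applied per plane (it is
rate-based, and planes differ in rate), is strictly increasing in the
measured counts, and reduces to the identity at τ = 0. τ is not a
published constant of the study; the default 44 ns is a typical
electron-multiplier dead time and is configurable
(`dead_time_correct(stack, tau = )`).

**Alignment and accumulation.** Stage drift between planes is estimated
as an integer-pixel translation of each plane relative to plane 1 of the
¹⁴N¹²C⁻ biomass channel — the channel with the most structure — by
maximizing the normalized cross-correlation over the overlap, searched in
±`max_shift` (default 10 px). Sub-pixel alignment is deliberately not
attempted: interpolation would redistribute integer counts and distort
Poisson statistics. Accumulation sums the de-drifted planes over the
common overlap of all planes; pixels outside it are NA and excluded
downstream. With zero shifts, accumulation conserves counts exactly.

**ROIs.** In the emulated workflow ROIs are hand-drawn on the ¹⁴N¹²C⁻
image; `extract_rois_auto()` provides an automated stand-in: Otsu
threshold on the accumulated biomass image, 8-connected components,
discard of components below `min_area_px` (default 20 px), labels in
raster-scan order. These defaults are design choices, not study
parameters, and are overridable; supplied masks take precedence.

**Ratios.** All ratios are computed from ROI-*summed* accumulated counts,
never from per-pixel ratio averages (ratios of sums are far better
behaved at low counts): r13C = ¹³C/¹²C, r15N = ¹⁵N¹²C/¹⁴N¹²C,
r33S = ³³S/³²S, r34S = ³⁴S/³²S, rC_CN = (¹²C+¹³C)/(¹⁴N¹²C+¹⁵N¹²C),
rS_CN = (³²S+³³S+³⁴S)/(¹⁴N¹²C+¹⁵N¹²C). A row with a zero denominator is
dropped, with a message, rather than zero-filled: a cell with no CN
signal is not a cell measurement. Instrumental fractionation is corrected
multiplicatively against a standard of independently known composition
(measured mean × true/measured); by default only the C and N isotope
ratios are corrected — a sulfur correction is typically impossible when
the standard is sulfur-poor, and at the atom-percent enrichments of SIP
experiments the permil-scale sulfur correction is immaterial. Both
corrected and uncorrected paths are supported and flagged
(`attr(ratios, "corrected")`).

**Reference ratios.** δ-conversions use VPDB (0.0112372) for carbon and
AIR (0.0036765) for nitrogen; these reproduce the spore calibration
standard's printed (δ¹³C = −21.86‰, R = 0.01099) and (δ¹⁵N = 7.94‰,
R = 0.00371) pairs at the printed precision. VCDT values are included for
sulfur. Atom fractions use the two-isotope approximation F = R/(1+R)
throughout, including ³³S (³⁴S/³⁶S neglected in the ³³S atom fraction),
matching single-ratio usage in labeling calculations.

## Clustering and validation

The five labeling-sensitive ratios (r13C, r15N, r33S, rC_CN, rS_CN) are
the default feature space; r34S carries no label in a ¹³C/¹⁵N/³³S
experiment. Features are z-scored by default — the five ratios span an
order of magnitude, and without scaling the carbon ratios dominate every
Euclidean distance; the raw-space option is retained for sensitivity
checks.

Ten algorithms are implemented from scratch and validated against
independent references in the test suite: k-means (Lloyd iterations,
k-means++ seeding, empty clusters re-seeded with the farthest point,
best of 20 restarts by WSS), fuzzy c-means (Bezdek alternating updates,
m = 2, tol = 1e−6 on max |Δu|, max 500 iterations, best of 20 random
starts by the objective J; the m = 2 inner loop is compiled), PAM
(BUILD + best-improvement SWAP), and the seven Lance–Williams linkages
d(ij,k) = αᵢd(i,k) + αⱼd(j,k) + βd(i,j) + γ|d(i,k) − d(j,k)| with the
standard coefficient table. Centroid, median and Ward operate on squared
Euclidean distances (Ward.D2-equivalent merge order) with heights
reported on the distance scale. Merge and assignment ties everywhere go
to the lowest index; randomness enters only through explicit seeds.

Cluster number and method are selected by scanning k = 2..10 for each
method and scoring the hardened partition with the Calinski–Harabasz
index; fuzzy solutions are hardened by arg-max membership (CH is defined
for partitions, and published per-solution CH values are single numbers).
Grid cells whose hardened partition has an empty cluster are recorded as
invalid and excluded from the arg-max; ties prefer smaller k, then the
fixed method order. Silhouette widths, s(i) = (b−a)/max(a,b) with s = 0
for singletons, complement CH for the chosen solution.

## Canonical phenotype labels

Cluster indices from any single run are arbitrary. To make labels
reproducible and comparable across runs and feature subsets, cluster
centers are matched one-to-one to named *archetype* centers — by default
the published 7-day per-cluster mean ratios (components a–e) — minimizing
the total squared distance in the standardized feature space. The
assignment is solved exactly (dynamic programming over column subsets,
equivalent to the Hungarian algorithm; brute-force-verified over all 5!
permutations in the tests). Cross-solution consistency counting
(`compare_ratio_subsets()`) canonicalizes every subset solution against
the archetypes restricted to that subset's columns before comparing
labels; without such alignment, cross-solution agreement is meaningless.
The published ratio-subset menu includes a carbon+sulfur block whose
"C/S" entry is not one of the six ratio columns; it is represented here
by the two elemental ratios C/CN and S/CN (their quotient is C/S).

Phenotype summary tables report, per canonical cluster, n and the mean
and sample sd (n−1 denominator) of each ratio, plus an "All" column —
the layout of the study's per-condition summary. FISH cross-tabulations
count ROIs by (taxon × cluster), with unmatched ROIs under `unknown`.

## The synthetic generator

`generate_ratio_table()` draws each phenotype component as an independent
diagonal Gaussian in 6-dimensional ratio space, with means, sds and sizes
taken verbatim from the published per-condition cluster summaries
(presets: 2-day 665 ROIs, 7-day 777, 10-day 760, unlabeled control 645,
killed control 268; 2202 across the three labeled time points, 3115 in
total). Values below a floor of 1e−6 are resampled, not clipped —
clipping would pile a point mass on the floor and distort cluster shapes.
Resampling makes each marginal a left-truncated normal; for components
whose mean is within ~1 sd of zero (e.g. the r15N of the least-enriched
component) this shifts the effective mean upward by up to a few tenths of
a sd, and the tests account for it analytically. The published summaries
do not include the ³⁴S/³²S ratio; the generator assumes natural-abundance
³⁴S (mean 0.0442 ≈ VCDT, sd 0.002) in every component. Per-component
taxon mixes default to the published FISH correspondences (a/b/c ≈
86/98/92% gammaproteobacteria; d 85% gamma, 15% unidentified; e 68%
delta, 32% unidentified).

`generate_count_table()` inverts the ratio definitions exactly — given a
total CN count, it solves for the seven channel expectations that
reproduce a row's six ratios, then draws independent Poisson counts. With
the expectations themselves (`poisson = FALSE`), `compute_ratios()`
returns the inputs to machine precision; with Poisson noise at CN = 10⁶,
¹³C/¹²C is recovered within 4 counting-statistics sigma for ≥99% of ROIs.
`generate_ion_scene()` builds full image stacks: cells placed without
overlap (filaments as thick segments, cocci as disks, rods as short
segments), per-pixel channel rates from each cell's expectations spread
uniformly over its area plus a natural-abundance background, independent
Poisson planes, optional integer per-plane drift, with ground-truth mask
and taxon tables returned.

**What the generator does not emulate:** within-cell heterogeneity
(sulfur granules, storage inclusions), correlations between ratios within
a component (only per-ratio sds are published, so covariances are
unknowable from the summaries), non-Gaussian tails, detector effects
beyond dead time (QSA, relative sensitivity factors), and FISH optics.
Passing recovery tests on this generator therefore demonstrates that the
pipeline arithmetic and the clustering machinery are correct under the
published summary statistics — not that clustering would resolve any
particular real sample.

## What the recovery experiment shows — including where it fails

The headline desk-scale experiment simulates the 7-day condition
(components a–e, sizes 443/136/106/32/60) and asks whether fuzzy c-means
(k = 5, m = 2, z-scored, 20 restarts) recovers the generating component
means after canonicalization. Reported coordinates are the per-cluster
member means in raw ratio space — the same construction as the published
summary tables, so like is compared with like; the membership-weighted
fuzzy centroids are also available (`coef(fit)`) and differ by a few
percent where components overlap.

The well-separated coordinates are recovered faithfully: the
deltaproteobacteria-like component's ¹⁵N/¹⁴N (≈0.10) and ³³S/³²S (≈0.22–0.24
vs 0.2229), and the acetate-incorporating component's ¹³C/¹²C (≈0.29–0.31
vs 0.2687).

Two coordinates are *not* recovered, and this is a property of the
objective, not an implementation defect: under diagonal Gaussians at the
published parameters, the global optimum of the m = 2 fuzzy c-means
objective **splits the dominant component a (n = 443) into two clusters
and merges components b (n = 136) and d (n = 32)**, which differ mainly
in C/CN and S/CN but overlap heavily given their large published sds
(C/CN sd 0.20 and 0.24). The split-a solution has a genuinely lower
objective J than the ground-truth-like partition (verified independently:
`e1071::cmeans` converges to the same J; on several seeds the truth-like
configuration is not even a fixed point). Consequently the recovered "d"
S/CN coordinate sits near 0.18 (generating value 0.3125) and "b" C/CN
near 0.48 (generating 0.7612), and the CH scan across ten seeds selects
k = 4, not 5. k-means, whose hard assignments do not let a large cluster
absorb objective mass from its neighbors, recovers all five components at
the same parameters (≈95% label agreement, CH ≈ 650 vs ≈ 460). Two
readings: first, m = 2 fuzzy c-means trades a small overlapping component
against splitting a dominant one — worth checking with a k-means
cross-fit in any application; second, a diagonal-Gaussian resample of
published summary statistics lacks whatever correlation structure
separated those components in the real measurements. The affected
acceptance checks are left failing by design rather than tuned around.

## Numerical choices and limitations

* Tolerances: FCM tol 1e−6 (max |Δu|), max 500 iterations; k-means runs
  to assignment fixpoint (max 100 Lloyd iterations); PAM swaps to a local
  optimum with best-improvement steps.
* Degenerate inputs: constant feature columns are dropped with a warning
  (all-constant is an error); a point coincident with an FCM center gets
  membership 1 there; empty k-means clusters are re-seeded with the
  farthest point; singleton clusters have silhouette 0 and sd reported
  as 0 with a warning.
* Problem sizes: the test suite and the acceptance script run at the
  study's own scale (n = 777 ROIs, k ≤ 10, 20 restarts, ten seeds for the
  scan) in well under a minute each; oracle-equivalence checks use ≤12
  points where exhaustive enumeration is exact.
* 32-bit TIFF storage holds integer counts up to 2³¹ − 1 exactly;
  dead-time-corrected (real-valued) stacks live in memory and are not
  round-tripped through TIFF.
* The CLI (`inst/cli/isophene`) is a thin wrapper; the R functions are
  the primary interface.
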