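---
title: "Methods: 3D morphometry of placental villous trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of placental villous trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the measurement
model, the statistical procedures and their assumptions, the synthetic
data generator and what it does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The measurement model

The unit of analysis is one isolated peripheral villous tree per
placenta, traced as a 3D centerline skeleton with a local diameter at
every center point. Tracing starts at the proximal cut end (the root)
and proceeds distally; the biologically defined ends of the structure
are the free terminal tips.

**Branches and nodes.** A branch connects two branching nodes, or a node
and a terminal end. In the skeleton this means: points with two or more
children are nodes, points with one child are interior centerline
samples, points with no child are terminal ends. The root is the start
of tracing, not a biological end, so it never counts as a terminal end;
a root point with several children is rejected at ingest because a
traced stem starts as a single branch. Coincident consecutive points —
which hand tracing can produce — are merged with a warning rather than
rejected.

**Terminal distance ordering.** Branches are classified by their
distance, in nodes, to the nearest terminal end reachable distally:
terminal branches are bT0, directly preterminal branches bT1, and in
general `order(b) = 1 + min(order of children of b)`. The minimum (not
maximum or path-specific) rule means a long interior chain whose every
node also bears a terminal twig stays at bT1 throughout. Orders of 3 and
higher are measured and retained in the output tables, but the group
statistics use bT0–bT2 only, because peripheral trees are shallow and
higher orders are sparse.

**Per-branch measurements.**

* *Length*: the summed Euclidean length of the centerline polyline.
* *Planar branching angle*: the change of direction of a branch relative
  to the branch at the next higher order. A branch's direction is the
  chord from its proximal to its distal endpoint; the angle is the angle
  between the child's and the parent's chords, in degrees in [0, 180],
  with 0 meaning continuation without direction change. It is computed
  in the plane the two chords span, which is the only plane the two
  directions define; nothing is projected onto an external plane. The
  root branch has no previous branch, so its angle is undefined and is
  reported as missing, never imputed. A configuration with local
  tangents at the node instead of endpoint chords was considered and
  rejected: tangents are sensitive to the sampling density of the
  tracing, whereas chords are stable and match a direction "derived from
  the endpoint".
* *Tortuosity*: centerline path length divided by the straight-line
  distance between that branch's own endpoints. A straight branch has
  tortuosity exactly 1; the measure is scale-free and at least 1 by the
  triangle inequality.
* *Surface area and volume*: the villus between consecutive center
  points is modelled as a conical frustum with end radii `diameter/2`.
  Volumes are `pi h/3 (r1^2 + r1 r2 + r2^2)` summed along the branch;
  surfaces sum the lateral areas `pi (r1 + r2) sqrt(h^2 + (r1 - r2)^2)`.
  End caps are excluded: they are internal cross-sections of a
  continuous villus, and excluding them makes the measures invariant
  under inserting collinear midpoints with interpolated diameters
  (verified to 1e-9 relative error in the tests).

**Aggregation.** For each specimen and order k in {0, 1, 2}, the
per-branch values are averaged with equal weights into `mpa_bTk`,
`mt_bTk`, `ml_bTk`, `msa_bTk`, `mv_bTk` — one value per placenta, the
exchangeable unit for all group statistics. A mean is missing when no
branch of that order exists (small trees often lack bT2), and `mpa` can
be missing while the other means are defined when the only branch of an
order is the root. Missing values are dropped test-wise, never imputed.
Several trees of one specimen, if present, are pooled before averaging.

## Subgrouping by preterminal tortuosity

Clinically normal placentas are split at specimen mean bT1 tortuosity
1.2: above is `HT-normal` (high tortuosity), below `LT-normal`. The
cutoff is a tunable parameter (`threshold`, dimensionless, default 1.2)
separating two observed regimes. Values exactly at the threshold go to
LT with a warning, because the high group is defined by strictly
exceeding the cutoff. The pipeline then runs both the two-group
comparison (IUGR vs all normals) and the three-group comparison (IUGR,
HT-normal, LT-normal) from the same per-specimen table.

## Statistical procedures

**Rank-based comparisons.** The omnibus test is the Kruskal–Wallis H
with midranks and the standard tie correction; the default p-value uses
the chi-square approximation with `groups - 1` degrees of freedom.
Pairwise contrasts use Dunn's z on the joint ranks,
`z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1)))(1/n_i + 1/n_j))`
with `T = sum(t^3 - t)` over tie groups, with Bonferroni adjustment over
the pairs by default (Holm and unadjusted are available; both raw and
adjusted p-values are reported so either convention can be compared).
Stars follow `* p < 0.05, ** p < 0.01, *** p < 0.001`, computed from
adjusted p-values. All tests are two-sided.

Both tests also offer `p_method = "permutation"`, a seeded Monte-Carlo
label-permutation p-value. At the cohort sizes typical here (14–50 per
group) the chi-square and normal approximations are adequate, but for
small per-group n (below about 8) the chi-square p deviates from the
exact permutation null by more than typical Monte-Carlo error, so the
permutation option is the better choice there; the test suite validates
it against exact full enumeration of all label assignments at n = 12.

**Angular analysis.** Terminal branching angles (one mean per placenta)
are summarized per group three ways. Rose histograms use 10-degree
sectors by default (display only). Mode locations come from a wrapped
Gaussian kernel density (period 360 degrees) evaluated on a 1-degree
grid over [0, 180]; binning alone cannot resolve modes to 1 degree,
which is why mode detection is kernel-based. The bandwidth (degrees,
default 4) is the smoothing scale: maxima closer together than one
bandwidth are merged into the higher one. Unimodality is tested with
Hartigan's dip statistic — the minimum over unimodal distribution
functions of the maximum absolute distance to the empirical CDF — with
a Monte-Carlo p-value: the fraction of `n_boot` (default 10000, minimum
1000) seeded uniform samples of the same size whose dip reaches the
observed one. The dip is scale- and shift-free, so the uniform null
covers any continuous unimodal reference.

**The dip computation.** The dip is computed exactly, not by table
lookup or approximation. The computation enumerates candidate mode
placements: at every distinct sample value (where the unimodal class
allows an atom) and inside every gap between consecutive values, where
the mode position is optimized — feasibility is jointly convex in the
mode position and the band half-width, so a ternary search on the
position inside a bisection on the half-width solves each configuration.
Per side, a band of half-width d is feasible exactly when the greatest
convex minorant of the upper constraints dominates the lower constraints
(mirrored for the concave side), and the two sides must join at the
mode: the minimal extrapolated left limit there may not exceed the band
ceiling nor the maximal achievable start of the concave side. The
implementation is compiled (Rcpp) and is validated in the test suite
against an independent linear-programming oracle that fits explicit
piecewise-linear unimodal CDFs, plus closed-form anchors: a balanced
two-spike sample attains the maximal dip 0.25, equally spaced samples
attain the minimal dip 1/(2n), and a constant sample has dip 0 by
convention.

**Two-group t.** The pooled-variance Student t (Welch optional)
complements the rank tests for two-group comparisons. Zero-variance
degeneracies follow the conventions: identical constant samples give
p = 1, separated constant samples give the limit p = 0 and are flagged.

## The synthetic cohort generator

No tracing data are deposited with the study this package's analysis
flow follows, so the generator is the package's test bed: it produces
SWC cohorts whose statistical structure matches what the analysis
assumes, with recorded ground truth per branch. The defaults encode the
study conditions: 40 IUGR and 50 clinically normal specimens, the
normals being 14 high-tortuosity and 36 low-tortuosity (the manifest
labels both simply "normal"; rediscovering the split is part of the
analysis). Terminal-angle mixture components sit at 58 and 76 degrees
(IUGR), 52 and 64 (LT-normal) and a single 67 (HT-normal); bT1
tortuosity is truncated-normal below the 1.2 cutoff for IUGR and
LT-normal (mean 1.08, sd 0.04) and above it for HT-normal (mean 1.28,
sd 0.05); HT-normal branches at bT1 are 40% longer and all its branches
10% thicker, reproducing the direction (not the unpublished magnitudes)
of the high-tortuosity subgroup's larger length, surface and volume.

Choices the source conditions do not fix, made once as field-realistic
conventions: angle component standard deviation 6 degrees (so cohort
rose diagrams resolve two maxima 12 degrees apart); branch lengths
truncated-normal with means 60/80/100 um for bT0/bT1/bT2+ and sd 15 um;
diameters around 50 um with a mild proximal thickening and a 5% linear
taper within each branch; terminal-end counts shifted-Poisson with mean
12, giving trees of roughly 20–40 branches like a traced peripheral
bush.

**Mixtures act at the specimen level.** Each placenta is assigned one
angle-mixture component, and its branch angles scatter around that
component's mean. This is deliberate: the bimodality to be detected is
in the distribution of per-placenta mean angles, and a branch-level
mixture would average out within each placenta into a unimodal
distribution of means. It reflects the interpretation that a placenta
as a whole is in one architectural state.

**Geometric realization.** Topology is drawn first: strictly dichotomous
splits, with probability `prob_no_bT2` (0.45 for IUGR, 0.22 for normals,
the observed fractions of trees lacking bT2) of a caterpillar topology
in which every internal node keeps a terminal child — exactly the shapes
with no bT2 branch. Orders are then known combinatorially before any
geometry exists. Each branch is realized as a 9-point polyline whose
chord equals the prescribed direction exactly — child chords are placed
at the drawn branching angle from the parent chord with uniform azimuth,
so measured angles reproduce the draws to floating-point accuracy — and
whose tortuosity is met by superposing a sinusoidal perturbation
orthogonal to the chord, its amplitude solved by bisection on the
measured polyline length (relative tolerance 1e-12 on the chord scale; a
target of 1 returns the exactly collinear chain). Cohorts are
reproducible byte for byte: a master seed draws one sub-seed per
specimen, so extending a cohort does not reshuffle existing specimens.

**What the generator does not emulate** — and hence what passing
recovery tests does and does not show. Real tracings carry correlated
measurement noise (focus-plane depth error compresses z), diameter
estimation bias, occasional tracing mistakes (loops, skipped branches),
within-placenta heterogeneity across villous trees, and covariation
between angle, tortuosity and size that the generator draws
independently. Recovery of generator parameters therefore validates the
measurement and inference machinery — ordering, geometry, aggregation,
subgrouping, tests — not the biological fidelity of any particular
parameter value. Space-filling realism (villi avoiding each other) is
also not modelled; the metrics used are intrinsic to each branch and do
not depend on embedding validity.

## Numerical choices and degenerate inputs

* Angles use `acos` of the clamped normalized inner product; chords of
  zero length (coincident branch endpoints) raise a degenerate-geometry
  error naming the branch rather than returning NaN.
* Tortuosity of a collinear chain evaluates to exactly 1 because the
  path length and chord length are computed from identical segment sums.
* The dip bisection tolerance is 1e-10 on the statistic; test
  comparisons against the LP oracle use 5e-4, dominated by the oracle's
  mode-position grid.
* Fully tied samples give H = 0 and p = 1 (no evidence against the
  null, rather than 0/0).
* Report JSON is written without timestamps; reruns with identical
  inputs and configuration are byte-identical, and input SWC digests are
  recorded in the provenance block.

## Problem sizes used in the validation suite

The bundled tests size their simulations to validate each claim with an
independent oracle at small scale: the ordering oracle runs 200 random
trees of up to ~50 branches; the rank-test oracle enumerates all 34650
label assignments at n = 12; the dip oracle battery covers 140 samples
of n <= 8 plus clustered and tied designs up to n = 16 during
development; cohort recovery runs the full default cohort (90 specimens,
~3000 branches). The dip test inside pipeline validation uses the
minimum permitted 1000 null draws; production analyses should keep the
10000 default.

## Known limitations

* Only the most peripheral, isolated part of the villous tree is in
  scope — stem and anchoring villi are not traceable this way, and no
  attempt is made to extrapolate whole-organ quantities.
* The planar angle depends on branch chords, so very tortuous branches
  can have chords that underrepresent their local direction at the node.
* The dip test's Monte-Carlo null is the uniform distribution; for
  heavily tied data (not expected for per-placenta means) the p-value
  is conservative.
* The HT/LT split is a hard threshold; specimens near 1.2 flip groups
  under small measurement perturbations, which is inherent to the
  design being replicated, not to this implementation.
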