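---
title: "Methods: tracer connectomics with tracemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer connectomics with tracemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracemap)
```

`tracemap` packages the computational stages of a quantitative
neuroanatomical tracing study: extracting tracer injection sites from
section images, demarcating anatomical domain boundaries from
domain-labeled tracer signal, partitioning injection-by-target annotation
matrices into connectivity communities, and comparing reconstructed neuron
morphologies. Every stage has a seeded synthetic-data generator with
machine-readable ground truth, so the whole pipeline is testable without
any imaging archive. This vignette explains the models, their assumptions,
the tunable parameters, and the numerical choices made where the design
was open.

## Injection-site extraction

Tracer injection sites appear in section images as saturated, irregular
blobs surrounded by high-intensity background that carries no connectivity
information. The extraction pipeline has three stages.

**Wavelet background suppression.** The image is decomposed to five levels
with a separable 2D discrete wavelet transform; detail bands at levels
1–3 (fine scales, where fiber-like texture lives) are removed, diagonal
details with large magnitude at the remaining levels are amplified (a
compact bright blob projects strongly onto coarse diagonal bands),
small-magnitude horizontal/vertical details are dampened, and the level-5
low-pass band is dampened and Gaussian-smoothed. Magnitude thresholds are
quantile-based (`diag_large_quantile = 0.9`, `hv_small_quantile = 0.5`),
which makes the schedule invariant to exposure scaling; gains default to
2.0 / 0.5 / 0.5 and are configurable in `band_modification()`.

The default wavelet is the symmetric biorthogonal CDF 5/3 transform,
implemented by lifting and therefore exactly invertible (round-trip error
is at floating-point precision). Linear phase matters here: orthogonal
Daubechies filters are minimum-phase, and once detail bands are zeroed
their group delay translates image structures diagonally by several
pixels per decomposition level — enough to corrupt a centroid estimate.
Orthogonal `haar`, `db2`, and `db4` banks remain available for
applications that modify nothing. Images whose sides are not multiples of
`2^levels` are symmetric-reflection padded and cropped after
reconstruction, so perfect reconstruction holds for every size.

**Locally adaptive contrast enhancement.** Intensities are min-max
normalized, then mapped through `T(f, c) = (pi^2/4) f^c`, the first-order
small-angle form of `sin^2((pi/2) f^p)` with `c = 2p`. The exponent is
spatially adaptive: `c = c1 (f_g + eps)/((1 - f_g) + eps) + c2`, where
`f_g` is the Gaussian-smoothed image. Bright neighborhoods therefore get a
large exponent, crushing the moderately bright halo around the saturated
core, while dim regions keep a mild exponent. The expansion around the
local mean adds `(f/f_g) dT/dc (f - f_g)` with `dT/dc = (pi^2/4) f^c ln f`
(defined as 0 at `f = 0`). Defaults `c1 = 1`, `c2 = 1` keep the exponent
at least 1 everywhere (an exponent below 1 would brighten background);
`gauss_sigma = 10` px sets the neighborhood scale. The output is
renormalized against its 99.5th-percentile intensity and clipped rather
than min-max scaled: a handful of extreme enhanced values inside the
saturated core would otherwise compress the usable dynamic range.
A note on the small-angle regime: the Taylor step `sin(u) ~ u` errs by
`u^2/6`, i.e. under 2% wherever `f^p <= 0.2`; the squared mappings
consequently agree to `u^2/3`, under 3.5% on that region.

**MSER blob extraction.** The enhanced image is quantized to 8 bits and
bright extremal regions are swept: at each threshold the 8-connected
component containing the global intensity maximum is tracked (the seed is
located on a lightly smoothed copy, so saturation ties cannot land it on a
stray bright pixel). Stability at threshold `t` is the relative area
change across `t ± delta` (default `delta = 5`); thresholds within `delta`
of the quantization ends are excluded, since a clipped plateau would look
spuriously stable there. Among local minima of the instability curve whose
areas fall within `[min_area, max_area_frac * image area]` (defaults 50 px
and 25%), the largest-area region is returned — the full blob rather than
its saturated core, which forms a second, nested stable region. Blob
pixels are then intersected with a co-registered labeled atlas raster to
report per-region overlap fractions; the primary region is the modal one,
with lexicographic tie-breaking for determinism.

The synthetic section generator renders the blob as a randomly oriented,
smoothed superellipse (exponent 2–2.6, so the area stays within ~10% of a
disk of the nominal radius) with a near-saturated core, multiplicative
speckle, bright fiber streaks, and Gaussian noise over a constant
background. It emulates saturation and irregular shape; it does not
emulate registration error, tissue tearing, or spectral bleed-through, so
passing recovery tests speak to segmentation robustness, not to
registration quality.

## Domain-boundary demarcation

Anatomical domains (medial, lateral, caudal) of a nucleus are demarcated
per atlas level from domain-labeled tracer-signal coordinates. The
training set for a level pools the segmented foreground pixels of all
sections registered to it, each point inheriting its section's domain
label.

An ensemble of RBF-kernel soft-margin SVMs is trained over the
power-of-two grids `C in 2^(-2..5)`, `gamma in 2^(-5..2)` — 64 members.
The grid extents are a design choice (only "powers of two" and the member
count are fixed by convention); coordinates are z-score standardized per
level first, so the gamma grid covers sensible kernel widths regardless of
pixel scale. Each member's weight is its mean held-out accuracy over 10
independent repetitions of stratified 3-fold cross-validation (30 held-out
folds); fold assignment deals each class round-robin after shuffling, so
every fold's class counts are within one of proportional. Prediction is
the accuracy-weighted vote, with ties resolved by the fixed class order
medial < lateral < caudal. Levels are processed independently — no
smoothing across adjacent atlas levels — and the output stays
raster-valued.

The synthetic generator draws three truncated anisotropic Gaussian clouds
(y-spread 0.8 of x-spread) inside a deterministic nucleus-shaped polygon
that deforms smoothly with the level index. When an overlap fraction is
requested, all spreads are rescaled by one global factor solved
numerically (deterministic fixed-seed pilot sample) so that the expected
fraction of points lying nearer a foreign domain center matches the
request; the ground-truth surface is the argmax of the class densities,
i.e. the Bayes rule of the generative model. Pixelwise agreement between
the dense ensemble classification and that surface is the benchmark
statistic; with three domains, ~10% overlap and 500 points per domain
across seven levels, the ensemble typically agrees with the ground truth
on 96–98% of mask pixels (`demarcation_benchmark()` reproduces this; the
reproduction script in `scripts/` runs exactly that study). Whether such agreement is
measured pixelwise or per-domain is a reporting choice; the package
reports pixelwise agreement plus a full confusion table.

## Connectivity communities

Annotation matrices hold one row per injection (pixel density for
anterograde tracers, cell counts for retrograde) and one column per
target — a 175 × 175 px atlas grid cell or a named ROI. Entries below the
minimum annotation thresholds (0.0045 for anterograde density, 8 for
retrograde cell counts) are removed; comparison is "at or above keeps".
Rows are then rescaled so every injection's total labeling equals the
maximum injection total (zero rows are left alone with a warning); the
maximum row is returned bit-for-bit unchanged.

The rectangular matrix is cast as a weighted bipartite graph over
injections and targets, and Newman modularity is maximized with the
Louvain algorithm at resolution 1.0. The igraph implementation is
deterministic in vertex order, so run-to-run variability is restored by
shuffling the vertex order per run from the root seed; 100 runs are
summarized by consensus: the co-assignment matrix is thresholded at
`tau = 0.5`, re-partitioned, and iterated until all runs agree. Consensus
of identical partitions returns immediately, making the operation
idempotent.

Downstream summaries follow standard practice: matrix reordering sorts
rows and columns by community and then by within-community strength, so
grouped injections and their strongest targets fall along the diagonal;
community color coding assigns each segmented pixel's grid cell to the
injection (within the cell's community) with the largest annotation value
at that cell — a rule applied globally, including when a community holds
several injections; stacked-bar summaries give each injection's labeling
fraction per atlas level with the two most-labeled ROIs named per level;
connection strengths are binned into tertiles (strong/moderate/weak, ties
at a boundary going to the stronger bin); and repeated-injection
projection vectors are L1-normalized and clustered agglomeratively under
the cosine distance (average linkage by default — the linkage is a
configurable choice).

## Neuron morphometry

Reconstructions use SWC semantics: a rooted tree of 3D nodes with radii,
soma nodes typed 1. Analyses restrict to neurites near the soma by
trimming: walking root-outward, a branch is cut at the first node whose
Euclidean distance from the soma center exceeds the radius (default 300,
unit-free in the morphology's native units — the choice of a numeric
default rather than a physical unit is deliberate, since slice geometry
makes nanometer readings of such radii implausible), and everything
distal, including re-entrant stretches, is removed.

Sampling aliasing is regularized with LOESS: every non-endpoint,
non-bifurcation vertex is replaced by a locally quadratic fit per
coordinate against arc length, over the five vertices before and after it
along its branch, with tricube weights on rank distance; shrinking windows
are used near branch ends, and endpoints and bifurcations are excluded
from filtering, which leaves topology and branch anchor points
bit-identical. Collinear evenly spaced branches are fixed points of the
filter.

Sholl profiles come in two forms. The classic profile counts exact
segment-sphere crossings (quadratic roots within each segment, so a
segment dipping in and out of a shell contributes twice; tangencies count
zero). The surface-area profile assigns each segment's frustum lateral
area to the bin of its midpoint's path distance divided by the neuron's
maximum path distance; bin sums conserve total membrane area to 1e-9.

Morphometric features follow common (L-Measure-style) conventions, since
the feature names alone do not fix formulas: tortuosity is the mean branch
path/chord ratio; partition asymmetry averages `|L - R|/(L + R - 2)` over
bifurcations (0 when both subtrees are single tips); Rall's ratio averages
`(r1^1.5 + r2^1.5)/r0^1.5`; the fractal dimension is a box-count slope
over six dyadic scales on the densely resampled polyline; branch
generation is the maximum number of bifurcations crossed from root to tip.
Soma features model the type-1 contour as an ellipsoid (volume from the
semi-axis extents, surface via the Thomsen approximation, sphericity
`pi^(1/3) (6V)^(2/3) / A`, skewness as coordinate-wise third standardized
moments of the contour nodes). Group comparison uses z-scored PCA
(constant features dropped with a warning) and two-sided pairwise Wilcoxon
rank-sum tests — exact p for small untied samples, normal approximation
with continuity correction otherwise, Hodges–Lehmann shift estimates with
confidence intervals — with Benjamini–Hochberg adjustment applied jointly
across the whole feature-by-pair family.

Topology is compared through persistence: the dendritic tree is filtered
by path distance from the soma and decomposed into branches with the elder
rule (at each merge the branch from the farther tip survives), giving one
(birth, death) point per leaf with birth ≥ death under this
distal-to-proximal orientation. Diagrams are compared with the order-1
Wasserstein distance under the L∞ ground metric, diagonal projection
allowed at cost `|birth - death|/2`; the optimal matching is solved
exactly by an O(n³) assignment algorithm, which handles the diagram sizes
that trimmed reconstructions produce (tens of points) in well under a
second.

The synthetic neuron generator grows branches as von Mises–Fisher
persistent random walks. The concentration parameter is calibrated
against the target mean branch tortuosity with a deterministic
vectorized pilot simulation whose branch lengths follow the same Gamma
law as generation (tortuosity is convex in branch length, so a
fixed-length pilot would bias low); a target of exactly 1 produces
perfectly straight branches. The calibration is accurate to a few percent
over the realistic dendritic range (up to ~1.3) and degrades for extreme
targets, where the path/chord ratio becomes heavy-tailed. Branching
approximates a Poisson process along the cable: after each segment of
mean length `mean_branch_len`, a line bifurcates with probability
`bifurcation_rate × mean_branch_len` and otherwise keeps elongating, with
termination only at `max_extent` or the branch-order cap (default 12) —
dendritic arbors fill their target field rather than dying at random
branch points, and this choice also keeps cohort bifurcation counts
concentrated rather than extinction-dominated. Two further realism bounds
apply: a root-to-tip line whose cable exceeds 1.5 × tortuosity ×
`max_extent` is terminated as pathologically wandering, and the whole
arbor is capped at 20,000 nodes (finite total cable). All lines advance
in lockstep, one vectorized vMF draw per growth step.

## Problem sizes and reproducibility

All generators and analyses are bit-reproducible under a fixed seed
(`withr::local_seed` scopes every random draw; derived seeds stay below
2^31). The test suite exercises the study-scale configurations directly:
seven synthetic atlas levels with 500 points per domain for the
demarcation benchmark, 20 seeded section images for injection-site
recovery, 100-run Louvain consensus on 15 × 120 planted matrices, and 50
replicate two-cohort simulations (10 neurons per group) for the
morphometric power check, with 30 null replicates for false-positive
control. Tie-breaking rules (class order in the ensemble vote,
lexicographic region names, stronger-bin tertile boundaries) are fixed so
that every result is deterministic given the data.

Known limitations: no section-to-atlas registration (the atlas raster is
assumed co-registered); boundary maps stay raster-valued (no contour
vectorization); the tortuosity calibration is validated for dendritic
ranges only; and the synthetic generators emulate the statistical
structure of tracing data, not its full histological variability — results
on real archives depend additionally on registration and artifact
filtering quality, which are out of scope here.
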