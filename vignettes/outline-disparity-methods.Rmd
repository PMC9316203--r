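---
title: "Outline morphometrics and morphospace disparity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics and morphospace disparity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stylomorph)
```

## The analysis in one paragraph

stylomorph quantifies shape variation in the larval head capsule and
piercing stylets of owllion larvae (the clade comprising antlion- and
owlfly-type larvae) and compares morphological disparity across time
slices: extant specimens against Cretaceous, Eocene and Miocene amber
fossils. Each specimen is a single closed outline of head capsule plus
stylets. Outlines are standardized (stylet straightened, half mirrored,
resampled), converted to elliptic Fourier coefficients, normalized to
remove size, rotation, translation and starting point, and embedded in a
PCA morphospace. Group disparity is measured as occupied *size* (sum of
variances of the scores) and *position* (average displacement relative
to the morphospace origin), with bootstrap and rarefaction to correct
for strongly unequal sample sizes, and differences are tested by
PERMANOVA and bootstrapped, Bonferroni-corrected pairwise resampling
tests.

Because no machine-readable outlines of real specimens are distributed
with the package, a parametric generator produces labelled synthetic
head+stylet outlines with controllable group structure; every stage of
the pipeline is exercised and validated on that synthetic material.

## Elliptic Fourier analysis

A closed contour traversed once with arc-length parameter $t \in [0,T]$
is expanded as

$$x(t) = A_0 + \sum_{n=1}^{H} a_n \cos\tfrac{2\pi n t}{T} + b_n \sin\tfrac{2\pi n t}{T},
\qquad
y(t) = C_0 + \sum_{n=1}^{H} c_n \cos\tfrac{2\pi n t}{T} + d_n \sin\tfrac{2\pi n t}{T}.$$

For a polygonal contour the velocities are piecewise constant, so all
coefficients have exact closed forms (the classical piecewise-linear
result); `compute_efa()` evaluates those sums directly, with no FFT and
no truncation assumptions. An aliasing guard refuses more harmonics than
half the number of contour points. The closed form is verified in the
test suite against dense trapezoid quadrature of the defining integrals
(an independent oracle that integrates the coordinate functions
themselves) to better than $10^{-8}$ on random polygons.

One consequence of the arc-length parameterization is worth noting: an
ellipse is a *pure* first harmonic only under its trigonometric
parameterization. Under arc length the first harmonic still dominates
overwhelmingly (fraction $> 0.99$ of harmonic power for a 2:1 ellipse),
but higher harmonics are not exactly zero and $a_1$ is not exactly the
semi-axis. Tests assert the dominant-harmonic property, not spurious
exactness.

### Normalization

`efa_normalize()` applies the standard first-harmonic procedure: the
parameter is phase-shifted so $t = 0$ sits at the first-harmonic
ellipse's semi-major axis, the shape is rotated so that axis lies along
$+x$, and all coefficients are divided by the semi-major axis length
(kept as `size_scalar`). After normalization $a_1 = 1$,
$b_1 = c_1 = 0$, and the half-angle phase formula's major/minor
ambiguity is resolved by picking the candidate with the larger
first-harmonic amplitude at $t=0$.

The remaining $180^\circ$ ambiguity (phase $\theta$ vs $\theta+\pi$)
deserves a remark. Working through the algebra, that switch leaves every
odd harmonic — including the entire first harmonic, and with it $d_1$ —
unchanged, and flips the sign of every even-harmonic coefficient. A
tie-break based on $d_1$ therefore cannot discriminate; stylomorph
instead canonicalizes by making the first even-harmonic coefficient
with magnitude above $10^{-7}$ positive. This is deterministic and
similarity-invariant so long as that coefficient is bounded away from
zero, which holds for all head+stylet shapes (their strong fore–aft
asymmetry makes $a_2$ large). Invariance of the full normalized
coefficient vector under random translation, rotation, scaling and
starting-point shifts is verified to $10^{-6}$ over 1000 cases.

For bilaterally symmetric outlines the canonical frame puts the midline
along $x$, making $x(t)$ even and $y(t)$ odd: all $b_n$ and $c_n$
vanish. This is used as a property test of both the generator (its
noise-free outlines are exactly symmetric) and the normalization.

### Defaults

Twenty harmonics are retained (`n_harmonics = 20`). On generated head
outlines the median cumulative harmonic power at 20 harmonics exceeds
0.999, so higher harmonics carry essentially digitization noise; the
setting is recorded in every output manifest. The analysis vector drops
the constants fixed by normalization ($a_1, b_1, c_1$) and keeps $d_1$,
giving $4H - 3 = 77$ columns. $d_1$ is retained deliberately: only
three coefficients are pinned by the normalization, and the signed
first-harmonic aspect ratio is real shape information. Excluding it is
possible upstream by dropping the column, and a sensitivity check is a
one-liner on the assembled matrix.

## Outline standardization

Specimens are drawn as the better-accessible half and mirrored, after
the stylet is artificially straightened — so the pipeline implements the
same standardization for arbitrary input halves:

* `straighten_stylet()` rigidly rotates the stylet sub-polyline about
  the innermost *proximal* landmark (the articulation end) until the
  proximal-to-distal landmark segment is parallel to the
  anterior–posterior midline, distal end anterior. Rotating about the
  proximal landmark preserves head-capsule geometry exactly; the
  rotation is an isometry of the stylet, so its arc length and internal
  distances are untouched. Landmark auto-detection
  (`detect_stylet_landmarks()`) is provided for canonical halves, but
  explicit indices always win; ties break toward the more distal point.
* `mirror_half()` reflects across the midline, drops the duplicated
  midline endpoints, enforces counterclockwise orientation and refuses
  reflections that self-intersect (naming the first crossing segment
  pair).
* `resample_equal_arclength()` produces `m` points (default 512)
  starting at the anterior pole — the midline intersection with the
  largest $y$ — so the starting point is consistent across specimens
  and the phase normalization in the Fourier step is a no-op check
  rather than a load-bearing correction. The resampler iterates the
  equal-arc pass to its equal-chord fixed point: once consecutive
  spacing is uniform another pass lands on the same vertices, which
  makes the operation idempotent (to $10^{-6}$) instead of only
  approximately so for cornered contours. Degenerate (zero-perimeter)
  input and `m < 64` are refused.

## The synthetic generator

`generate_outline()` builds one half analytically and mirrors it, so
every noise-free outline is exactly bilaterally symmetric, closed,
simple and counterclockwise:

* head capsule: a superellipse lateral margin joined to a posterior rim
  modelled as a circular arc whose signed sagitta is
  `posterior_rim_curvature * head_width` — negative values indent the
  rim (concave), positive bulge it posteriorly (convex);
* stylets: tapered blades around a quadratic Bézier centerline rising
  from the anterior rim, width `stylet_thickness * head_width` at the
  base tapering to a sharp tip, length `stylet_rel_length *
  head_length`, optional outward curvature and cosmetic inner-margin
  teeth. Head and stylets form one closed contour, because the
  harmonic analysis requires a single closed curve (and the source
  drawings digitized them as one object).

Invalid parameter combinations (e.g. stylets too thick for the head
width, or a contour that self-intersects after mirroring) raise errors
naming the offending parameters; `generate_dataset()` redraws such
specimens up to a retry cap of 100.

Noise is applied to the *shape parameters* (mean + Gaussian dispersion
per group), not per vertex, so the mapping from truth to shape stays
well-posed; a small per-vertex jitter flag exists for robustness
experiments only. Each group consumes its own RNG stream
(`seed + seed_offset`), so a group's specimens do not depend on which
other groups are generated.

### The study-shaped design

`study_group_specs()` encodes the study conditions: 243 extant, 46
Cretaceous, 9 Miocene and 2 Eocene specimens (300 in total), with group
structure expressed through exactly three shape factors — posterior-rim
concavity, relative stylet length, stylet thickness. The extant group
has twice the dispersion of the fossil groups (the extant fauna
occupies the largest morphospace) and the Cretaceous group is offset
toward thicker stylets, the factor that surfaces as the
thickness-associated PC.

The dispersion magnitudes and the Cretaceous offset were fixed once by
a small pilot simulation before the main build, with three goals: the
mean-eigenvalue rule should return three effective components (the
fourth eigenvalue sits near 0.7% of variance against a 1.3% cut), the
extant group should exceed the Cretaceous group in sum of variances,
and the coarse fossil-vs-extant size and position tests should reach
corrected $p < 0.01$. Validation over ten independent seeds satisfied
all three in every replicate; the values were then frozen.

What the generator does *not* emulate: antennae and palps (small and
very slender in these larvae, and plausibly excluded from drawn
outlines), stemmata protrusions, digitization noise correlated along
the outline, preservation artefacts of amber fossils, and any
allometric or ontogenetic structure. Passing tests therefore show that
the *pipeline* recovers known structure from shapes of this kind — not
that real owllion larvae have any particular disparity pattern.

## Morphospace

PCA is computed on the centered, unstandardized coefficient matrix
(covariance PCA — coefficients share units, and standardizing would
inflate noise harmonics). Loadings have a reproducible sign convention
(largest-magnitude entry positive). The effective dimensionality is the
number of eigenvalues strictly above the mean eigenvalue — the
classical Kaiser–Guttman-style rule used by SHAPE-family tooling; a
cumulative-90% alternative is available by config. If the rule returns
0 (all eigenvalues equal) the pipeline falls back to two components
with a warning. `shape_along_pc()` renders mean $\pm k$ SD shapes along
a component by inverting the flattening and reconstructing the outline,
which is how the PC interpretations (rim concavity, stylet length,
stylet thickness) are read off.

`variance_report()` handles one reporting subtlety: published
per-component percentages are independently rounded, so their sum can
legitimately differ from a published cumulative total. Printed
proportions of 72.4, 17.9 and 3.4 percent sum to 93.7 against a stated
total of 93.8 — the formatter flags agreement within 0.15 percentage
points as within-rounding, and never asserts equality.

## Disparity and tests

* **Sum of variances** (occupied size): sum of per-column sample
  variances ($n-1$ denominator, matching `var()` and the dispRity
  convention) over the effective components; equals the trace of the
  group covariance matrix and is translation-invariant.
* **Average displacement** (position): mean over members of (distance
  from the morphospace origin) / (distance from the group centroid).
  Deliberately *not* translation-invariant — it measures where a group
  sits. Members exactly at the centroid are excluded with a warning;
  an all-coincident group is an error.
* **Bootstrap/rarefaction**: each replicate resamples `rarefy_to` rows
  with replacement (default: the smallest group size with $n \ge 3$)
  and recomputes the metric; 1000 replicates by default, percentile 95%
  intervals. Rarefaction below 3 is refused (the metrics are unstable),
  and groups with $n < 3$ — the Eocene slice, $n = 2$ — are reported
  but flagged `too_small` rather than silently bootstrapped.
* **PERMANOVA**: one-way pseudo-$F$ on Euclidean distances of the
  effective-component scores, free permutation of labels, default 9999
  permutations; when the number of distinct label arrangements is
  smaller, the null is enumerated exhaustively and the p-value is
  exact. Sampled p-values use $(1 + \#\{F^* \ge F\})/(1 + N)$ and can
  never be zero.
* **Pairwise size/position tests**: for each pair of sufficiently large
  groups, the observed statistic is the absolute disparity difference;
  the null pools the pair and draws two bootstrap samples rarefied to
  the smaller group's $n$ — exchangeable under the null of no
  difference, the dispRity-style construction. Bonferroni correction
  multiplies by the number of pairs tested within a metric family. Two
  grouping schemes ship: coarse fossil-vs-extant (the headline
  comparison) and per-slice.

## Numerical choices and degenerate inputs

* Orientation: clockwise input outlines are silently reversed (noted in
  provenance); zero-area or under-3-point outlines are errors.
* Simplicity testing is exact segment-pair intersection with a
  bounding-box prefilter; touching or overlapping collinear segments
  count as crossings.
* Chain-code export quantizes to a grid (default 1/1024 of the
  perimeter) and is documented as lossy; round-trip error is bounded by
  about one grid unit. XY CSV and TPS round-trip to $10^{-9}$.
* All stochastic stages take explicit seeds; the pipeline derives
  per-stage seeds from the run seed, and identical config + seed yields
  byte-identical output files.

## Problem sizes in the shipped tests

The test suite exercises the full 300-specimen design at 256 contour
points and 20 harmonics; the replicate study behind the recovery checks
uses 100 independent seeds, the PERMANOVA type-I calibration 1000 null
datasets of two 10-member groups at 999 permutations, and the
coefficient oracle 100 random polygons against $10^6$-step quadrature.
These sizes were chosen so the whole suite completes comfortably on a
single CPU while keeping Monte-Carlo error well below the decision
margins.

## Known limitations

* Open curves, wavelet or semilandmark alternatives, between-group PCA
  and phylogenetic corrections are out of scope.
* The average-displacement origin is the grand mean of the analyzed
  sample; adding or removing specimens moves the origin, so position
  metrics are comparable only within one embedding.
* The equal-chord fixed-point resampler slightly smooths sub-chord
  detail at near-cusp features (stylet tips); at the default 512 points
  this is far below the harmonic truncation error.
* With $n = 2$ (Eocene) no disparity metric is stable; the group is
  carried through descriptively and excluded from pairwise testing.
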