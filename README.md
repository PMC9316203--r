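# stylomorph

Outline morphometrics and morphospace disparity for stylet-bearing
insect larvae.

Larvae of the owllion clade (antlion- and owlfly-type lacewings) carry
a distinctive head capsule with a pair of piercing stylets. Comparing
how the *shape* of that head+stylet complex is distributed across time
— Cretaceous, Eocene and Miocene amber fossils against the extant
fauna — asks for quantitative outline morphometrics: how large a region
of shape space does each fauna occupy, and does that region sit
somewhere different? stylomorph is an R package for exactly this
workflow, aimed at morphometricians and palaeoentomologists working
with digitized closed outlines.

## The method

Each specimen is one closed outline (head capsule and stylets as a
single curve). The pipeline:

1. **Standardization** — straighten the stylet by rotating it about its
   proximal (articulation) landmark until the landmark axis parallels
   the anterior–posterior midline; mirror the drawn half into a full
   bilaterally symmetric outline; resample at `m` equal-spaced points
   starting from the anterior pole.
2. **Elliptic Fourier analysis** — expand the contour
   (x(t), y(t)) over arc length t as
   `x(t) = A0 + Σ aₙ cos(2πnt/T) + bₙ sin(2πnt/T)` (likewise c, d for
   y), with exact closed-form coefficients for polygonal contours, and
   normalize to the first harmonic so translation, rotation, scale and
   starting point drop out. H = 20 harmonics, giving 4H − 3 = 77 shape
   coefficients per specimen.
3. **Morphospace** — covariance PCA of the coefficient matrix; the
   effective dimensionality is the number of eigenvalues above the mean
   eigenvalue; shapes along each PC are rendered by inverse Fourier
   reconstruction.
4. **Disparity** — per group, occupied *size* = sum of variances of the
   effective-PC scores (the covariance trace) and *position* = average
   displacement, the mean ratio of each member's distance from the
   morphospace origin to its distance from the group centroid; both
   bootstrapped with rarefaction to a common sample size.
5. **Inference** — one-way PERMANOVA (pseudo-F on Euclidean distances,
   permutation null, exhaustive when feasible) and bootstrapped,
   Bonferroni-corrected pairwise disparity tests with a pooled
   exchangeable null.

Because hand-drawn outlines of real specimens are not shipped, a
parametric generator (`generate_outline()`, `generate_dataset()`)
produces labelled synthetic head+stylet outlines whose group structure
mimics the study design: 243 extant / 46 Cretaceous / 9 Miocene /
2 Eocene, three dominant shape factors (posterior-rim concavity,
relative stylet length, stylet thickness), extant dispersion twice the
fossil dispersion, and a Cretaceous offset toward thicker stylets.

## Worked example

```r
library(stylomorph)
cfg <- pipeline_config(groups = study_group_specs(), n_points = 256,
                       n_harmonics = 20, seed = 1)
res <- run_pipeline(cfg)
print(res)
```

```
<morphospace> 300 specimens, 77 components, effective k = 3
  explained variance: PC1 65.8%, PC2 18.8%, PC3 13.8%, PC4 0.7%, PC5 0.3%
  components 65.8% + 18.8% + 13.8% sum to cumulative 98.4%; stated total 98.5% (within rounding, discrepancy 0.10 pp)
<permanova> pseudo-F = 9.877 (df 1, 298), p = 0.0002 (sampled, 9999 arrangements)
<pairwise_tests> metric=sum_of_variances, 1 pair(s), Bonferroni x1
 group_a group_b           metric observed_diff p_raw p_bonferroni n_resamples
  extant  fossil sum_of_variances   0.003456799 0.001        0.001         999
<pairwise_tests> metric=average_displacement, 1 pair(s), Bonferroni x1
 group_a group_b               metric observed_diff p_raw p_bonferroni
  extant  fossil average_displacement     0.4164924 0.001        0.001
```

Reading this: the coefficient morphospace has three effective principal
components (eigenvalue above the mean eigenvalue); the extant group
occupies a much larger region than the fossil pool (sum-of-variances
difference 0.0035, corrected p = 0.001 against the pooled bootstrap
null) and the two pools sit in significantly different positions
(PERMANOVA pseudo-F = 9.9, p = 0.0002; average-displacement difference
0.42, corrected p = 0.001). Per-group disparity with bootstrap CIs and
rarefaction is in `res$disparity`; the Eocene group (n = 2) is carried
through but flagged too small for disparity. On this synthetic design
the extant sum of variances (0.0056) is ~3.4× the Cretaceous one
(0.0016), the built-in analogue of the extant fauna having the highest
morphological diversity.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/stylomorph.R run --out results_dir --seed 1
```

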