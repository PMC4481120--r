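---
title: "Quantifying landmark precision and distance reliability in replicated 3D morphometric data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying landmark precision and distance reliability in replicated 3D morphometric data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmarkprec)
```

## The problem

When the same anatomical landmarks are digitized repeatedly — with a 3D
digitizer arm on the physical specimen, or with landmarking software on
micro-CT volumes — every coordinate carries digitizing error, and every
device may see a suture or a bone tip slightly differently. Before 3D-image
measurements can replace physical ones in a morphometric study, two
questions must be answered quantitatively:

1. **Landmark precision.** How far does each landmark scatter around its
   mean position, per device?
2. **Distance reliability and accuracy.** How repeatable are the
   inter-landmark distances within a device, how much does reliability drop
   when two devices' replicates are pooled, and is there a systematic bias
   between devices?

`landmarkprec` implements the full analysis pipeline for a replicated study
design — individuals x methods x replicates — together with a synthetic-data
generator with known ground truth, so that every stage can be validated
end to end without access to the original specimens.

## Superimposition

All configurations are brought into a common shape space by generalized
Procrustes analysis (`gpa()`): each configuration is centered, scaled to
unit centroid size, and rotated by the least-squares optimal proper
rotation onto the current mean shape; the mean is re-estimated as the
normalized average of the rotated configurations and the sweep repeats.
Numerical choices:

* **Reflections are always excluded.** The rotation solver flips the sign
  of the smallest singular value's axis when the unconstrained optimum
  would be a reflection; anatomical configurations must never be mirrored.
* **Convergence** is declared when the root-mean-square change of the mean
  shape falls below `tol` (default `1e-10`), with `max_iter = 100`; GPA on
  realistic data converges in a handful of sweeps, and these defaults make
  results reproducible to reporting precision. Non-convergence returns a
  flagged result with a warning rather than an error.
* **Initialization**: the first configuration's orientation seeds the mean,
  so the algorithm is deterministic without a random seed. The fit is
  invariant (up to a global rotation) to any rigid motion and positive
  scaling applied independently to each input; the objective — the summed
  squared Procrustes distance to the mean, recorded after each rotation
  sweep — is provably non-increasing.
* Configurations are held at **unit centroid size** (no per-iteration scale
  re-optimization): the classic partial-Procrustes formulation used
  throughout geometric morphometrics.
* A rank-deficient (collinear) configuration makes the rotation
  non-identifiable and is a hard error; planar (rank-2) configurations are
  accepted.

## Leave-one-landmark-out precision

An ordinary GPA confounds per-landmark variation: the least-squares fit
redistributes a highly variable landmark's displacement across all other
landmarks ("Pinocchio effect"). The estimator in
`loo_landmark_deviation()` therefore excludes the landmark of interest,
fits the GPA on the remaining landmarks, and then carries the held-out
landmark into shape space with its configuration's fitted similarity
transform. Its deviation is the Euclidean distance to the arithmetic mean
of the transformed held-out points.

Three details were genuinely open and were resolved as follows:

* **The held-out landmark receives the full similarity transform** —
  centering by the reduced-configuration centroid, division by the reduced
  centroid size, then the rotation — not the rotation alone. Without
  centering and scaling the held-out point does not live in the same
  coordinate system as the fitted landmarks; rotation-only application is
  not geometrically coherent.
* **Every replicate enters as its own configuration** and deviations are
  averaged over all configurations of a method. Pooling uses all the
  information and keeps the reported n consistent with the replicated
  design.
* **The mm rescale** multiplies shape-space deviations by the method's mean
  centroid size, computed on the same landmark subset that entered the GPA
  (by default the midline + left-side landmarks of a bilaterally symmetric
  scheme), keeping the scale internally consistent.

`naive_landmark_deviation()` computes the same statistic from a single
all-landmark GPA. It exists for the contrast: in simulations with one
landmark's error SD inflated several-fold, the naive estimator shrinks the
inflated landmark's apparent deviation and inflates the others, while the
leave-one-out estimator ranks the inflated landmark first essentially
always. With many landmarks (the bundled scheme analyzes 20) the naive
fit spreads a single landmark's variance thinly, so the *profile* advantage
of the leave-one-out estimator, while systematic, is small relative to
Monte-Carlo noise at realistic sample sizes; it is decisive for small
configurations.

## Distances, bilateral averaging, and gross-error screening

Inter-landmark distances follow a distance scheme (24 bundled distances;
`compute_distances()`), are computed per side for bilateral pairs, and
averaged across sides (`average_bilateral()`); a masked side falls back to
the present side with a `single_side` flag. Masked landmarks mask the
affected distance — they never become zeros.

Replicate pairs are screened for gross digitizing error
(`flag_gross_errors()`): an absolute replicate-to-replicate difference
above 0.5 mm is flagged, or above 0.3 mm for distances whose method-wise
mean is below 3.0 mm (small distances carry proportionally more error, so
a tighter absolute rule applies). The 0.3-mm rule is driven by the
*observed* method-wise mean; an explicit id list (`small_distance_ids`)
can override it when a study fixes the small-distance set a priori.
Screening is report-only: flagged pairs indicate landmarks to re-digitize,
and nothing is auto-corrected or silently dropped (the pipeline can be
made to abort via `strict_qc`).

## Repeatability and difference reports

Distance repeatability is the among-individual share of total variance,
estimated from one-way ANOVA mean squares (`variance_components()`):
`s² = MS_within`, `s²_A = (MS_among − MS_within)/k₀`, and

> r = s²_A / (s² + s²_A)

with `k₀` the replicate count for balanced designs and the standard
effective group size `(N − Σnᵢ²/N)/(a − 1)` otherwise (unbalanced designs
are supported but flagged — the intended design is balanced). A negative
among-individual estimate is clipped to zero, keeping `r` in `[0, 1]`; the
raw value is retained in the report. When all values are identical both
components are zero and `r` is defined as 0.

`within_method_repeatability()` groups replicates by individual within one
method (k = 2 in the default design); `between_method_repeatability()`
pools both methods' replicates for every individual measured by both
(k = 4), restricting to the intersection of individuals so the design stays
balanced. The drop from within- to between-method repeatability measures
the disagreement between devices beyond their internal noise.

`within_method_differences()` and `between_method_differences()` report
raw (signed, first-listed minus second) and absolute differences per
distance; `percentage_error()` divides each distance's mean absolute
difference by that distance's mean and multiplies by 100, and the summary
"% of mean" is the mean ± SD of the per-distance percentages, not the ratio
of summary means. Between-method differences use the mean over each
method's replicates per individual (a flag switches to replicate 1 only);
the mean is the lower-noise choice. `repeatability_length_correlation()`
tests the association between per-distance repeatability and mean distance
length (Pearson, two-sided t with df = n − 2, alpha 0.05): with landmark
error homogeneous in mm, smaller distances carry proportionally more error
and lower repeatability.

## The synthetic-data generator

`simulate_dataset()` emulates the replicated multi-method design: 20
individuals, 2 replicates per individual per method, and three methods —
a digitizer (`DIG`) and two CT resolutions (`MED`, `HIGH`) emitted in voxel
units with pixel sizes 0.01742 and 0.00871 mm, so the pipeline must apply
`convert_units()` exactly as a user would.

The error model, per configuration:

```
individual shape  = size_i * template + iid jitter          (biology)
configuration     = shape + method bias + iid error         (digitization)
                    [+ random rotation and translation]     (frame nuisance)
```

* **Individual variation** has two components: iid per-coordinate jitter
  (`individual_sd`, default 0.12 mm — localized shape differences) and a
  per-individual lognormal size factor (`individual_size_cv`, default
  0.04). The size component matters: among-individual distance variance
  must grow with distance length (as it does in real organisms) for
  repeatability to rise with length while absolute digitizing error stays
  constant; with iid jitter alone every distance would have identical
  among- and within-variance and no repeatability-length association could
  exist.
* **Digitizing error** is iid Gaussian per coordinate with a per-landmark
  SD vector per method (defaults: DIG 0.06, MED 0.035, HIGH 0.03 mm). A
  heavy-tailed contamination of these errors can be emulated by passing an
  inflated per-landmark SD vector when exercising the gross-error screen.
* **Method bias** is a fixed per-landmark 3-vector drawn once per dataset
  (`bias_sd`; defaults DIG 0.30, MED/HIGH 0.07 mm): a device that sees a
  suture differently sees it differently in every replicate. Bias is what
  separates between-method from within-method reliability.
* **Frame nuisance**: each configuration optionally lives in its own random
  rigid frame (uniform rotation, Gaussian translation), as with a digitizer
  arm that defines a fresh coordinate system per session. The nuisance
  *scale* range defaults to the degenerate `[1, 1]`: a digitizer arm and a
  calibrated CT both report true millimetres, and a random per-digitization
  scale would corrupt every mm distance analysis. Setting
  `nuisance_scale_range = c(0.9, 1.1)` (or wider) exercises the full
  similarity invariance of the Procrustes stages, which is how the test
  suite uses it.

The default magnitudes were calibrated analytically to the published
characteristics of a digitizer-versus-microCT comparison of ~20 mm toad
skulls: within-method absolute replicate differences of roughly
0.07–0.09 mm, between-method absolute differences around 0.26 mm against
the digitizer and 0.11 mm between CT resolutions, within-method mean
repeatabilities of 0.94–0.98, and a marked repeatability drop when
digitizer and CT replicates are pooled. `expected_repeatability()` gives
the delta-method prediction of per-distance repeatability implied by the
parameters (valid for isotropic error without bias; bilateral averaging
halves the independent variance components but not the shared size
component), and is used as the recovery target in tests.

The `toad_like` template is a fixed, bilaterally symmetric 35-point
configuration spanning ~17 mm with the bundled scheme's structure; its 24
distances range from ~2 to ~14 mm, and the distances with means below
3.0 mm are {5, 8, 10, 11, 13, 24}, mimicking the small-distance subset of
the motivating design (its distance 17 is ~7.1 mm).

What the generator does **not** emulate: correlated (anisotropic) landmark
errors along bone edges, digitizer drift within a session, allometric shape
change beyond isometric size, missing landmarks from damaged specimens, and
outlier gross errors unless injected. Passing tests therefore demonstrate
correctness of the estimators under the stated error model, not robustness
to every pathology of real data.

## Validation problem sizes

The test suite validates: the GPA against an independently coded
alternating-minimization oracle with random restarts (50 random instances,
up to 6 configurations of up to 8 landmarks, agreement to 1e-8 in total
Procrustes distance); similarity invariance of deviations and
repeatability to 1e-8; repeatability recovery at a 9:1 variance ratio
(200 individuals x 2 replicates, 20 seeds, within ±0.03 of the analytic
0.9); leave-one-out localization of a 5x inflated landmark (20 x 2, 100
seeds); the between-method repeatability drop under method bias (100
seeds); the repeatability-length association (100 seeds); and exact
arithmetic for the QC thresholds, unit conversion, and difference
reports. These sizes keep the full suite within a desktop-scale run while
holding Monte-Carlo error well below the tested tolerances.

## Known limitations

* Precision analyses require complete configurations: any configuration
  with a masked landmark in the analyzed subset must be excluded by the
  caller (the motivating design used only specimens where all landmarks
  could be placed).
* The repeatability model is a one-way ANOVA per distance; it does not
  model replicate order effects or method-by-individual interaction
  (between-method bias appears as residual variance, which is exactly what
  the within/between comparison exploits).
* The leave-one-out deviation still uses a fit that contains the *other*
  landmarks' errors; with one grossly inflated landmark, estimates at the
  remaining landmarks are mildly inflated through the shared transforms.
* `expected_repeatability()` is a first-order delta-method approximation;
  it is exact for the variance *ratio* under homogeneous SDs, and accurate
  when SDs are small relative to distance lengths.
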