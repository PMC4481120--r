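# landmarkprec

Measurement-error analysis for replicated 3D landmark data.

When the same specimens are landmarked repeatedly with different
instruments — a 3D digitizer arm on the physical object, landmarking
software on micro-CT volumes at different resolutions or scanning
filters — a morphometric study needs to know how precise each landmark
is per instrument, how reliable the derived linear distances are, and
whether instruments disagree systematically. `landmarkprec` implements
that pipeline for a replicated design (individuals × methods ×
replicates):

* **Generalized Procrustes superimposition** (`gpa()`), written for 3D
  landmark blocks: centering, unit-centroid-size scaling, least-squares
  proper rotations (reflections excluded), deterministic initialization.
* **Leave-one-landmark-out precision** (`loo_landmark_deviation()`,
  `landmark_precision_report()`): each landmark is excluded from the
  superimposition, carried into shape space by its configuration's fitted
  similarity transform, and its scatter about the mean landmark reported in
  shape units and in mm. Excluding the landmark prevents a variable
  landmark's error from being redistributed across the configuration by
  the least-squares fit.
* **Distance extraction** with bilateral averaging and a gross-error screen
  (`distance_table()`, `flag_gross_errors()`): replicate differences above
  0.5 mm are flagged, 0.3 mm for distances with method-wise means below
  3.0 mm.
* **Distance repeatability** from one-way ANOVA variance components
  (`variance_components()`, `within_method_repeatability()`,
  `between_method_repeatability()`):

  r = s²_A / (s² + s²_A)

  with s²_A the among-individual and s² the residual variance. Pooling two
  methods' replicates per individual (k = 4) measures between-method
  disagreement as a repeatability drop.
* **Raw / absolute / percentage difference reports** and the
  repeatability-versus-distance-length correlation
  (`within_method_differences()`, `between_method_differences()`,
  `percentage_error()`, `repeatability_length_correlation()`).
* **A synthetic-data generator with known ground truth**
  (`simulate_dataset()`): individual shape + size variation, per-method
  per-landmark digitizing error and systematic bias, optional random rigid
  frames, voxel-unit methods requiring mm conversion (`convert_units()`).

Data come in as long-format CSV
(`individual,method,replicate,landmark,side,x,y,z`), per-configuration
whitespace TXT blocks, or TPS records (`read_landmark_table()`); the
20-landmark / 24-distance toad-skull scheme that motivated the package is
bundled (`default_schemes()`).

## Worked example

```r
library(landmarkprec)

sim <- simulate_dataset(sim_params(seed = 1))   # 20 ind x 3 methods x 2 reps
res <- run_pipeline(pipeline_config(dataset = sim$dataset, seed = 1))
print(res)
#> Pipeline result: 120 configurations, 3 methods
#>   mean within-method r:  DIG=0.910, HIGH=0.977, MED=0.972
#>   mean between-method r: DIG + HIGH=0.523, DIG + MED=0.499, HIGH + MED=0.918
```

Within each method the distances are highly repeatable (r ≥ 0.91): the
among-individual variance dwarfs replicate noise. Pooling digitizer (DIG)
replicates with either CT resolution drops mean repeatability sharply —
the generator gives DIG a systematic per-landmark bias — while the two CT
resolutions pooled together barely drop (0.918), exactly the pattern that
motivates separating within- from between-method reliability.

```r
head(res$precision$DIG$per_landmark[, c("landmark", "side",
                                        "mean_deviation_mm",
                                        "sd_deviation_mm")], 4)
#>  landmark side mean_deviation_mm sd_deviation_mm
#>         1    M         0.2823445       0.1312040
#>         2    M         0.2455268       0.1000819
#>         3    M         0.2775462       0.1036127
#>        13    M         0.2469913       0.1288117
```

Per-landmark precision for the digitizer: each landmark scatters ~0.25–0.28
mm around its mean position (leave-one-out estimate, rescaled from shape
space by the method's mean centroid size).

```r
res$differences_between[["DIG - MED"]]$summary
#>    statistic      mean        sd
#>     mean_raw 0.2325764 0.3567450
#>     mean_abs 0.3396316 0.2521909
#>  pct_of_mean 7.4292869 5.7718155

res$correlations[["DIG + MED"]]
#> Pearson correlation: r = 0.462, d.f. = 22, P = 0.02292 (significant)
```

DIG and MED disagree by ~0.34 mm per distance on average (≈ 7.4 % of the
distance means), and between-method repeatability rises significantly with
distance length: the same absolute error weighs more on small distances.

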