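# qsmref

Statistical effects of reference-region choice in quantitative
susceptibility mapping (QSM), for imaging scientists who run ROI-based
group comparisons on susceptibility maps.

A susceptibility map is only defined up to an additive constant: the
k-space dipole kernel `D(k) = 1/3 − k_z²/|k|²` is zero at the origin, so
the map's global mean is unobservable and every study must either
reference to some region or implicitly reference to the whole brain.
Referencing replaces each subject's test-ROI mean `X` by `X − R`, and by
Bienaymé's identity

```
Var(X − R) = Var(X) + Var(R) − 2 Cov(X, R)
```

the between-subject variance entering the Welch statistic
`t_d = (x̄_n − ȳ_m)/S_d`, `S_d² = S_X²/n + S_Y²/m`, can go anywhere from 0
(reference identical to the ROI) to `4σ²` (perfectly anticorrelated,
equal variances). A reference whose mean differs between groups changes
the null hypothesis itself and produces false positives. This package
makes all of that measurable on synthetic data with known truth:

* a dipole-consistent phantom generator, forward model, and TKD /
  Tikhonov inversion emulators;
* five referencing strategies: anatomical ROI, whole brain, lowest-3rd-
  percentile relative variance, R2\* < 4 Hz (with a closed-form ARLO-style
  multi-echo R2\* fitter), and none;
* the cohort ROI pipeline: spherical-kernel erosion ×3, 1st/99th
  percentile trimming, reference → age-correct → ANOVA → Tukey–Kramer with
  post-hoc gating, plus variance-change diagnostics;
* ground-truth accuracy classification of reconstructions per ROI and
  strategy;
* Monte-Carlo verification of the variance bounds, hypothesis
  equivalence, and power effects.

## Worked example

```r
library(qsmref)

# phantom -> field -> two imperfect reconstructions -> accuracy per strategy
ph    <- build_phantom()
k     <- dipole_kernel(dim(ph$chi$values))
field <- forward_field(ph$chi, k)
recons <- list(
  tkd      = reconstruct(field, k, "tkd",      brain_mask = ph$chi$brain_mask),
  tikhonov = reconstruct(field, k, "tikhonov", brain_mask = ph$chi$brain_mask))
accuracy_table(recons, ph$chi, ph$labels, c("none", "csf", "wholebrain"))
#> <accuracy_table> 2 reconstructions x 9 ROIs x 3 strategies (alpha = 0.05)
#>                  none csf wholebrain
#> csf                 0   2          0
#> corpus_callosum     0   0          0
#> ...
#> Sum                 0   2          0
```

Direct single-step inversions reconstruct ROI means with method-specific
bias, so almost no ROI passes the voxelwise accuracy test; referencing to
CSF makes the CSF row accurate in both reconstructions by construction
(self-reference forces t = 0).

```r
# epilepsy-style cohort: 27 HC / 19 LTLE / 17 RTLE, CSF referencing
cohort <- simulate_cohort(cohort_design(), seed = 42)
report <- run_group_pipeline(cohort, strategy = "csf")
report$anova
#>                roi      F      p significant
#> 1              csf    NaN    NaN       FALSE
#> 2  corpus_callosum 1.0140 0.3689       FALSE
#> 3 internal_capsule 1.1343 0.3285       FALSE
#> ...
#> 8         thalamus 2.9838 0.0582       FALSE
```

Under the default null design (equal group means, unbiased reference) no
ROI reaches significance, as it should; the `csf` row is NA because an ROI
referenced to itself is constant. `report$variance_change` shows what the
strategy did to the between-subject spread (−100 % for CSF itself, −47 %
for the corpus callosum in this draw: the shared subject offset is
cancelled).

```r
# the variance bounds, analytically and by Monte-Carlo
variance_bound_scan(correlations = c(-1, 0, 1), n_per_point = 2e4, seed = 1)
#>   rho ratio_analytic ratio_mc        se
#> 1  -1              4 4.012817 0.0400010
#> 2   0              2 2.001517 0.0200005
#> 3   1              0 0.000000 0.0000000
```

The referenced-to-raw variance ratio hits the analytic curve `2 − 2ρ`:
fourfold inflation at ρ = −1, doubling for an uncorrelated reference,
exact cancellation at ρ = +1.

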