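---
title: "Reference regions and the statistics of susceptibility maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference regions and the statistics of susceptibility maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmref)
```

## The problem

Quantitative susceptibility mapping (QSM) reconstructs tissue magnetic
susceptibility $\chi$ from the MRI field perturbation $\Delta B$ through the
dipole convolution $\Delta B = \chi * D$, where the k-space kernel
$D(k) = 1/3 - k_z^2/|k|^2$ vanishes at the origin (and on a conical
surface). The zero at $k = 0$ means the global mean of $\chi$ is
unobservable: a susceptibility map is only defined up to an additive
constant. Practitioners therefore *reference* maps — subtract the mean (or
median) susceptibility of a chosen reference region from every voxel —
before comparing values across subjects or scanners.

This package treats referencing as a statistical operation and asks what it
does to group comparisons. Everything runs on synthetic data with known
ground truth: a dipole-consistent phantom for reconstruction-accuracy
questions and a generative cohort model for group-statistics questions.

## The cohort model

Per-subject ROI mean susceptibilities are drawn, for subject $s$ in group
$g$ with age $a_s$, as

$$ x_{s,j} = \mu_{g,j} + b_s + \beta\,(a_s - \bar a) + \varepsilon_{s,j},
\qquad b_s \sim N(0, \tau^2),\ \varepsilon_{s,j} \sim N(0, \sigma_j^2). $$

The shared offset $b_s$ is the inter-subject global-susceptibility shift
(scaling, calibration, diffuse physiology) that referencing is designed to
remove; it induces covariance $\tau^2$ between every pair of ROI columns.
A designated reference ROI can carry a group-specific mean shift — reference
region pathology — which is the mechanism by which referencing *biases*
group comparisons rather than merely rescaling them.

Defaults are chosen to emulate a temporal-lobe-epilepsy study: 27 healthy
controls and 19/17 left/right-TLE patients, ages uniform on 16–67 years,
between-subject ROI spread $\sigma = 0.01$ ppm, shared-offset spread
$\tau = 0.005$ ppm, and an age slope of 0.001 ppm/year. Group sizes and the
age range follow the emulated study design; $\sigma$, $\tau$ and the slope
are this package's choices of realistic magnitudes for deep grey-matter
susceptibilities (ROI means of order 0.01–0.1 ppm, age-related iron
accumulation of roughly 0.05 ppm over five decades). Ages are drawn
uniformly because only a range is specified; the reported medians would
require a skewed model that adds nothing to the statistical questions
studied here.

## Why referencing changes test outcomes

For the two-group comparison the package uses the unequal-variance Welch
statistic $t_d = (\bar x_n - \bar y_m)/S_d$ with
$S_d^2 = S_X^2/n + S_Y^2/m$. Referencing replaces $X$ by $X - R$, and by
the Bienaymé identity

$$ \operatorname{Var}(X - R) = \operatorname{Var}(X) +
\operatorname{Var}(R) - 2\operatorname{Cov}(X, R). $$

With equal variances $\sigma^2$ and correlation $\rho$ this is
$(2 - 2\rho)\,\sigma^2$, bounded between $0$ (at $\rho = +1$, the reference
equals the test ROI) and $4\sigma^2$ (at $\rho = -1$). An uncorrelated
reference can only inflate the variance and lower power; a reference that
shares the subject offset cancels $\tau^2$ and sharpens the test; a
reference whose mean differs between groups changes the null hypothesis
itself and manufactures false positives. `bienayme_decomposition()`,
`variance_bound_scan()`, `hypothesis_equivalence_sim()` and `power_curve()`
verify each of these claims by construction and by Monte-Carlo.

```{r}
scan <- variance_bound_scan(correlations = c(-1, 0, 1),
                            n_per_point = 2e4, seed = 1)
scan
```

## Referencing strategies

Five strategies are implemented (`reference_strategy()`):

1. **Anatomical** — mean or median over a labelled ROI (CSF, corpus
   callosum, internal capsule in the default phantom).
2. **Whole brain** — mean over the brain mask. Direct dipole inversions
   leave the lattice mean at zero, so this is essentially equivalent to not
   referencing; the package tests that equivalence explicitly.
3. **Relative variance** — voxels in the lowest 3rd percentile of
   $|\operatorname{Var}(\chi)[r] / \operatorname{mean}(\chi)[r]|$ across
   volumes on a common grid. The ranking uses the absolute ratio because
   near-zero across-subject means produce arbitrarily large (and sign-
   meaningless) ratios which must never win a *lowest*-percentile
   selection; undefined (0/0) voxels are treated as infinitely variable.
   All volumes are assumed to share one lattice — no registration or
   template construction is performed.
4. **R2\* threshold** — voxels with $R_2^* < 4$ Hz in the subject's own
   relaxation map, a segmentation-free proxy for fluid-like tissue.
5. **None** — the do-nothing baseline all diagnostics are measured against.

Percentiles throughout use linear interpolation between order statistics
(R's type-7 default), stated so that voxel counts are exactly reproducible.

### R2\* fitting

`fit_r2s()` implements the closed-form ARLO-style estimator for equally
spaced echoes: Simpson-rule integrals $s_j$ over consecutive echo triplets
are paired with signal differences $d_j = y_j - y_{j+2}$, and
$T_2^* = (\sum s_j^2 + \tfrac{\Delta}{3}\sum s_j d_j) /
(\tfrac{\Delta}{3}\sum d_j^2 + \sum s_j d_j)$. On noiseless
mono-exponential data this is exact up to the Simpson discretization (well
under 1 % for the echo spacings used), and a log-linear least-squares fit
(`fit_r2s_loglin()`) serves as the independent cross-check. Negative rates
are clipped to 0 Hz, constant signals return 0 Hz, and magnitudes carry
Gaussian (not Rician) noise in simulation — a documented simplification
acceptable at the simulated signal-to-noise ratios.

## ROI preprocessing

The cohort-style ROI pipeline (`summarize_roi()`) erodes each ROI mask with
the radius-1 spherical kernel — interpreted literally as the 6-neighbour
cross, since the 26-neighbourhood has radius $\sqrt{3}$ — applied three
times, then removes voxel values outside the 1st–99th percentiles, then
computes mean and SD. The order (erode, trim, summarize) is fixed;
trimming percentiles are computed per subject per ROI on the eroded voxel
set, with inclusive bounds.

## The two workflows

**Challenge-style accuracy** (`accuracy_table()`): reconstructions of one
phantom are compared to ground truth per ROI with a voxelwise Welch t test,
both sides referenced by the strategy under study; an ROI is *accurate*
when the means are not significantly different at $\alpha = 0.05$. The
test is unpaired, voxels within an ROI being treated as independent draws
from an ROI-specific distribution. The test is computed from sufficient
statistics so that referencing an ROI to its own mean gives a numerator of
exactly zero — self-referencing is accurate by construction, and the
accuracy table reproduces that structurally.

**Cohort statistics** (`run_group_pipeline()`): reference, then age-correct
(pooled simple linear regression of the referenced value on age, residuals
plus grand mean; a per-group model is available via the `groups` argument
of `age_correct()`), then a one-way ANOVA per ROI, then Tukey–Kramer
pairwise comparisons only for ROIs passing the ANOVA gate at
$\alpha = 0.05$. No further multiple-testing correction is applied across
ROIs, mirroring common clinical practice. The variance-change diagnostic
$100\,[\operatorname{Var}(x - r) - \operatorname{Var}(x)] /
\operatorname{Var}(x)$ summarizes what each strategy did to the
between-subject spread.

```{r}
design <- cohort_design()
cohort <- simulate_cohort(design, seed = 42)
report <- run_group_pipeline(cohort, strategy = "csf")
head(report$anova)
head(report$variance_change)
```

## Numerical choices and degenerate inputs

* Unbiased $(n-1)$ sample variances everywhere, so the Bienaymé identity
  holds to machine precision on sample moments.
* Welch degrees of freedom by Welch–Satterthwaite; two constant equal
  samples define $t = 0$, $p = 1$; an ROI referenced to itself inside the
  pipeline yields an NA ANOVA and is reported as not significant rather
  than an error.
* The TKD truncation is sign-preserving at $\delta = 0.2$ (sign 0 treated
  as $+$); the Tikhonov default is $\lambda = 0.05$. Both defaults were
  picked once as well-conditioned for the bundled phantom; the inversion
  methods are named emulators, not reimplementations of any published
  pipeline.
* The B0 axis defaults to the third lattice axis and is configurable;
  kernels are built on unshifted discrete frequencies scaled by voxel size.
* The phantom is parametric (spheres in an ellipsoidal brain), so every
  ROI mean is known exactly by construction; piecewise-constant ROIs make
  several tests exact but produce zero within-ROI variance, which the
  degenerate-variance rules above handle explicitly.

## Problem sizes

The bundled phantom is a $48^3$ lattice with nine ROIs; theory scans use
$10^5$ pairs per correlation point; calibration experiments use 1000
replicates of the 63-subject cohort. These sizes resolve the analytic
bounds to within a couple of percent while keeping a full run of the test
suite on a single CPU in well under a minute per experiment.

## What the synthetic data does and does not show

The generator reproduces the *statistical* structure that referencing
interacts with: shared offsets, reference-region pathology, age trends,
method-specific reconstruction bias, and the dipole physics of the forward
model. It does not attempt realistic brain anatomy, susceptibility
anisotropy or microstructure, phase noise, background fields, registration
error, or deep-learning reconstructions. Passing tests therefore
demonstrate that the statistical machinery behaves as the theory predicts
under the stated model — not that any particular clinical dataset obeys
that model. In particular, real reference regions are segmented with
error, and real cohorts have non-uniform age structure; both would widen
the uncertainty of any single study's conclusions.
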