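---
title: "Quantifying motor-pool topography with the scatter index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor-pool topography with the scatter index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorpool)
library(dplyr)
```

## The problem

Spinal motor neurons innervating one muscle group form a *motor pool* with a
stereotyped position in the ventral horn. Retrograde tracers injected into
dorsal or ventral forelimb muscles label the corresponding pools, which are
then traced on serial coronal sections. Genetic axon-guidance defects (and
their experience-dependent correction) show up as a *spreading* of a pool
beyond its normal territory, particularly along the dorso-ventral axis.
motorpool implements the full quantification chain: reconstructing a
comparable coordinate frame across sections, summarizing a pool's spreading
with a single covariance-based statistic, and running the cohort-level
statistics used to compare genotypes and housing conditions. Because no
public dataset of such traces exists, the package ships a synthetic
generator that emulates every assay with known ground truth, so the whole
chain is testable end to end.

## Coordinate convention

All in-plane coordinates are expressed in **normalized hemicord units**:
X is medio-lateral (lateral positive), Y is dorso-ventral (dorsal
positive), the origin is the central canal, and the distance from the canal
to the lateral edge of the grey matter is 1. This dimensionless frame is
what makes pools comparable across animals and ages; a directional SD of
0.13 means "13% of the hemicord radius". With SDs of that size, ellipse
areas land in the 10^-4^–10^-3^ range, which is the natural scale of the
scatter index below.

## The scatter index

For a pooled set of neuron positions $(x_i, y_i)$, let
$\Sigma = \mathrm{cov}(x, y)$ be the unbiased ($n-1$ denominator) 2×2
sample covariance matrix with eigenvalues $\lambda_1 \ge \lambda_2$. The
scatter index is

$$\mathrm{SI} \;=\; \pi\,\lambda_1\,\lambda_2 \;=\; \pi\,\det\Sigma ,$$

the area of the covariance ellipse whose axes are the principal directions
and whose "radii" are the directional *variances*. The eigenvalues
themselves — not their square roots — enter the product; for an
axis-aligned pool this gives $\mathrm{SI} = \pi\,\sigma_x^2\,\sigma_y^2$,
and published group values are numerically consistent with exactly this
reading (e.g. $\pi \cdot 0.11^2 \cdot 0.13^2 \approx 6.4\times10^{-4}$
against a reported ventral-pool SI of $6.9\times10^{-4} \pm 1.2\times10^{-4}$).
The ellipse that `autoplot()` draws uses semi-axes $\sqrt{\lambda}$ (the
principal SDs) so the picture matches the data spread; both are reported to
avoid ambiguity. *Directional scattering* is simply $\mathrm{sd}(x)$ and
$\mathrm{sd}(y)$.

Properties the tests enforce: SI is invariant under translation and
rotation (it is a determinant), scales exactly as $a^2 b^2$ under
anisotropic scaling, equals the independent $\pi \det \Sigma$ oracle to
machine precision, and requires at least 3 points (below that the
covariance is rank-deficient and SI is undefined rather than 0).

## From serial sections to one point cloud

Three stages turn per-section traces into the pooled cloud:

1. **Rigid alignment** (`align_series()`). Every section carries four
   optical reference fiducials. Each section is mapped onto the first
   section (an arbitrary but deterministic template) by the least-squares
   rigid transform — rotation plus translation, *no scaling* — fit to the
   fiducials by 2-D SVD (Kabsch). Keeping alignment rigid means all scale
   correction happens in one place, the next stage, and the section
   diameter cannot be corrected twice. The aligned series is then moved by
   a single global rigid motion so that the mean mid-sagittal axis points
   dorsally and the mean central canal sits at the origin; a global rigid
   motion cannot change the SI, but it fixes the ML/DV axes that the
   directional SDs refer to. Per-section fiducial residuals are reported.

2. **Diameter normalization** (`normalize_series()`). Sections taken at the
   cervical enlargement are physiologically wider than their neighbours.
   For each section an interpolating cubic spline (chord-length
   parameterized) is fit through the five lateral-edge landmarks, and its
   intersection with the line through the central canal perpendicular to
   the mid-sagittal axis is found by bracketed root-finding (tolerance
   1e-10 in the curve parameter). The canal-to-intercept distance $d_i$ is
   the section's effective hemicord radius. The per-section $d_i$ profile
   is denoised with a cross-validated smoothing spline over section index,
   and each section is rescaled isotropically about its own canal by
   $1/\hat d_i$, bringing every section to unit hemicord radius. Two open
   choices were resolved deliberately here:
   * *Smoothing, not interpolation, of the intercept profile.* An
     interpolant reproduces every noisy intercept exactly and would pass
     measurement noise straight into the scale factors; the smoothing
     spline damps isolated outliers while leaving an exactly constant
     profile untouched, so undistorted series round-trip to machine
     precision. With fewer than 4 usable sections the raw distances are
     used (with a warning).
   * *Unit reference diameter.* Rescaling to $\hat d_i = 1$ (rather than to
     the series-mean diameter, available via
     `reference_diameter = "mean"`) is what actually removes the
     enlargement and puts all animals in the same dimensionless frame; a
     series-mean reference would retain an animal-specific global scale of
     roughly the mean enlargement factor (~10% for typical profiles) in
     every downstream SD and SI.
   * *Intercept multiplicity and failures.* If the perpendicular crosses
     the curve more than once, the lateral-side intersection nearest the
     canal is used. Sections without a valid intercept are dropped with a
     logged warning rather than failing the series, mirroring tolerant
     manual workflows.

3. **Anterior–posterior projection** (`project_pool()`). All neurons of one
   pool are collapsed across sections into a single 2-D cloud (z is
   discarded), and `scatter_index()` is computed on the projected pool.
   Left and right hemicords are never mixed: tracer injections are
   unilateral, so one series is one hemicord.

`series_scatter()` chains the three stages and returns one tidy row per
pool.

## What the generator simulates

`sim_series()` builds an animal the way the measurement sees it, in this
order: each pool is drawn once as a bivariate normal cloud (the retained
ground truth), neurons are assigned uniformly to sections, each section's
*tissue* (neurons and edge landmarks) is multiplied by a smooth Gaussian
enlargement profile peaking mid-series, landmark positions get additive
measurement noise, and finally the whole section — including the
fiducials, which as extra-tissue marks are *not* scaled by the enlargement
— is jittered by a random rigid transform (mounting misalignment).
Defaults, chosen once as plausible for this preparation and stated here as
the package's own study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_sections` | 30 | 40 µm sections spanning a labeled pool (~1.2 mm) |
| `neurons_per_pool` | 60 | labeled motor neurons per pool per animal |
| `enlargement_amplitude` | 0.2 | +20% diameter at the enlargement peak |
| `enlargement_width` | 5 sections | width (SD) of the enlargement bump |
| `rigid_jitter_translation` | 0.05 | per-section mounting shift (hemicord units, per axis) |
| `rigid_jitter_rotation` | 0.05 rad | per-section mounting rotation (~3°) |
| `landmark_noise` | 0.01 | tracing noise on edge landmarks (1% of radius) |

`sim_cohort()` populates every assay at the published group parameters
(`preset_behavior()`, `preset_scatter()`, `preset_synapse()`,
`preset_pnn()`), converting each printed SEM into a between-animal SD as
$\mathrm{SEM}\sqrt{N}$ and using each assay's own published $N$ — the
assays are distinct sub-cohorts, mirroring the published per-assay group sizes, so animal ids are
not shared across tables. Specifics worth knowing:

* **Behavior.** Each recorded ladder-rung value is the mean of three
  simulated trials. A per-animal latent factor (shared across timepoints,
  variance $\tfrac{2}{3}\sigma_b^2$) plus trial noise (variance
  $\sigma_b^2$ per trial) makes the recorded 3-trial mean have exactly the
  published between-animal variance while inducing the within-animal
  correlation that the repeated-measures ANOVA needs. Zero-SEM presets
  reproduce group means exactly.
* **Scatter.** Per-animal directional SDs are drawn around the published
  group means; pools are then sampled at those SDs, so the `scatter` table
  carries measured values and the `truth` table the generating parameters.
  Where a pool's directional SDs are unpublished (the dorsal pools, and
  medio-lateral SDs of young animals), they are derived from the published
  SI via $\mathrm{SI} = \pi \sigma_{ml}^2 \sigma_{dv}^2$ (isotropic where
  both are missing).
* **Synapse counts.** Per-neuron vGlut1/vGAT counts are Poisson around a
  per-animal mean (default 30 neurons counted per animal); analyses
  average within animal first.
* **PNN categories.** Per-neuron `none`/`weak`/`strong` draws are
  multinomial at the group probabilities (default 50 neurons scored per
  animal), so per-animal fraction variability is binomial only.
* **ML–DV correlation defaults to 0** because only axis-aligned SDs are
  published; the generator accepts any $|\rho|<1$.

What the generator does **not** emulate: pixel-level images, tracing
ambiguity between adjacent neurons, left–right asymmetries, non-rigid
tissue deformation, and any within-animal correlation between assays.
Passing recovery tests therefore demonstrates correctness of the geometry
and statistics under rigid jitter plus smooth enlargement — not robustness
to deformations the model does not contain.

## The statistics layer

The comparison policy mirrors the source analyses: under `policy = "auto"`,
`compare_groups()` screens each group with Shapiro–Wilk at α = 0.05 (the
study names no test for its normality check; Shapiro–Wilk is the standard
small-sample choice) and uses an unpaired two-tailed Student's t-test when
both groups pass, otherwise a two-tailed Mann–Whitney test — exact by full
null distribution for combined N ≤ 20 without ties, normal approximation
with tie and continuity correction otherwise. Longitudinal behavior is
tested with a two-way mixed ANOVA (`rm_anova_interaction()`), significance
being the genotype × time interaction at α = 0.05; incomplete animals are
dropped, and no sphericity correction is applied (the published protocol
names none; with three timepoints the interaction is reported uncorrected).
`si_behavior_regression()` regresses SI on crossing time by default — the
published slope (~8×10^-5^) only has sensible units as SI per second — with
the reverse orientation available. PNN categories are compared per category
by one-way ANOVA on per-animal fractions; synapse counts by pairwise
Student's t-tests on per-animal means within genotype. The animal is the
statistical unit throughout; no multiple-testing correction is applied by
default (per-comparison reporting, as in the source), with a Holm option in
`compare_synapse_counts()`. Degenerate inputs follow explicit conventions:
identical constant groups return p = 1 with a warning, constant ANOVA
responses return F = 0, p = 1.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scales the method is meant for:
recovery over 50 simulated series (30 sections, 2×60 neurons) with a 30%
enlargement and default jitter, where the median relative error of the
recovered directional SDs must stay below 5% (it is ~0.2% in practice,
and exact to 1e-9 with all distortions off); 1000-replicate null
simulations for the type-I error of the two-group policy, the
repeated-measures interaction and the regression (all required to sit in
[0.03, 0.07] at α = 0.05); and 150–200-replicate cohort simulations at the
published means/SEMs/Ns, which must reproduce the published significance
pattern (dorso-ventral scattering difference under normal housing,
its absence after enrichment from birth, raised excitatory but unchanged
inhibitory synapse counts) in the majority of replicates.

## Worked example

```{r example}
series <- sim_series(seed = 1, enlargement_amplitude = 0.3)
series_scatter(series)

coh <- sim_cohort(groups = data.frame(housing = "NH", genotype = c("wt", "mut")),
                  seed = 1)
coh$scatter |>
  filter(pool == "ventral") |>
  compare_groups(sd_dv, genotype)
```

## Known limitations

* The normalization corrects a smooth, section-wise *isotropic* diameter
  change; shear or anisotropic deformation is outside the model.
* The reference-curve spline is only as good as five landmarks allow;
  strongly non-convex edge shapes between landmarks are not represented.
* Published dorsal-pool directional SDs do not exist, so dorsal-pool
  simulations rest on the isotropy assumption described above.
* The exact Mann–Whitney path switches to the normal approximation in the
  presence of ties regardless of sample size.
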