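---
title: "Longitudinal deformation-based morphometry with longdbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal deformation-based morphometry with longdbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A pair of structural brain volumes taken a year apart differs by a small,
spatially smooth deformation. Deformation-based morphometry estimates that
warp and reads atrophy off its Jacobian determinant (JD): the voxelwise
ratio of follow-up to baseline volume. `JD < 1` is local tissue loss. The
approach is more sensitive than differencing segmented volumes because it
measures change at every voxel rather than only at tissue boundaries, which
is what makes it attractive as a surrogate endpoint for trials of
neuroprotective treatments after traumatic brain injury (TBI).

`longdbm` implements the full chain — symmetric registration, JD mapping,
regional summaries, voxelwise and subject-level statistics, and power
calculations — together with a synthetic longitudinal phantom generator
whose ground truth is known exactly, so that each stage can be validated by
parameter recovery rather than by eye.

## The registration model

Registration estimates one stationary velocity field $v$ per subject. The
baseline is warped by $\exp(-v/2)$ and the follow-up by $\exp(+v/2)$; their
mean is the subject's midpoint ("temporal average") image, and the full
anatomical correspondence map is $W = \exp(v)$, defined so that
$\mathrm{followup}(W(x)) \approx \mathrm{baseline}(x)$. Under atrophy the
map contracts and $\det \nabla W < 1$. Treating both time points
symmetrically avoids the interpolation asymmetry that biases longitudinal
atrophy estimates when one scan is held fixed.

The estimator is a symmetric variant of demons registration:

* **Forces.** Sum-of-squared-difference demons forces
  $\delta = r\,J / (|J|^2 + r^2/s^2)$ with $r$ the intensity residual,
  $J$ the mean gradient of the two half-warped images and $s$ the mean
  voxel size (which caps the per-iteration step at about half a voxel).
  Estimation runs on copies of the images smoothed by `imageFwhmMm`
  (default 7 mm); the estimated warps are applied to the raw images for all
  outputs. Noise that is independent between the two scans can otherwise be
  "explained" by deformation, which drives the objective below the noise
  floor while roughening the field enough to break the antisymmetry of the
  two registration directions.
* **Regularization.** The update field is smoothed with a fluid Gaussian
  (`fluidSigmaMm`) and the velocity with a diffusion Gaussian
  (`diffusionSigmaMm`) after each accepted step. Updates are confined to a
  dilated support mask around image content; in noise-only background the
  demons denominator is dominated by noise and an unmasked update field
  would accumulate a random-walk deformation.
* **Acceptance.** A candidate step is only accepted if the masked
  mean-squared intensity difference does not increase, so the per-level
  objective trace is non-increasing by construction; the level stops when
  the relative improvement per iteration falls below `tol`. This guards the
  other failure mode of weakly-regularized demons on noisy images:
  "explaining" independent acquisition noise by deformation, which drives
  the objective below the noise floor while roughening the field.
* **Multi-resolution.** Three pyramid levels (block-mean downsampling by 2),
  50/50/25 iterations coarse-to-fine, scaling-and-squaring exponentiation
  with 6 squarings.

Interval weighting is geometric: `annualizeJd()` computes
$\exp(\log JD / \Delta t)$, treating volume change as compounding. The
linear annualized rate
$100\,(V_{fu} - V_{bl})/V_{bl}/\Delta t$ is also reported for volumetric
summaries; the two agree to first order for the small rates involved (the
package tests assert agreement within 0.1 percentage points at 1-year
intervals), and the geometric convention is used wherever JD values are
averaged or compared.

Folding (non-positive determinants) is never clamped: `jacobianMap()`
reports a folding count and `annualizeJd()` masks the affected voxels,
because silently clamping would bias exactly the summaries this pipeline
exists to measure.

## The synthetic cohort and what it does (not) emulate

`buildTemplatePhantom()` constructs a deterministic head-sized phantom on a
48³ grid of 3 mm voxels: an ellipsoidal brain with a central CSF ventricle,
a deep grey-matter shell, white matter, and a cortical ribbon whose inner
and outer surfaces are folded by an azimuthal sinusoid (default 8 folds).
Fold crowns are gyral, troughs sulcal; each azimuthal half-period crossed
with three polar bands yields 24 gyral and 24 sulcal regions of interest.
Class intensities are distinct (WM 120, deep GM 85, cortex 80, CSF 25,
background 0) with a smooth ±6 texture so tissue interiors carry usable
gradients, as real T1 anatomy does. The 3 mm spacing keeps a whole head in
a 48³ grid; the cortical ribbon (≈13 mm) stays several voxels thick, which
is the resolution constraint that matters for JD recovery.

Ground-truth deformations are radial mass-conserving shell maps: along each
ray from the brain centre (in ellipsoid-normalized coordinates) the cubed
radius is remapped piecewise linearly so that each tissue shell's volume
scales by exactly $c_k = [(1 + r_k/100)\,e^{\text{off}}]^{\Delta t}$. A map
that sends rays to rays has $\det = c_k$ exactly inside each shell,
independent of the fold-modulated boundaries, so the analytic JD stored as
ground truth is exact rather than approximate. Displacements taper to zero
just outside the brain, and the pullback used to synthesize the follow-up
image is the exact inverse obtained by fixed-point iteration (residual
below 10⁻³ voxels).

Per-subject annual rates are drawn from the study-condition distributions —
cases lose 1.55 ± 2.19 %/yr of grey and 1.49 ± 2.20 %/yr of white matter,
controls lose 0.55 ± 1.13 %/yr of grey and gain 0.26 ± 1.11 %/yr of white
matter — with a GM–WM correlation of 0.7 (chosen so the implied whole-brain
rate SD is below the tissue SDs, as observed). Remaining defaults:

* **Sulcal excess 1.065.** The study reports the sulcus-by-group interaction
  only as a coefficient of order 0.001 on the JD scale; a 6.5% rate excess
  in sulcal cortex reproduces an interaction of that order at a case mean of
  −1.55 %/yr. This is a calibration to an order of magnitude, not to a
  stated effect size.
* **Scanner offset 0.012** on annual log-JD between the two scanners. With
  the group mixture and rate SDs above, this makes scanner type account for
  roughly 9% of summary-JD variance, matching the reported hierarchical
  partitioning share.
* **Lesions** occur in 67.2% of cases as spherical intensity drops
  (radius 9 mm, intensity to 35%) in both time points. They are
  intensity-only by default: the study's claim under test is that the
  longitudinal JD analysis is robust to lesions, which the lesion-exclusion
  re-runs probe; coupling lesions to deformation would conflate that test.
* **Age and sex** have no effect on atrophy (the study found none);
  demographics still differ by group (cases older, more male) so covariate
  adjustment is exercised.
* **Neuropsychology.** Scores are coupled to each subject's true atrophy by
  a Gaussian copula with latent correlation $2\sin(\pi\rho/6)$, making the
  population Spearman correlation exactly the target (default pattern peaks
  at ρ = 0.51 for follow-up memory); missingness follows the study-like
  per-cell rates.
* **Intervals** are log-normal (median 13.1 months for cases, 12.7 for
  controls) and truncated to [0.3, 4] years.

What the phantom does *not* emulate: realistic MRI contrast or artifacts,
cross-subject anatomical variability (all subjects share one template and
grid, removing the need for spatial normalization — deliberately out of
scope), partial-volume effects at 1 mm scale, and non-linear atrophy
trajectories. Passing tests therefore demonstrate that the *algorithms*
recover known effects under controlled conditions, not that the pipeline
handles every property of clinical data.

## Statistical machinery

**Voxelwise inference.** Massively-univariate OLS per voxel with a group
contrast and covariates (age, sex, scanner, ICV), threshold-free cluster
enhancement (E = 0.5, H = 2, 26-connectivity, dh = max-stat/100 — the de
facto volumetric defaults, since the study names the method but not its
parameters), and Freedman–Lane permutation: nuisance effects are regressed
out, reduced-model residuals permuted, and the max-TFCE null rebuilt per
tail. Corrected p values use the add-one estimator
$(1 + \#\{\max \ge T\})/(m+1)$; two-sided inference Bonferroni-corrects
over the two sign tails. Exhaustive enumeration replaces sampling for small
two-group designs (intended for intercept-only nuisance, where relabeling
classes are exact). The permutation default here is m = 1000 with 10000 the
study-scale choice for final maps.

**Hierarchical partitioning.** The R² of outcome ~ group + age + sex +
scanner is decomposed into independent contributions by the subset-size
weighting (Shapley) identity over all 2^k subsets — algebraically identical
to averaging incremental R² over all k! orderings, which the tests verify
against an explicit-ordering oracle at 10⁻¹⁰. Goodness of fit is Gaussian
R², as the outcomes are continuous JD summaries.

**Sulcus versus gyrus.** Per-ROI mean JD is modelled with fixed effects for
group, ROI class and covariates, a random intercept and a random class
slope per subject; the group × class interaction is tested by a
likelihood-ratio comparison of maximum-likelihood fits (REML likelihoods
are not comparable across fixed-effect structures). Singular random-effect
fits fall back to a random intercept with a warning. Covariates are
standardized internally for optimizer stability; group and class
coefficients are unaffected.

**Neuropsychological correlations.** Spearman ρ per test × visit (baseline,
follow-up, change = follow-up − baseline) against GM and WM mean JD,
pairwise-complete, with Benjamini–Hochberg FDR across the 12 cells per
tissue — the family excludes tissue type, following the study's stated
correction. "Change" is the simple difference, the only definition the
two-visit design supports.

**Power.** Cohen's d uses the pooled SD; its 95% CI uses the normal
approximation $SE = \sqrt{(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))}$ (the
study does not state its CI method; this one reproduces the printed
intervals at two decimals). Sample size per arm is
$N = \lceil 2\,((1.96 + 0.842)/(TE \cdot ES))^2 \rceil$ with the z
constants fixed at their conventional printed precision. Ceiling rounding
reproduces five of the six published per-arm sizes exactly from the printed
effect sizes; the grey-matter volume figure (894) evidently reflects an
unrounded effect size and is reproducible to ±1.

## Numerical choices and degenerate inputs

* Gradients are central differences with one-sided borders, voxel size
  folded in, so JD is unit-free.
* Gaussian smoothing is separable with row-renormalized borders: constants
  are preserved exactly and interior-supported mass is conserved to 0.1%.
* `registerSymmetric(I, I)` short-circuits through the acceptance rule
  (the objective starts at zero) and returns the identity exactly.
* Registration of non-overlapping content cannot reduce the objective; the
  function warns and returns the identity rather than diverging.
* Empty masks, non-positive volumes or intervals, rank-deficient designs
  and emptied subgroups are hard errors that name the offending input.
* The default registration settings (`fluidSigmaMm` 2, `diffusionSigmaMm`
  1.0, `imageFwhmMm` 7, `tol` 10⁻³) were chosen jointly so that three
  properties hold at once on the default phantom: compartment-mean JD
  recovery within ±0.005 across −1 to −4 %/yr, direction antisymmetry of
  the log JD below 0.01, and no folding. Without image pre-smoothing these
  trade off against each other: stronger velocity smoothing stalls the
  accepted-step rule at the finest level and under-recovers steep rates,
  weaker smoothing fits acquisition noise.

## Problem sizes used in validation

The packaged tests and the acceptance script run, on one CPU, with: 48³
phantoms for registration recovery (a registration takes well under a
minute); 100 replicate null cohorts of n = 10 + 10 on 8³ grids with m = 99
permutations for familywise-error calibration; a planted 3% deficit in a
5-voxel-radius sphere at n = 20 + 20 on a 16³ grid for sensitivity; 100
replicate ROI cohorts of n = 60 + 30 (24 + 24 ROIs) for interaction
coverage and 200 smaller replicates for the null LRT distribution; and
n = 2000 per group (rates only) for generator calibration. These sizes were
chosen so each check's sampling error is small relative to the tolerance it
asserts.

## Known limitations

* The demons stand-in is tuned for the phantom's contrast and smooth
  ground-truth fields; on clinical data with bias fields and pathology it
  would need the usual preprocessing (bias correction, brain extraction)
  and possibly different regularization.
* Exhaustive permutation mode treats relabeling classes as exact, which
  holds for intercept-only nuisance; with continuous covariates it is an
  approximation and sampled Freedman–Lane should be used.
* The phantom shares one grid across subjects; template construction and
  spatial normalization are intentionally absent, so the pipeline cannot be
  run end-to-end on heterogeneous clinical geometry without adding a
  normalization step.
* Lesion simulation is intensity-only by default; deformation-coupled
  lesions (e.g. ex-vacuo ventricular expansion) are not modelled.
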