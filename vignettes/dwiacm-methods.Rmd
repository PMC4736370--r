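---
title: "Microstructure and connectedness from diffusion MRI: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstructure and connectedness from diffusion MRI: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dwiacm` implements a complete analysis chain for assessing white-matter
tissue **microstructure** (diffusion-tensor scalars) and **connectedness**
(Anatomical Connectivity Mapping, ACM) simultaneously, with nonparametric
voxelwise group inference. This vignette explains the models, the tunable
parameters, and the design decisions that were genuinely open, so that a
user can judge what the package's validation does — and does not — show.

## The diffusion tensor and its scalars

Each voxel's diffusion-weighted signal is modelled as
$S(g, b) = S_0 \exp(-b\, g^\top D g)$ with $D$ a symmetric positive 3x3
tensor (mm²/s). Two fits are provided:

* `fit_tensor_lls()` — ordinary least squares on
  $\log S = \log S_0 - b\, g^\top D g$. Exact on noiseless data, but the log
  transform distorts the error structure under magnitude (Rician) noise.
* `fit_tensor_nls()` — Levenberg–Marquardt least squares on the raw signal
  (analytic Jacobian, at most 100 iterations, objective tolerance 1e-10),
  initialised from the log-linear fit. A voxel that fails to converge keeps
  the initial estimate and is flagged. Fitting the untransformed signal is
  what makes the nonlinear route preferable at realistic SNR; the test suite
  verifies it is never less accurate than the log-linear fit at SNR 20.

From the eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$:
MD $= (\lambda_1+\lambda_2+\lambda_3)/3$, AD $= \lambda_1$,
RD $= (\lambda_2+\lambda_3)/2$, and
FA $= \sqrt{3/2}\,\lVert\lambda - \text{MD}\rVert / \lVert\lambda\rVert$
(the standard definitions). Numerical conventions: eigenvalues are clamped
below at $\varepsilon = 10^{-12}$ mm²/s before scalar computation (keeps FA
in $[0,1]$, avoids NaNs); an all-zero tensor has FA defined as 0; in
near-degenerate voxels ($\lambda_1 \approx \lambda_2$) the principal
eigenvector is whichever the symmetric eigendecomposition returns —
downstream tracking treats orientation uncertainty explicitly, so the
tie-break is immaterial.

## Probabilistic tractography

Streamlines are propagated by Euler integration in world millimetres:
$x_{t+1} = x_t + \ell\, d_t$, with the direction $d_t$ sampled per step from
a per-voxel **Watson orientation mixture** (`orientation_model`): up to $K$
compartments per voxel, each with a mean axis, a concentration $\kappa$, and
a fraction. Defaults follow common whole-brain probabilistic-tracking
practice: step length $\ell = 0.5$ mm, at most 2000 steps per direction,
curvature threshold 0.2 interpreted as the **minimum cosine between
successive steps** (about 78.5°; a violating draw terminates the streamline,
with no re-sampling), 500 streamlines per seed voxel. Tracking is
bidirectional from every seed (voxel centre, no jitter by default) and the
reversed first half is concatenated with the second. There is no FA stopping
threshold by default; termination occurs on leaving the mask, on a curvature
violation, or at the step cap.

The Watson model is a deliberate parametric stand-in for a sampled
fibre-orientation posterior (such as an MCMC crossing-fibre posterior). It
is isolated behind the `orientation_model` contract so that a bootstrap or
MCMC backend could be substituted without touching the tracker. Two
constructors exist: from a fitted tensor field (one compartment per voxel,
$\kappa = \kappa_{\max}\,\text{FA}^2$, default $\kappa_{\max} = 200$), and —
for phantoms — directly from the known compartments, including crossing
voxels. With $\kappa = \infty$ the sampler returns the mean axis exactly and
probabilistic tracking degenerates to deterministic principal-eigenvector
tracking; the tests assert exact agreement with an independently written
deterministic tracker in this limit.

Reproducibility: every streamline draws from its own counter-based RNG
stream keyed by `(seed, voxel index, streamline index)`, so whole-brain
tracking is bit-identical across runs and iteration orders given one seed,
and independent of R's global RNG.

## Anatomical Connectivity Mapping

`acm_from_streamlines()` counts, per voxel, the number of streamlines that
traverse it, with **unique visitation** (a streamline looping back through a
voxel counts once) — matching the path-distribution reading of "number of
streamlines that project through each voxel". Traversal is determined by
sampling each segment at intervals of at most half the smallest voxel edge;
an exact 3-D line–voxel walk is available (`method = "exact"`) and serves as
the slower oracle. Counts are **not** normalised by brain size: brain size
enters the group model as a covariate instead. Because every masked voxel
seeds `n_per_voxel` streamlines that all traverse their own voxel, each
masked voxel has the analytic floor ACM $\ge$ `n_per_voxel`. Seed and count
masks are separate arguments (a grey+white seed mask with white-only
counting is legitimate); by default they coincide.

## Group statistics

Per-subject maps are smoothed with an isotropic Gaussian kernel of 4 mm
FWHM ($\sigma = \text{FWHM}/2\sqrt{2\ln 2}$ per axis, normalised discrete
kernel, zero padding). The "4 mm" figure is read as an isotropic FWHM in mm;
it is configurable.

The GLM uses cell-means group coding (one indicator per group, no
intercept) plus nuisance covariates age, gender (0/1) and brain-mask voxel
count; continuous covariates are mean-centred so group contrasts compare
adjusted group means. Contrasts: `"A>B"` one-tailed t; `"group"` omnibus F.
Tail direction is always an explicit property of the contrast.

Inference is nonparametric: **Freedman–Lane** permutation (the default
scheme of the reference implementations of randomise-style inference) —
nuisance covariates are regressed out, residuals are permuted over subjects,
the full model is refitted — with **TFCE** enhancement
($E = 0.5$, $H = 2$, 26-connectivity, 100 integration steps,
$dh = \max/100$; these are the enhancement's recommended defaults, all
exposed) and max-statistic FWE correction:
$p(v) = (1 + \#\{\text{perm max} \ge \text{obs}(v)\})/(n_{\text{perm}}+1)$.
The observed labelling always counts, so the smallest attainable p is
$1/(n_{\text{perm}}+1)$; when fewer distinct subject permutations exist than
requested, all are enumerated with a warning. The partition into interest
and nuisance is by design column (group indicators vs covariates) — a
documented simplification of contrast-space partitioning that coincides
with it for the group contrasts used here. Small-volume correction re-forms
the max-statistic null over an a-priori ROI from the retained
per-permutation enhanced maps; ROI p-values can only shrink relative to
global FWE p-values, and the SVC report (surviving voxels, peak p, peak
coordinate) mirrors the tract-table layout common in this literature.
Whether an omnibus F gate should be applied voxel-wise or globally before
post-hoc t-tests is left to the user; the package computes both statistics
independently and the examples gate globally (run the F test first, then
post-hoc t contrasts).

`residual_normality_check()` (Lilliefors test per voxel) quantifies the
non-normality that motivates the permutation route, and
`icv_correlation()` checks whether ROI-mean ACM depends linearly on
intracranial volume per group — the confound check for a streamline count
that could scale with brain size.

## What the synthetic cohorts emulate

The synthetic-data module generates DWI phantoms with known ground truth so
that every stage is testable without real acquisitions:

* **Acquisition**: 61 approximately uniform directions (electrostatic
  repulsion on the half-sphere, energy-minimised with multi-start BFGS) at
  b = 1500 s/mm² plus 10 b = 0 volumes; SNR 20 on b = 0 (Rician noise,
  $M = |(S+n_1) + i n_2|$), a typical regime for this b-value.
* **Geometry**: tube tracts (polyline plus radius) on a 20³ grid of 2 mm
  isotropic voxels by default — a desk-scale stand-in for whole-brain 2.3 mm
  data; crossing voxels carry one compartment per tube with equal fractions
  and a multi-tensor mixture signal (sufficient to exercise crossing-capable
  tracking; no attempt to simulate an MCMC posterior).
* **Lesion model**: a sphere in which each compartment's $\lambda_\perp$ is
  multiplied by $f \ge 1$. This produces exactly the FA-down / RD-up /
  MD-up / AD-unchanged signature of a radial-diffusivity insult, with a
  closed-form effect size.
* **Cohorts**: groups NS (n = 15, $f = 1$), LB (n = 15, $f = 1.5$) and CB
  (n = 12, $f = 2$) by default, mirroring a sighted / late-onset /
  congenital three-group structure in size and ordering of severity.
  Between-subject variability is multiplicative log-normal jitter (5%) on
  eigenvalues and background diffusivity; ages are drawn per group
  (means 42–52, sd 13–15, matching published group summaries only loosely —
  individual covariates are synthetic); gender is Bernoulli(1/2); the
  brain-mask voxel-count covariate emulates intracranial-volume variation
  as a 3% log-normal jitter of the grid count (it is a covariate, not a
  geometric change — cohorts share one space by construction, so spatial
  normalisation is out of scope).

What passing tests therefore show: correctness of the estimators, the
tracking and counting contracts, calibration of the permutation inference,
and reproduction of the directional effect structure under a known
ground-truth insult. What they do not show: robustness to real-world
artefacts (susceptibility distortion, motion, eddy currents), registration
error, anatomical mask imperfection, or realistic head geometry — all
deliberately outside the generator.

## Calibrating tracking dispersion for cohort ACM

For cohort-level connectivity analysis (`cohort_maps()`), the FA-to-kappa
scale defaults to $\kappa_{\max} = 15$ rather than the single-subject
default of 200. The reason is quantitative. With a Watson concentration
$\kappa$, the probability that a sampled step violates the curvature cosine
threshold $c = 0.2$ is approximately
$\int_0^{c} e^{\kappa t^2}\,dt \,/\, \int_0^1 e^{\kappa t^2}\,dt$, which
collapses exponentially in $\kappa$: it is negligible above $\kappa \approx
10$ and becomes appreciable only below $\kappa \approx 5$. At
$\kappa_{\max} = 200$, even a strongly damaged segment (FA 0.5, $\kappa
\approx 50$) transmits essentially every streamline, and connectivity
mapping degenerates into a constant map — the regime in which ACM carries no
information beyond geometry. At $\kappa_{\max} = 15$, healthy tract voxels
(FA $\approx 0.8$, $\kappa \approx 10$) still transmit reliably while
lesioned voxels (FA $\approx 0.6$, $\kappa \approx 5$) lose a substantial
fraction of through-traffic, so focal damage accumulates into a
connectivity deficit along the tract — the phenomenon ACM exists to detect,
and the desk-scale analogue of posterior orientation uncertainty growing
steeply as anisotropy falls. This is a generator/analysis calibration fixed
before the validation suite was frozen, not a per-dataset tuning knob.

## Problem sizes

The validation suite and the acceptance script run at deliberately modest
sizes chosen as the package's reference conditions: 20³-voxel phantoms for
single-subject contracts; 500 replicate voxels per FA level for the
recovery study; 50 streamlines per voxel for cohort ACM (the per-voxel
count affects only Monte-Carlo precision of the counts — the tests verify
that map reproducibility increases monotonically with it, so scaling it up
only sharpens maps); 500 permutations for all permutation tests (minimum
attainable p 1/501; production analyses would use 5000); 20 replicate null
cohorts of 2 x 6 subjects at 10³ voxels for the FWE calibration.

## Known limitations

* The Watson orientation model has a single concentration per compartment;
  it does not represent asymmetric or multi-modal orientation uncertainty.
* The Freedman–Lane partition is by design column, not by contrast space.
* Gender is coded 0/1 and enters linearly; the bvec sign/axis convention of
  scanner exports is not auto-detected (irrelevant for synthetic data; a
  flip is a one-line change to the gradient table).
* TCK is the only streamline container dialect implemented (Float32LE).
* The exact line–voxel counting oracle and the half-voxel sampled traversal
  can differ on corner-clipped voxels; the sampled rule is the documented
  default.
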