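---
title: "FA-threshold sensitivity of atlas-based neonatal DTI segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FA-threshold sensitivity of atlas-based neonatal DTI segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

Atlas-based analysis of neonatal diffusion tensor imaging assigns every
voxel a named white-matter (WM) region via a co-registered label atlas, then
refines each region with scalar thresholds before averaging diffusion
measures over it. Neonatal WM is only partially myelinated, so its
fractional anisotropy (FA) sits far below adult values, and the FA cutoff
used to separate WM from grey matter (GM) is consequential: a high (adult)
cutoff discards much of the developing WM, a low one admits GM and
partial-volume voxels. `dtithresh` quantifies that sensitivity.

The masking cascade per subject and region is:

1. **Atlas label**: all voxels carrying the region's integer label.
2. **CSF exclusion**: drop voxels with trace $> 0.006\ \mathrm{mm^2/s}$
   (strict; a voxel exactly at the cutoff is retained). The survivors form
   the *base* mask, the denominator for all relative volumes.
3. **FA thresholds**: for each cutoff $t \in \{0.15, 0.20, 0.25\}$, keep
   base voxels with $\mathrm{FA} > t$ (strict; a voxel exactly at $t$ is
   excluded). Nesting across cutoffs holds by construction.
4. **Minimum-voxel rule**: any (region, condition) cell with fewer than 10
   voxels is flagged excluded and contributes no statistics. The flag is per
   subject, region *and* condition: a region lost at FA>0.25 still
   contributes at FA>0.15. Listwise deletion across conditions would discard
   usable data and is not applied.

Per cell the package records the voxel count, the volume as a percent of the
base mask (100 by definition for the base condition; the raw atlas-label
denominator is kept as a diagnostic column), and unweighted voxel means of
FA, axial diffusivity (AD $= \lambda_1$) and radial diffusivity (RD $=
(\lambda_2+\lambda_3)/2$). Across subjects it computes, per region and
condition: mean, sample SD ($n-1$), the coefficient of variation
$\mathrm{CV} = \mathrm{SD}/\mathrm{mean}$, and Student-$t$ 95% confidence
intervals. CV is reported both for volumes and for the scalar means, since
either can be the variability measure of interest; neither is privileged.

Region-wise comparison across the four conditions uses the Kruskal–Wallis
rank test (tie-corrected $H$, $\chi^2_{3}$ p-value), with adjacent-condition
two-group contrasts as a secondary output. Significance uses the strict
inequality $p < \alpha/k$ with the exact fraction (e.g. $0.05/12 =
0.0041\overline{6}$, presented as 0.00417), because the rounding direction
matters at the boundary. The family size defaults to the number of distinct
region *names* — left/right homologues count once, matching a twelve-region
analysis set — and is a configuration knob, since one could also argue for
24 sided tests. When a pooled comparison has $n \le 30$ a seeded Monte-Carlo
permutation p-value (10,000 resamples by default) is reported alongside the
$\chi^2$ approximation, which is weakest exactly there.

## Tensor model

Real-data mode consumes precomputed FA/trace/AD/RD maps directly. Synthetic
mode (and any raw-DWI input) fits the diffusion tensor per voxel by ordinary
log-linear least squares on
$\ln(S_i/S_0) = -b\, g_i^\top D\, g_i$, with $S_0$ the mean of the $b=0$
volumes. Unweighted OLS is the reproducible baseline; weighted and nonlinear
fitters are deliberately out of scope. Three numerical policies matter:

- **Invalid voxels**: $S_0 \le 0$ or any $S_i \le 0$ invalidates the voxel.
  Flooring the signal at machine epsilon before the log would fabricate
  plausible tensors; zero-filling would let such voxels pass FA thresholds
  as non-WM. A validity mask propagates instead.
- **Negative eigenvalues**: retained (and counted) for trace/AD/RD, clamped
  to zero only inside the FA formula. CSF is where clamping would bite
  hardest, and trace-based CSF exclusion needs the raw eigenvalue sum;
  clamping only FA keeps it in $[0,1]$. An all-zero eigenvalue triple
  defines FA as 0, not NaN.
- **Eigendecomposition**: a vectorized closed-form (trigonometric) solver for
  symmetric $3\times 3$ matrices supplies eigenvalues for whole volumes; when
  eigenvectors are requested, per-voxel LAPACK decompositions are used so
  values and vectors are mutually consistent.

"Trace" throughout is the eigenvalue sum $\lambda_1+\lambda_2+\lambda_3$
(three times the mean diffusivity), consistent with the magnitude of the
0.006 mm²/s CSF cutoff (≈ 3 × free-water diffusivity at body temperature).

## The synthetic phantom

The phantom exists so the full pipeline can be exercised, calibrated and
tested without clinical data. Geometry is deliberately abstract: the
analysis consumes co-registered labels plus realistic scalar contrast, and
registration is out of scope, so anatomy would add nothing testable. Each of
12 bilateral WM regions is a rectangular block (mirrored across the
mid-sagittal plane) inside a GM interior, wrapped in a 2-voxel GM shell and
a 2-voxel CSF rim. The default grid is $48^3$ voxels of
$1.5625 \times 1.5625 \times 3$ mm — the in-plane resolution of a 20 cm
field of view on a 128×128 matrix — giving 800-voxel regions with 384-voxel
interiors.

Compartments:

- **WM**: axially symmetric tensors ($\lambda_2 = \lambda_3$) solved
  analytically so each region's noise-free FA equals the subject's target FA
  and $\lambda_1$ equals the target AD. Region targets span FA 0.15 (an
  anterior-corona-radiata-like, least mature, crossing-fiber region) to 0.50
  (a posterior-limb-like, most mature region), with AD in the neonatal range
  1.4–1.9 × 10⁻³ mm²/s and the corpus callosum given the highest AD.
  Between-subject variability enters as a per-region Gaussian FA offset
  (SD 0.02, roughly the spread of published neonatal regional means).
  Principal orientations are fixed per region, sweep smoothly across it, or
  mix two orthogonal populations voxel-wise ("crossing", fraction 0.3 for
  corona-radiata-like regions); the crossing mixture is calibrated by root
  finding so its *effective* FA still hits the target.
- **GM**: FA drawn uniformly in [0.02, 0.12] (below every cutoff by
  construction) at mean diffusivity 1.1 × 10⁻³ mm²/s.
- **CSF**: isotropic with trace 9 × 10⁻³ mm²/s (diffusivity 3 × 10⁻³ per
  axis), safely above the exclusion cutoff.
- **Partial volume**: every voxel within one voxel of a compartment border
  receives the 7-point-stencil average of the adjacent pure tensors. This
  reproduces the boundary-voxel failure mode that makes low thresholds
  risky; it is the phantom's only source of within-region noise-free
  heterogeneity. Interior voxels carry the subject target exactly — the
  within-region noise-free FA spread is set to zero by design, so that
  calibration is exact and all residual voxel scatter is attributable to
  measurement noise.

Signals follow the monoexponential model $S = S_0\exp(-b\,g^\top D g)$ over
25 electrostatic-repulsion directions plus three $b=0$ volumes at
$b = 1000\ \mathrm{s/mm^2}$ (the direction set ships as an FSL-style
bvec/bval fixture). Noise is Rician — the magnitude of the complex
Gaussian-perturbed signal, the correct model for magnitude MR images — with
channel SD $S_0/\mathrm{SNR}$; $\mathrm{SNR} = \infty$ is a noise-free
sentinel that returns exact signals and enables exact test oracles. The
cohort default is SNR 30: clinical neonatal EPI runs at roughly SNR 20 per
repetition on the $b=0$ image, and the emulated protocol averages two
repetitions ($\sqrt{2}$ gain). At that level the lowest-FA region drops
below the 10-voxel rule at FA>0.25 in most subjects while remaining fully
identifiable at FA>0.15 — the identifiability collapse that motivates
more inclusive neonatal thresholds.

What the phantom does **not** emulate: anatomy and registration error, EPI
distortion, motion, eddy currents, spatially varying noise, within-region
maturation gradients, and realistic region-size differences (all blocks are
equal-sized). Passing tests therefore demonstrate correctness of the
*analysis* under known contrast, noise and partial volume — not robustness
to registration or acquisition artifacts, which are upstream of this
pipeline by design.

## Numerical and design choices

- Strict inequalities at both thresholds, ties resolved as stated above.
- Left and right homologues are distinct regions in every table; midline
  structures carry a single mask.
- The crossing-mixture calibration brackets its root in population FA
  $[\mathrm{target}, 0.70]$; axially symmetric positivity bounds FA below
  ≈ 0.7035, and requested FA/AD pairs without a positive-eigenvalue solution
  raise a parameterization error.
- Per-subject seeds are derived from the master seed, so a cohort is
  bit-reproducible from `(config, seed)` alone; every output directory
  carries a manifest with the configuration echo, seed and md5 hashes.
- Student-$t$ CIs rather than normal: at $n = 45$ the difference is
  negligible, and small phantom cohorts benefit.

Problem sizes were chosen for fast, deterministic test runs: the default
study uses 8 subjects on a $48^3$ grid (a full pipeline run takes well under
a minute on one CPU), parameter-recovery checks use dedicated two-region
phantoms with ≥ 1500 interior voxels per region, and permutation oracles
enumerate exhaustively up to $n = 8$ with 10–20 thousand Monte-Carlo
resamples elsewhere.

## Known limitations

- At realistic SNR, magnitude (Rician) noise plus eigenvalue repulsion
  inflates fitted FA where true FA is low: in a true-FA-0.15 region at
  SNR 20 the package's own recovery checks measure a mean inflation of
  0.03–0.04, while a true-FA-0.5 region is recovered well within 0.01. This
  is a property of unweighted log-linear estimation on magnitude signals,
  not of the phantom, and it is the quantitative face of the finding that
  low-FA regions yield the least reliable neonatal DTI measures.
- The $\chi^2$ p-value of the Kruskal–Wallis test is asymptotic; at the
  small per-condition counts of desk-scale cohorts it can differ from the
  exact permutation p by far more than Monte-Carlo error (e.g. 0.05 vs 0.10
  on two groups of three). Both are reported when $n \le 30$; the
  permutation p is the one validated against exhaustive enumeration.
- Percent-volume CV is 0 for the base condition by construction (the base
  is its own denominator); the CV of absolute voxel counts is computed as
  well and is the analogue of a variability analysis of regional volumes.
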