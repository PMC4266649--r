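# dtithresh

Threshold sensitivity of atlas-based white-matter segmentation for neonatal
diffusion tensor imaging (DTI).

## The problem

Neonatal white matter (WM) is only partially myelinated: its fractional
anisotropy (FA) is far below adult values, so the FA cutoff used to refine
atlas-defined regions before averaging diffusion scalars is consequential.
The adult convention FA > 0.25 discards much of the developing WM and makes
regional measures unstable; very low cutoffs admit grey matter and
partial-volume voxels. `dtithresh` is for imaging researchers who want to
quantify exactly how that choice changes regional volumes, scalar means and
their inter-subject variability — either on their own co-registered scalar
maps and label atlas (NIfTI), or on a fully synthetic neonatal brain phantom
so no clinical data is required.

## What it computes

Per subject and region, the masking cascade

1. atlas label →
2. CSF exclusion by **trace > 0.006 mm²/s** (the *base* mask) →
3. FA thresholds **FA > 0.15 / 0.20 / 0.25** (strict, nested) →
4. a **minimum-voxel rule** (cells with < 10 voxels are excluded),

then voxel counts, volume as percent of the base mask, and unweighted mean
FA, axial diffusivity (AD = λ₁) and radial diffusivity (RD = (λ₂+λ₃)/2).
Across subjects: mean, SD, coefficient of variation CV = SD/mean, and
Student-t 95% CIs per region × condition; region-wise Kruskal–Wallis tests
(tie-corrected H, χ² p, plus a seeded permutation p at small n) across the
four conditions with Bonferroni control (e.g. 0.05/12 → p < 0.00417), and
adjacent-threshold pairwise contrasts.

Raw DWI can be fitted on the way in: per-voxel log-linear least squares on
ln(S/S₀) = −b gᵀDg, eigendecomposition, and FA/trace/AD/RD maps. The
synthetic mode generates seeded cohorts — a geometric label template (12
bilateral WM regions spanning FA 0.15–0.5, GM, CSF, partial-volume
boundaries), ground-truth tensor fields with between-subject variability,
and Rician-noise DWI at 25 directions + 3 b0, b = 1000 s/mm².

## Worked example

```r
library(dtithresh)

cohort <- simulate_phantom_cohort(n_subjects = 8, seed = 42)
study  <- threshold_study(cohort, seed = 42)
print(study)
```

```
DTI threshold-sensitivity study
  subjects: 8   regions: 24   conditions: base, FA>0.15, FA>0.20, FA>0.25
  cohort-mean volume retained (% of CSF-excluded base):
    base: 100.0   FA>0.15: 93.3   FA>0.20: 77.5   FA>0.25: 58.4
  mean CV of regional volume across subjects:
    base: 0.00   FA>0.15: 0.05   FA>0.20: 0.16   FA>0.25: 0.28
  Kruskal-Wallis across conditions at alpha = 0.00417 (0.05/12):
    mean_fa: 12/24 region-sides significant
    mean_ad: 16/24 region-sides significant
    mean_rd: 2/24 region-sides significant
```

Reading it: raising the cutoff from 0.15 to 0.25 discards a third of the
retained volume (93% → 58% of the CSF-excluded base) and multiplies the
inter-subject variability of what remains (mean CV 0.05 → 0.28), and in half
the region-sides the regional mean FA under the four conditions differs
significantly at the corrected alpha — i.e. the threshold choice, not
biology, moves the numbers. High-FA regions (internal-capsule-like) barely
shift; the lowest-FA region shifts most and falls below the 10-voxel rule at
FA > 0.25 in most subjects. `summary(study)` prints region × condition grids
with CIs, `plot(study)` draws grouped bars, `write_study(study, dir)` emits
CSV/JSON tables, a Markdown report and a hashed manifest.

Real-data mode (registration is the caller's responsibility):

```r
run_threshold_pipeline("out", mode = "real",
                       scalar_files = list(list(fa = "s1_fa.nii.gz",
                                                trace = "s1_trace.nii.gz",
                                                ad = "s1_ad.nii.gz",
                                                rd = "s1_rd.nii.gz")),
                       label_file = "atlas_labels.nii.gz",
                       region_table = my_regions)
```

A thin command-line wrapper with `phantom` and `analyze` subcommands lives
at `inst/cli/dtithresh.R`.

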