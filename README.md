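# igrtmotion

Motion, margin and dose-impact analysis for image-guided radiotherapy of
prostate cancer, for medical physicists and radiotherapy researchers who
work with endorectal-balloon (ERB) and fiducial-marker (FM) protocols.

Patients treated with an air-filled ERB and three implanted gold markers
are imaged daily: a cone-beam CT (CBCT) at setup and a pair of orthogonal
kV radiographs before and after each fraction. The balloon's day-to-day
displacement measures **interfractional** setup error; the markers' drift
within a fraction measures **intrafractional** motion. `igrtmotion`
implements the complete analysis chain on top of that data model:

- **Segmentation** of ERB (largest dark component, hole-filled) and FMs
  (bright 26-connected components) from 3D volumes, with centroids,
  balloon shape descriptors and inter-marker distances.
- **Reference-scan selection** per patient: the CBCT whose FM-to-ERB
  centroid distance Δd_absolute is closest to (and within 1 mm of) the
  planning CT's value.
- **Error decomposition** per axis (LR/SI/AP): group mean μ, pooled SD,
  systematic error Σ = SD over patients of the per-patient mean shifts,
  random error σ = RMS of the per-patient SDs.
- **CTV-to-PTV margins** after quadrature combination of inter- and
  intrafractional components:
  Stroom `2.0 Σ + 0.7 σ` and van Herk `2.5 Σ + 0.7 σ`.
- **Dose impact**: rigid isocenter-shift accumulation of per-fraction dose,
  cumulative DVHs at 0.5 Gy resolution, and a paired Wilcoxon signed-rank
  comparison of motion-perturbed vs static plans.
- **Offline adaptive replanning**: a containment-based decision rule on the
  first four fractions, plus initial-vs-adapted plan margin comparison.
- **A digital phantom** that generates whole cohorts (geometry, Gaussian
  motion with known Σ/σ truth, CT/CBCT-like volumes, a static dose grid)
  so the entire pipeline is testable without clinical data. Volume I/O is
  NRRD and NIfTI; tables are CSV/JSON.

## Worked example

Margins from a published-style error table (Σ and σ per axis in mm,
inter- and intrafractional):

```r
library(igrtmotion)
inter <- error_stats(sigma_sys = c(1.12, 2.28, 1.48),
                     sigma_rand = c(1.89, 3.19, 2.10))
intra <- error_stats(sigma_sys = c(0.44, 0.69, 0.80),
                     sigma_rand = c(1.91, 2.30, 2.27))
format_margin_block(margin_report(inter, intra))
#>            LR   SI   AP
#> Sigma    1.20 2.38 1.68
#> sigma    2.69 3.93 3.09
#> Stroom   4.29 7.52 5.53
#> van Herk 4.89 8.71 6.37
```

Reading: combined systematic error in SI is 2.38 mm and random error
3.93 mm, so a van Herk PTV margin of 8.71 mm in SI (and 4.89/6.37 mm in
LR/AP) would cover the measured motion for 90 % of patients.

An end-to-end synthetic cohort — simulate, render, segment, select
references, extract shifts, decompose errors, compute margins, accumulate
motion dose, check the adaptation rule (about half a minute):

```r
report <- run_pipeline(pipeline_config(n_patients = 5, n_fractions = 10,
                                       seed = 1))
report
#> pipeline_report: 5 patients x 10 fractions (50 CBCTs)
#>
#> Interfractional error statistics (mm):
#>          LR    SI    AP
#> mu    -0.87 -3.62 -0.57
#> SD     2.46  3.66  2.88
#> Sigma  1.89  2.01  2.14
#> sigma  1.86  3.33  2.24
#>
#> Intrafractional error statistics (mm):
#>         LR   SI    AP
#> mu    0.10 0.06 -1.32
#> SD    2.00 2.27  2.44
#> Sigma 0.76 0.60  1.35
#> sigma 1.96 2.30  2.20
#>
#> CTV-to-PTV margins (mm):
#>            LR   SI   AP
#> Sigma    2.03 2.10 2.53
#> sigma    2.71 4.04 3.14
#> Stroom   5.96 7.03 7.25
#> van Herk 6.98 8.08 8.52
#>
#> DVH comparison (motion vs static): p = 1.000 (degenerate (all differences zero))
#> Adaptation decisions: 0 adapt / 5 keep
```

The measured statistics recover the generator's motion model (here the
default, set to the reported 31-patient cohort magnitudes) up to sampling
noise at 5 × 9 fractions; the degenerate DVH comparison says the phantom's
PTV margin absorbed every composed shift, so the motion-perturbed CTV dose
is identical to the static plan at 0.5 Gy resolution; and no patient
triggered the offline-replanning rule. `run_pipeline(cfg, output_dir =
"out")` additionally writes shift tables, error statistics, margin tables,
DVH curves, adaptation decisions and a provenance record (seed, config
hash, versions).

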