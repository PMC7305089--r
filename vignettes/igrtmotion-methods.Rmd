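---
title: "Motion, margins and dose impact in image-guided prostate radiotherapy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion, margins and dose impact: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igrtmotion)
```

## The problem

In external-beam radiotherapy of prostate cancer, the clinical target volume
(CTV) is expanded to a planning target volume (PTV) to absorb two kinds of
geometric uncertainty: *interfractional* setup error (day-to-day variation in
where the target sits at the start of each fraction) and *intrafractional*
motion (drift of the target during a fraction). Clinics that treat with an
air-filled endorectal balloon (ERB) and implanted fiducial markers (FM) can
measure both: the balloon's position in the daily cone-beam CT (CBCT) tracks
setup error, and the marker positions in orthogonal kV radiograph pairs taken
before and after each fraction track intrafraction drift.

`igrtmotion` implements the full analysis chain for this setting:
segmentation of ERB and FM from CT/CBCT-like volumes, selection of a
per-patient reference scan, decomposition of the measured displacements into
group-mean, systematic and random components, CTV-to-PTV margin computation,
propagation of the measured motion into structure DVHs under a rigid
isocenter-shift dose model, and an offline adaptive-replanning decision rule.
Because clinical image archives of this kind are not public, the package
ships a seeded digital phantom that generates whole cohorts with known
ground truth, so every stage is testable end to end.

## Error model and statistics

All displacements are mm triples in the patient frame: LR (left-right,
+left), SI (superior-inferior, +superior), AP (anterior-posterior,
+anterior). Axes are treated independently; rotations and deformation are
out of scope (the rigid-translation model is the standard first-order
treatment in the margin-recipe literature, and per-axis statistics are what
clinical reports tabulate).

For a cohort of $P$ patients with $F$ usable fractions each, let $x_{pf}$ be
the shift of patient $p$ at fraction $f$ along one axis. With
$m_p = \mathrm{mean}_f(x_{pf})$ and $s_p = \mathrm{SD}_f(x_{pf})$ (sample
SD, $n-1$), the cohort statistics are

* $\mu = \mathrm{mean}_p(m_p)$ — group systematic deviation,
* $\Sigma = \mathrm{SD}_p(m_p)$ — systematic error (1 SD),
* $\sigma = \sqrt{\mathrm{mean}_p(s_p^2)}$ — random error (RMS of the
  per-patient SDs),
* $\mathrm{SD}$ — pooled SD of all $x_{pf}$.

This is the van Herk-school convention. Two choices here were genuinely
open. First, the overall "SD" row could be the pooled SD or the mean of
per-patient SDs; the pooled SD is used because it satisfies
$\mathrm{SD}^2 \approx \Sigma^2 + \sigma^2$, which is how the published
cohort tables this package reproduces behave numerically (checked as a
property test on simulated cohorts). Second, $\sigma$ is the RMS rather than
the arithmetic mean of $s_p$, so that $\sigma^2$ is an unbiased estimate of
the random variance.

Inter- and intrafractional components are combined in quadrature,
$\Sigma = (\Sigma_\mathrm{inter}^2 + \Sigma_\mathrm{intra}^2)^{1/2}$ and
likewise for $\sigma$, and fed into two population margin recipes:

* Stroom: $2.0\,\Sigma + 0.7\,\sigma$,
* van Herk: $2.5\,\Sigma + 0.7\,\sigma$.

All chained computation uses unrounded intermediates; rounding (half away
from zero, 2 decimals) is applied only in display tables. On published
2-decimal inputs the difference between the two policies is at most
0.01 mm, which the test suite asserts; one published table cell (Stroom AP)
is reproducible only under rounded chaining, so agreement is asserted at
the 2-decimal level.

```{r margins}
inter <- error_stats(sigma_sys = c(1.12, 2.28, 1.48),
                     sigma_rand = c(1.89, 3.19, 2.10))
intra <- error_stats(sigma_sys = c(0.44, 0.69, 0.80),
                     sigma_rand = c(1.91, 2.30, 2.27))
format_margin_block(margin_report(inter, intra))
```

## Reference-scan selection

Interfractional shifts need a reference. Following the clinical procedure
this package models, the reference CBCT is chosen by internal consistency:
in every scan the Euclidean distance $\Delta d_\mathrm{absolute}$ between
the FM centroid (mean of the three marker positions) and the ERB centroid
is computed, and the fraction whose $\Delta d$ is closest to the planning
CT's value — and within 1 mm of it — becomes the reference. Ties break to
the earliest fraction; a patient with no scan within tolerance is excluded
from the interfractional analysis and reported. Interfractional shifts are
then ERB-centroid differences relative to the reference scan, whose own
shift is identically zero; the reference fraction is excluded from the
per-patient statistics by default (it is not an observation), leaving
$F - 1$ usable fractions.

## Segmentation

The in-silico scans contain three structures with widely separated
intensities: soft-tissue background, an air-filled balloon far below it,
and metal markers far above it. Segmentation is deliberately minimal and
transparent:

* **Markers** — voxels above a threshold, 26-connected components, size
  filter, unweighted voxel-centre centroids (the binary-image convention;
  no intensity weighting). Components are ordered canonically by SI, then
  LR, then AP so pre/post pairing is stable. Finding a number of markers
  other than the expected three raises a typed, countable error.
* **ERB** — largest 26-connected component below a threshold, interior
  holes filled, yielding centroid, volume, equivalent diameter and extents.

26-connectivity is used because marker blobs are small and noise can split
them; under 26-connectivity, fragments separated by less than one full
background voxel remain one component. Default thresholds are
calibration-free midpoints between the median (background) intensity and
the volume maximum (markers) or minimum (ERB). Percentile-based cutoffs
were considered and rejected: a fixed percentile lands inside a structure's
own intensity distribution whenever the structure's volume fraction is
comparable to the percentile, which truncates the measured balloon volume.
The midpoint rule keeps the measured ellipsoid volume within the
voxelisation error (< 5 %) of the analytic value and survives additive
Gaussian noise with SD up to roughly a third of the background-to-structure
contrast. Both thresholds remain explicit arguments everywhere.

## The digital phantom

The phantom emulates the data-generating process of an ERB/FM protocol at a
deliberately reduced scale:

* **Grid** — 96 × 96 × 64 voxels at 2 mm isotropic by default (the clinical
  3 mm slice / 512² matrix geometry can be configured, but the coarse grid
  keeps a full test run in minutes). All tests and shipped analyses state
  their grid.
* **Anatomy** — ellipsoids: an ERB of ~64 cm³ (semi-axes 23 × 33 × 20 mm,
  emulating a balloon inflated with ~65 cm³ of air) inside a rectum
  ellipsoid; a prostate-sized CTV (semi-axes 20 × 18 × 12 mm) anterior to
  it; a PTV grown by a per-axis margin, default (5, 9, 7) mm — at or above
  the van Herk margins the reported cohort statistics produce, matching the
  clinical situation in which the applied margin covered the measured
  motion. Three markers sit in an apex/base pattern (two inferior, one
  superior) with seeded per-patient jitter and a minimum-separation
  constraint.
* **Intensities** — HU-like levels: background 30, balloon −980, markers
  3000, plus additive Gaussian noise (default SD 20).
* **Motion** — per axis and per component (inter, intra), patient $p$ draws
  a systematic offset $m_p \sim N(\mu_\mathrm{true}, \Sigma_\mathrm{true}^2)$
  once and each fraction adds $e_{pf} \sim N(0, \sigma_\mathrm{true}^2)$.
  The default generator parameters are the published 31-patient cohort
  values (e.g. SI inter: $\Sigma$ 2.28 mm, $\sigma$ 3.19 mm). Gaussian form
  is an assumption — the source analyses report only per-axis moments — but
  it is the distribution under which the margin recipes were derived.
* **Rendering** — shapes are translated analytically *before* voxelisation,
  so ground-truth centroids are exact and sub-voxel shifts are meaningful;
  markers render as ~3×3×3-voxel blobs (a 3.5 mm-radius sphere on the 2 mm
  grid). Intrafractional data are generated directly as pre/post marker
  *coordinates* (no radiograph simulation), mirroring the fact that in the
  clinic these come from 2D image pairs, not volumes.
* **Dose** — a static IMRT-like field: exactly the prescription (50.4 Gy,
  28 × 1.8 Gy) everywhere inside the PTV, with a Gaussian-shoulder falloff
  outside parameterised by the 50 %-dose distance (default 10 mm). No beam
  model, no plan optimisation.

What the phantom does *not* emulate — CBCT reconstruction artifacts,
organ deformation, rotations, bladder filling, realistic dose gradients
inside the PTV — bounds what passing tests show: they validate the
*analysis chain* (segmentation → reference → statistics → margins → DVH →
adaptation) against known truth, not the imaging physics of real scanners.

A 31-patient × 28-fraction cohort produces exactly 868 CBCT-like volumes
and 1736 intrafraction records, the bookkeeping of the clinical dataset it
stands in for. Volumes are rendered lazily (`cohort_volume()`); the cohort
object stores geometry, true shifts and marker coordinates only, since 868
materialised volumes would occupy ~4 GB.

## Dose accumulation and DVH comparison

Motion is propagated into dose with the rigid isocenter-shift model: the
accumulated dose in structure voxel $v$ is
$\sum_f (d_\mathrm{fx}/D)\, \mathrm{dose}(v + s_f)$, where $s_f$ is the
fraction's composed shift, $d_\mathrm{fx}$ the fraction dose and $D$ the
prescription. Sampling is trilinear; shifted sample positions leaving the
grid clamp to the edge dose (zero-padding is available by flag) and are
counted in a warning. With all shifts zero the static dose is reproduced
exactly, which anchors the motion-vs-static comparison.

The composed per-fraction shift is the interfractional setup residual plus
half the pre-to-post intrafraction displacement — the time-averaged target
position under a linear drift. The weight is exposed (`intra_weight`)
because the clinical analyses this package models state that both
components were applied but not their composition rule.

DVHs are cumulative ($V(t)$ = percent of structure volume receiving at
least $t$ Gy) on a fixed grid of 0–59.5 Gy in 0.5 Gy steps (120 points);
statistical comparisons drop the final empty bin, giving the conventional
119 points at 0.5 Gy resolution. Mean curves across patients carry per-bin
sample SDs. Motion and static mean curves are compared per bin with a
two-sided Wilcoxon signed-rank test at $p = 0.05$: zero differences are
removed (all-zero comparisons are reported as degenerate with $p = 1$),
the exact null distribution is enumerated over all $2^n$ sign assignments
for $n \le 12$ (this handles ties, unlike the closed-form distribution),
and larger $n$ uses the normal approximation with tie and continuity
correction. Whether the clinical test paired DVH bins or some other
119-point summary is ambiguous in the source; per-bin pairing is
implemented and noted as an interpretation.

## Offline adaptation rule

Clinically, the first four fractions are inspected and a new planning CT is
acquired if the balloon and anterior rectal wall sit outside the planning
rectal contour — a visual judgement. The package operationalises it: the
containment fraction $|ERB \cap rectum|/|ERB|$ is computed for the first
four fraction scans, and adaptation triggers when at least 2 of 4 fractions
fall below 0.9. Both parameters are configuration, and the defaults are
explicit stand-ins chosen to be conservative (a single bad day does not
trigger replanning; a systematic displacement does) — they are not a
published rule. Adaptation itself is simulated by re-zeroing the patient's
systematic offset from fraction 5 on (a new planning CT re-references the
geometry) while random motion continues; on planted cohorts this reproduces
the expected drop in recomputed $\Sigma$.

## Numerical choices and degenerate inputs

* Connected-component labelling is iterative minimum-label propagation,
  vectorised over foreground voxels on a zero-padded array; it is validated
  against a queue-based flood fill on random small volumes.
* Hole filling classifies 6-connected background components that cannot
  reach the mask's bounding-box border as interior holes.
* Trilinear sampling is exact at voxel centres; out-of-lattice points clamp
  (default) or read zero.
* Ties in reference-scan selection break to the earliest fraction;
  an exactly-met tolerance (|Δd difference| = 1 mm) is rejected.
* Sample SDs use $n-1$ throughout; a single-patient cohort raises a typed
  error ($\Sigma$ undefined), as does a single-fraction series.
* All randomness flows from one top-level integer seed through
  deterministic per-stage derived seeds; identical configuration and seed
  reproduce every number bit for bit.

## Problem sizes in the shipped analyses

The package's own test suite and the reproduction script run, by choice, at
sizes that keep a complete run in a few minutes while leaving the
statistical assertions well-powered: statistical recovery uses 200
replicates of 31 × 28 cohorts (pure sampling, no rendering); rendering
fidelity uses one planning scan plus 50 fraction scans on the default grid;
the dosimetric null result uses 20 replicate 11-patient cohorts on the
shared dose grid; end-to-end pipeline checks use compact half-scale
phantoms. The margin arithmetic is exact and size-independent.

## Known limitations

* Rigid, translation-only motion; no rotations, deformation or
  bladder-filling effects.
* The synthetic dose field is flat inside the PTV, so motion can only
  reduce CTV dose; real plans carry internal gradients and hot spots.
  The dosimetric null result should be read as "the margin absorbs the
  measured motion", not as a statement about OAR dose.
* Thresholding segmentation presumes the high-contrast ERB/FM setting; it
  is a faithful minimal reconstruction of the in-house tool it models, not
  a general CBCT segmenter.
* The adaptation trigger is an operationalised stand-in for a clinical
  visual decision.
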