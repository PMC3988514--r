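---
title: "Simulating and correcting gamma-camera differences in brain SPECT Z-score analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and correcting gamma-camera differences in brain SPECT Z-score analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Brain perfusion SPECT Z-score analysis scores a patient volume against a
normal database (NDB) of voxel-wise means and SDs. Every volume entering
the analysis is smoothed and proportionally scaled so its brain-mask mean
equals a fixed target; the Z map is then

$$Z(v) = \frac{\mu_{\mathrm{NDB}}(v) - x(v)}{\sigma_{\mathrm{NDB}}(v)},$$

with positive $Z$ marking a count decrease (the clinical hypoperfusion
display convention). When the patient camera differs from the NDB camera,
the patient volume is first multiplied voxel-wise by a count-ratio
compensation map $R(v) = I_{\mathrm{ref}}(v) / I_{\mathrm{tgt}}(v)$ built
from a common object imaged on both systems. `spectharm` simulates the
entire chain so that the choice of that common object can be studied.

Acquisition is simulated directly in the reconstruction domain:

$$I = \mathrm{Chang}^{?}\Big(B_{f_c,n}\big(\mathrm{Pois}\{ s \cdot
      G_{\mathrm{FWHM}}( a \cdot A_\mu \cdot S ) \}\big)\Big)$$

where $a$ is the phantom activity, $A_\mu$ the mean attenuation survival
factor $\tfrac1{|D|}\sum_{d \in D} e^{-\int \mu\,dl}$ over a direction set
$D$, $S$ a smooth camera sensitivity field, $G$ a Gaussian point-spread
blur, $\mathrm{Pois}$ Poisson sampling after scaling the total to the
camera's count budget, $B$ the isotropic Butterworth post-filter
$1/\sqrt{1 + (f/f_c)^{2n}}$, and $\mathrm{Chang}^{?}$ an optional
first-order Chang correction (division by $A_{\mu_0}$ computed with an
assumed uniform $\mu_0$ over the object outline). Projection-space physics
— filtered back-projection itself, scatter, septal penetration, energy
resolution — is deliberately not modelled: all evaluated quantities operate
on reconstructed, aligned volumes, and a projection model would add cost
without touching any of them. For the same reason, anatomical
standardization is replaced by construction-time alignment: every phantom
and subject lives on one common grid (default $64^3$ at 3.5&nbsp;mm
isotropic).

## Tunable parameters

| Parameter | Default | Unit | Rationale |
| --- | --- | --- | --- |
| `gm_wm_ratio` | 4 | — | conventional gray:white fill contrast of the physical layered phantom |
| `fill` | 0.3 | activity/voxel | the phantoms' fill level (0.3 MBq/ml in the physical protocol) |
| `mu_soft` | 0.1 | cm⁻¹ | the Chang coefficient used clinically for ⁹⁹ᵐTc brain SPECT |
| `skull_mu` | 0.15 | cm⁻¹ | plausible bone excess over soft tissue; only its being larger matters |
| PSF FWHM | 8 / 10 | mm | reference vs target camera stand-ins; consoles equalize resolution only approximately |
| Butterworth cut-off | 0.45 × Nyquist / 0.75 cyc/cm | — | the two consoles' clinical settings, each in the unit its console uses |
| Butterworth order | 8 | — | typical console order; not printed in clinical protocols |
| `sensitivity_gradient` | 0 / 0.05 | — | ±5% radial field on the target camera reproducing its central-decrease / marginal-increase pattern |
| `count_budget` | 5 × 10⁶ | counts | typical total reconstructed counts of a ⁹⁹ᵐTc-ECD brain study |
| `between_subject_cv` | 0.08 | — | inter-subject global perfusion variability of healthy cohorts |
| `local_cv`, `field_smoothness_mm` | 0.05, 20 | —, mm | smooth regional inter-subject variability |
| `session_cv`, `session_smoothness_mm` | 0 (study config: 0.04), 30 | —, mm | scan-to-scan variability between separate acquisition sessions (see below) |
| `count_floor` | 0.05 | fraction of support mean | voxels below it are excluded from ratios (neutral value 1) |
| map smoothing | 0 | mm | the compensation is a literal per-voxel ratio; smoothing before the ratio is exposed but off |
| NDB smoothing | 12 | mm FWHM | the usual Z-score-analysis smoothing |
| normalization target | 50 | counts | the conventional proportional-scaling target |
| `sd_floor_fraction` | 0.1 | fraction of mean masked SD | keeps Z finite at low-variance voxels |
| height threshold / extent | p &lt; 0.05 / 50 voxels | — | the uncorrected two-sample t settings of the reference protocol |
| cluster connectivity | 26 | — | configurable 6/18/26 |
| display threshold | 1.5 | Z | Z-map noise floor before display |
| VOI threshold | 2 | Z | voxels with Z ≥ 2 count as deficit in the Severity/Extent/Ratio indices |

## What the generators emulate — and what they do not

`make_hoffman_like()` reproduces the layered construction of the physical
brain phantom: alternating gray/white axial slabs (two voxels thick by
default) inside an ellipsoidal support, gray hotter than white by
`gm_wm_ratio`, around a central white core. Only the gray:white contrast
and the coexistence of both compartments matter downstream, so no attempt
is made at cortical folding. `make_3dbrain_like()` adds a closed
bone-equivalent shell (activity 0, attenuation `skull_mu`) and, by default,
empties the white compartment — the anatomical phantom's gray matter alone
can hold radionuclide. `make_pool()` is a uniform fill: with
`shape_kind = "brain"` over the same ellipsoidal support (the simplest
like-for-like comparison), with `shape_kind = "cylinder"` over the
phantom-container cylinder. The physical pool **is** that container with
the brain plates removed, so the experiment driver uses the cylinder: its
attenuation geometry, and hence its Chang residual, differs from a head's,
which is precisely the mechanism by which a structureless compensation
object miscorrects brain scans.

Simulated normal subjects come from `make_brain_like()`, a smooth cortical
gray shell plus deep gray nuclei over a white interior. The cohort base is
deliberately *not* the plate phantom: the question the pipeline studies is
how compensation quality degrades as the compensation object's activity
distribution departs from real anatomy, and that question disappears if
subjects and phantom share their fine structure. `make_subject_cohort()`
multiplies the base by a global log-normal scalar (CV 0.08) and a smooth
unit-mean log-Gaussian field (CV 0.05, 20 mm), keeping activity positive
and giving brain-like inter-subject structure.

Two acquisitions of the same subject on two cameras are *separate scanning
sessions* in the emulated protocol (the cameras were run one after the
other, and each phantom was scanned three separate times per camera). The
`session_cv` field of `acquire()` models this scan-to-scan variability as
a smooth multiplicative field drawn per acquisition; it is off by default
(the bare op is deterministic apart from Poisson sampling) and set to
CV 0.04 at 30 mm in the study configuration, a value in the range of
published test–retest reproducibility for perfusion SPECT. Without it, the
two cameras see bit-identical ground truth and the simulated inter-camera
differences collapse to Poisson noise plus filter response — an operating
point far cleaner than any real paired study.

What passing tests therefore show about real data is qualitative, not
quantitative: the *orderings* of compensation sources under matched,
mismatched and structureless objects, the exact algebra of building and
applying ratio maps, and the calibration of the evaluation statistics.
They do not show that real cameras differ by a radial polynomial, that
real test–retest error is 4%, or that anatomical standardization (not
modelled) is error-free.

## Numerical choices

* **Attenuation line integrals.** Axis-aligned rays are integrated exactly
  over the piecewise-constant attenuation grid — half the emitting voxel
  plus all downstream voxels, by vectorized reverse cumulative sums —
  which makes the Chang-inversion identity exact by construction. Oblique
  rays fall back to half-voxel-step ray marching with nearest-voxel
  sampling. The default direction set is the six axis-aligned rays, a
  cheap Chang-style opposed-ray mean; more directions can be supplied.
* **Filtering.** Gaussian smoothing and the Butterworth filter are
  frequency-domain multiplications with periodic boundaries; all generated
  objects sit away from the grid edges, so wrap-around is negligible. Both
  transfer functions have unit gain at zero frequency, preserving totals.
  Negative undershoot after filtering is clipped to zero before Poisson
  sampling and before normalization.
* **Ratio totality.** Ratios are formed only where both mean images reach
  `count_floor` × their own support mean; elsewhere the map is the neutral
  value 1, so applying a map is total and safe. Chang division is clamped
  at a factor of 10⁻³.
* **SD floor.** The NDB SD is floored at `sd_floor_fraction` × (mean
  masked SD); for a degenerate zero-variance cohort the floor falls back
  to the same fraction of the normalization target, so the floor is always
  positive.
* **Degenerate t statistics.** Voxels with zero pooled variance get t = 0
  when the group means agree (and ±∞ otherwise), keeping identical-group
  comparisons exactly empty.
* **Ties and determinism.** Every stochastic stage (cohort, session
  fields, Poisson) is seeded; the experiment driver derives one seed per
  stage from the root seed, and a rerun from the same configuration is
  byte-identical.

## Open design decisions

* **Central/marginal partition.** The original analysis divided the
  difference image with an interactive image tool; that partition is not
  recoverable. The package cuts the brain mask at the half-volume radius
  from its centroid (quantile configurable), which is deterministic and
  testable, and intersects the Decrease/Increase masks with both halves.
* **Lobe atlas.** Region-wise correlations use a deterministic geometric
  stand-in atlas (deep "sublobar" core plus frontal / occipital /
  temporal / anterior shell sectors, and "all"); any user-supplied integer
  label volume is accepted. The disease VOI (`default_sva_voi()`) is a
  synthetic posterior-medial wedge standing in for the proprietary
  disease-specific VOI.
* **Index definitions.** Severity = mean suprathreshold Z in the VOI,
  Extent = % suprathreshold VOI voxels, Ratio = VOI extent fraction over
  whole-brain extent fraction (dimensionless; a percentage rendering is
  exposed), thresholded at Z ≥ 2 — the standard definitions of the
  clinical index software, which the source protocol names but does not
  restate.
* **Normalization.** Proportional scaling of the brain-mask mean to 50;
  cerebellar or region-based normalization would be a drop-in alternative
  via the mask argument but is not provided as a preset.
* **Z sign.** Positive = decrease. The evaluation module derives
  "Decrease"/"Increase" labels from the t-map sides explicitly rather
  than relying on the Z sign convention.

## Problem sizes

The default study configuration is a $64^3$ grid at 3.5 mm, a cohort of
n = 20 scanned on both cameras (attenuation-corrected and uncorrected
target arms), three acquisitions per phantom per camera, and one simulated
20%-reduction disease case; it completes in well under a minute on one
core. The test suite exercises the same operations on $32^3$ grids, with
the statistical calibration run at 100 replicates of 10-vs-10 group
comparisons, and the numerical oracles (DFT filtering, scalar-loop t /
correlation / index computations) on $8^3$–$16^3$ fixtures.

## Known limitations

* No projection/reconstruction physics: scatter, attenuation–geometry
  interplay inside FBP, and iterative reconstruction artifacts are out of
  scope, so absolute correlation and Z levels are cleaner than clinical
  values.
* No anatomical standardization: the real pipeline's template warp — a
  major error source for non-anatomical phantoms — is replaced by
  construction-time alignment, which shifts part of the pool phantom's
  real-world disadvantage into the attenuation-geometry channel.
* The sensitivity difference between cameras is a smooth low-order field;
  real detector non-uniformities have structure at many scales.
* The NDB cohort doubles as the Normal-SPECT compensation source, as in
  the emulated protocol; an independent compensation cohort would lower
  the Normal-SPECT method's apparent advantage.
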