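---
title: "Adaptive dose tracking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive dose tracking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## The clinical problem

Head-and-neck radiotherapy delivers 30–35 daily fractions of a highly
conformal plan. Anatomy changes over those weeks — tumour regression,
parotid shrinkage and medial drift, weight loss, day-to-day setup
variation — so the dose the tissues actually accumulate can depart from the
plan. `rtflow` estimates that accumulated dose from daily setup imaging and
turns it into a replanning decision aid: per-structure dose parameters per
fraction, threshold flags, and short-horizon forecasts.

Three modelling commitments define the whole pipeline:

1. **The planned dose is held fixed in room coordinates.** No dose
   recalculation on the daily anatomy is attempted; tissue moves through a
   static dose cloud. This is the standard decision-support approximation —
   for photon plans and the few-millimetre deformations involved, the error
   is small compared with the thresholds monitored, but it *is* an
   approximation, and sites with large density changes (shrinking air
   cavities) would need a recalculation engine that is explicitly out of
   scope.
2. **Lagrangian accumulation on the planning grid.** A structure is the
   fixed set of plan-grid voxels of its planning mask; on day `f` the voxel
   at plan position `x` receives the full-course-equivalent dose
   `d̂_f(x) = D_plan(x + u_f(x))`, where `u_f` is the recovered plan→daily
   deformation. Voxel identity never changes, so voxel-wise accumulation is
   well defined and needs no field inversion. (Whether a clinical system
   accumulates voxel-wise or at the DVH level is usually unstated; voxel-wise
   is the stronger choice and reduces to the same DVH in the rigid case.)
3. **Uniform fractionation of the full-course grid.** Each fraction is
   credited `1/N` of the full-course dose. Simultaneous-integrated-boost
   plans deliver all prescription levels in every fraction, so the grid
   scales uniformly and per-level bookkeeping is unnecessary.

The projected cumulative dose after fraction `k` of `N` is

```
D_sum,k(x) = (1/N) * sum_{f=1..k} d̂_f(x)  +  ((N-k)/N) * d̂_k(x)
```

— the delivered part plus the assumption that today's anatomy holds for the
remainder. At `k = N` the projection term vanishes and `D_sum` is the plain
mean of the per-fraction doses; with no anatomical change it equals the
planned dose exactly at every `k` (both identities are tested).

## Deformable registration

The published systems this mirrors use intensity-based optical-flow
registration whose exact data term is proprietary; the implementation here
is a fully specified member of the same family: multi-resolution
demons-type optical flow.

* **Force.** At each voxel the update is the brightness-constancy force
  `du = -(M∘φ - F) ∇(M∘φ) / (|∇(M∘φ)|² + (M∘φ - F)²/κ²)` with `κ` the mean
  voxel spacing — intensity difference driven along the warped-moving
  gradient with the usual demons normalisation. Updates are capped at
  `max_step_mm` (default 2 mm) per iteration.
* **Regularisation.** The update field is smoothed with a Gaussian of
  `smoothness` voxels (default 2.0; fluid-like) and the accumulated field
  with `smoothness_field` voxels (default 0.75; diffusion-like). The
  combination was chosen on phantom ground truth: identity registration must
  return a numerically zero field, a 5 mm rigid shift must be recovered
  within 1 mm median, and a 4 mm gland drift within 1.5 mm mean. Stronger
  field smoothing resists localised deformation and biases organ-drift
  recovery low; no field smoothing at all is unstable.
* **Pyramid.** Three levels (2× decimation each, Gaussian anti-aliasing),
  100 iterations per level, convergence when the mean update drops below
  `convergence_tol` (0.02 mm). Registration is deterministic.
* **Grid reconciliation.** The daily volume (CBCT, typically 2 mm frames)
  is resampled onto the planning grid before flow; all downstream math then
  lives on one grid.
* **Intensity normalisation.** CBCT intensities are not calibrated HU, but
  optical flow assumes brightness constancy. The daily volume's foreground
  histogram (above the image mean, which separates tissue from the dominant
  air peak) is mapped onto the plan's by a *smoothed* quantile transfer: the
  empirical CDF-to-quantile map is evaluated on an intensity grid and a
  cubic intensity map is fitted through it, weighted by the local intensity
  density. The raw empirical transfer is exact but ill-conditioned — in a
  sparsely populated intensity band (a gland's value range, say) a tiny CDF
  difference becomes a large value shift that perturbs every structure
  sharing the band and drives spurious flow — whereas detector
  miscalibration is smooth in intensity, so the low-order fit captures the
  genuine correction and suppresses the noise; matching distributions give
  the identity map, and any linear miscalibration is reproduced exactly.
  The air background of *both* images is flattened to the common foreground
  floor: the body outline stays visible while uncalibrated air values and
  the differing air-mass fractions of CT and CBCT stop generating spurious
  forces.

The field is stored plan→daily on the plan grid: `x + u(x)` is the daily
position of the plan tissue at `x`. This makes dose mapping a direct lookup
and means that warping the *daily* image by `u` reconstructs the anatomy on
the planning grid; registration QA therefore compares `warp(daily, u)`
against the plan image. (The alternative — warping the plan image forward —
would compare two images misaligned by roughly twice the deformation and is
not self-consistent under this storage convention.)

## Dose-volume metrics

All metrics are computed from raw per-voxel samples, never from a binned
curve, to avoid binning bias: `V95` (percent of volume at ≥ 95% of the
structure's own prescription), `Dmean`, `Dmax`, `D1cc` (minimum dose of the
hottest 1 cm³, sorted voxels with partial-volume handling; structures under
1 cm³ degrade to the minimum dose with a warning) and hotspot
(`Dmax` relative to prescription). DVH curves use 0.1 Gy bins by default,
start at 100% and are non-increasing by construction. One deliberate
interpretation: the hotspot ceiling (110%) refers to the *plan's highest*
prescription — in an SIB plan the boost plateau legitimately sits inside
the nested lower-dose targets, and judging each target against its own
level would flag every SIB plan at baseline.

## Endpoints and crossings

Targets carry a lower-bound V95 endpoint (warning 95%, adaptation 93%) and
a hotspot ceiling. Organs at risk carry their planning-goal dose as the
warning level; where the protocol allows a 10% excursion the adaptation
level is exactly `1.10 ×` the warning level. Parotid glands are
plan-dependent: a spared gland that met its 20 Gy mean-dose goal is
monitored against 20 Gy; one that missed it but stayed under 21 Gy against
21 Gy; a spared contralateral gland under 26 Gy against 26 Gy; anything
else is excluded from monitoring with a logged notice. Violations use
strict inequality — a value exactly at threshold does not violate — which
matches the `<` / `>` form the constraints are written in and makes
boundary tests deterministic. The crossing fraction `Fx` is the first
fraction whose `DP_sum` strictly violates; trajectories may recede after
crossing, so the end-of-treatment tally is recorded separately. The
cumulative-dose column reported alongside `Fx` uses the highest SIB level
divided by `N` (the conventional 2 Gy/fraction bookkeeping).

## Forecasting

The trend model is ordinary least squares on all observed fractions
(no sliding window — with no stated specification, refitting on the full
history is the simplest reading of trend analysis, and per-fraction refits
are cheap), extrapolated exactly four fractions ahead, refusing to predict
with fewer than five observations. Predictions are not clamped to physical
ranges (V95 may extrapolate above 100%); clamping would bias the accuracy
evaluation. That evaluation anchors the fit at `Fx - i` for
`i = 4, 3, 2, 1` and averages `pDP_sum[Fx-i] - DP_sum[Fx]` over flagged
series, with 95% confidence half-widths from the Student t distribution on
`n - 1` degrees of freedom — appropriate at the small `n` involved.
Series crossing before fraction 5 are excluded (the model cannot have run).

## The phantom: what it emulates, and what it does not

`make_plan_phantom()` builds a neck-like digital phantom: an elliptic body
cylinder (75 × 65 mm semi-axes) in air, nested spherical targets
(60/54 Gy SIB, 30 fractions, 2 Gy/fraction at the top level), parotid
ellipsoids lateral to the target, a spinal cord inside a vertebral column,
and a mandible arc. Intensities are HU-like with two scales of smooth
random texture (glands and tumour keep the texture as offsets, as real
tissue does), a 0.6-voxel point-spread blur — a real scanner never produces
single-voxel edges, and band-limited boundaries are what both the flow and
the histogram transfer assume — and 10 HU quantum noise. The dose model is
analytic: each target contributes its prescription as a plateau with
Gaussian falloff (12 mm scale), the grid taking the voxel-wise maximum, so
planned V95 is exactly 100% and the spared-parotid mean stays under 20 Gy
by construction, and every ground-truth dose along a known trajectory has a
closed form.

`course_truth()` defines the per-fraction anatomy change as an analytic
forward map: Gaussian-windowed medial parotid drift (default
0.2 mm/fraction), parotid volume loss (0.7%/fraction), target regression
(0.5%/fraction), global axial body shrinkage (0.1%/fraction) — figures in
the range reported for head-and-neck courses — composed with a random rigid
setup error (1.5 mm / 0.5° SD) and 20 HU CBCT-like noise, with optional
bright streak artifacts. Daily images are generated through the numerically
inverted forward map (fixed-point iteration, converging rapidly for these
smooth fields), so the returned ground-truth fields are exact in the
registration module's own convention.

What passing phantom tests does **not** show: robustness to real CBCT
physics (scatter, beam hardening, ring artifacts), to contouring error on
the planning side, to sliding interfaces (the regulariser assumes smooth
deformation), or to intensity changes that are anatomical rather than
geometric (mucus filling a cavity looks like motion to any intensity-driven
flow). The phantom validates the machinery — geometry, accumulation
algebra, threshold logic, trend statistics — under controlled conditions
with exact truth, not clinical registration accuracy.

## Numerical choices and degenerate inputs

* Voxel positions refer to voxel centers; physical mm, patient-based axes;
  trilinear interpolation everywhere, with a `1e-6`-voxel tolerance at grid
  boundaries so that voxel centers sitting exactly on the boundary stay
  in-field.
* Structure-dose samples falling outside the dose grid take 0 Gy and are
  counted; a fraction where more than 10% of a structure samples off-grid
  is flagged unreliable.
* Deformed masks are forward-splatted trilinearly and thresholded at 0.5;
  mask resampling across grids uses the same threshold.
* NCC regions are the structure mask dilated by 5 mm (boundary mismatch is
  exactly what should lower the score); both images are smoothed by one
  voxel first so uncorrelated noise in small low-contrast regions does not
  masquerade as misregistration. A zero-variance region makes NCC
  undefined and flags for review rather than passing silently.
* The displacement QA criterion is the conservative any-voxel maximum
  against the 7 mm threshold.
* A fraction whose processing fails hard is marked failed and the course
  continues — a monitoring tool must not stop at fraction 17 of 35.

## Problem sizes used in tests

The test and acceptance phantoms keep the default anatomy at coarser
resolution (64 × 64 × 40 at 3 mm, and 48 × 48 × 28 at 4 mm for fixed-point
checks), and the engineered drifting-parotid course uses 1.8 mm/fraction
over 12 fractions so that the warning crossing falls mid-course with a
steep, unambiguous trend. These sizes were chosen as the smallest at which
the phantom remains anatomically proportioned and registration tolerances
are meaningful; the package defaults (96 × 96 × 64 at 2 mm, 30 fractions)
remain the reference configuration for interactive use.

## Known limitations

No dose recalculation (rigid-dose approximation); no biological weighting
(EQD2) in accumulation; no diffeomorphic guarantee on the recovered fields
(the Jacobian can change sign under extreme drift — the displacement QA
flag is the guard); DICOM support is deliberately minimal (explicit VR
little endian, axis-aligned volumes, the CT/RTSTRUCT/RTDOSE tags this
pipeline needs); and the linear forecast is exactly that — linear — which
systematically overestimates coverage when a trend accelerates.
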