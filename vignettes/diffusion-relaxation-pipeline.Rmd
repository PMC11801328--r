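---
title: "Combined diffusion-relaxation analysis of the placenta: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined diffusion-relaxation analysis of the placenta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentadr)
```

## The measurement and the models

A combined diffusion-relaxation acquisition samples the placental signal
jointly across diffusion weighting $b$ and echo time $TE$. The protocol
implemented by `build_paper_scheme()` uses 60 diffusion preparations —
three gradient directions at each of $b$ = 5, 10, 25, 50, 100, 200, 400,
600, 1200, 1600 s/mm², eight at $b$ = 18, seven at $b$ = 36 and fifteen
at $b$ = 800 — each acquired at four echo times (78, 114, 150, 186 ms),
i.e. 240 measurements per voxel. Only the per-shell direction *counts*
are part of the protocol; the direction coordinates are generated by
antipodally symmetric electrostatic-repulsion sampling on the sphere
with a fixed internal seed, so two calls return identical schemes. There
is no $b = 0$ measurement; all code paths treat the lowest shell
($b$ = 5) as the diffusion reference.

Two isotropic models are fitted voxel-wise, both referenced to the
shortest echo time $TE_{\min}$:

* **T2\*-ADC (mono-exponential):**
  $S(TE, b) = S_0\, e^{-(TE - TE_{\min})/T_2^*}\, e^{-b\,\mathrm{ADC}}$

* **T2\*-IVIM (two compartments):**
  $S(TE, b) = S_0 \left[ f\, e^{-(TE - TE_{\min})/T_{2,\mathrm{fast}}^*}
  e^{-b D^*} + (1 - f)\, e^{-(TE - TE_{\min})/T_{2,\mathrm{slow}}^*}
  e^{-b\,\mathrm{ADC}} \right]$

The fast compartment represents perfusing (predominantly maternal)
blood, the slow compartment diffusing blood in the intervillous space;
$f$ is the perfusion fraction. Compartment labels are a convention, not
an estimate: the package always relabels a fit so that $D^* >
\mathrm{ADC}$, and $f$ always refers to the fast compartment. Fractional
anisotropy is obtained from a conventional single-tensor log-linear fit
restricted to the shortest echo time, with eigenvalues clamped at zero
so FA is in $[0, 1]$ by construction.

On genuinely two-compartment tissue the mono-exponential $T_2^*$ is an
*effective* quantity: it depends on the sampling scheme and sits below
the signal-fraction-weighted compartment mixture, because high-$b$
measurements suppress the fast compartment. The phantom's `t2_star`
ground-truth map uses the linear mixture $f\,T_{2,\mathrm{fast}}^* +
(1-f)\,T_{2,\mathrm{slow}}^*$ as its definition; tests therefore compare
mono-exponential fits against mono-exponentially generated data exactly,
and against two-compartment data only for monotone agreement.

## Fitting: algorithm, bounds, degeneracies

The paper-facing estimator choices are open in the underlying study
(which names only in-house scripts), so the following are this package's
own decisions:

* Bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), with
  $T_2^*$ limited to (1, 300] ms and ADC to [0, 0.01] mm²/s. The upper
  $T_2^*$ bound is deliberately *above* the 200 ms physiological
  exclusion so that thresholding remains an observable downstream step
  rather than a fitting constraint.
* Initialisation from log-linear regressions: log-signal against TE on
  the lowest shell ($T_2^*$) and against $b$ at $TE_{\min}$ (ADC).
* Two-compartment fitting is *segmented first*: the slow compartment is
  fitted log-linearly on $b \ge 200$ s/mm² (the conventional IVIM cut),
  the fast compartment on the low-$b$ residual, and the amplitudes give
  $S_0$ and $f$. The `"full"` strategy polishes this with a joint
  bounded fit from five starts (the segmented seed plus four
  deterministic log-normal perturbations); the lowest residual wins,
  ties broken by start order.
* **Rician mean correction.** Magnitude MRI noise is Rician, and a
  naive least-squares fit of the noiseless model is pulled up wherever
  the decay approaches the noise floor. We measured this on simulated
  data at SNR 30: the same fitter that is unbiased under additive
  Gaussian noise acquires a ≈ −20 % median bias on
  $T_{2,\mathrm{fast}}^*$ under Rician noise. The default fit therefore
  finishes with a refinement against the exact Rician first moment of
  the model, $E[M] = \sigma\sqrt{\pi/2}\,L_{1/2}(-S^2/2\sigma^2)$,
  using a noise level estimated from the residuals of the uncorrected
  fit (robust scale, then refined on measurements well above the
  floor). On noiseless data the estimated $\sigma$ vanishes and the
  correction is a no-op. This is a first-moment correction, not a full
  Rician likelihood; at very low SNR (≲ 5 at the reference
  measurement) it under-corrects, which we document as a limitation.
* Voxels with entirely non-positive signal, or with $f$ pinned at a
  bound with degenerate compartments, are flagged non-converged with a
  reason code and never abort a volume fit; `fit_volume()` reports the
  non-converged count and fraction.
* No spatial regularisation couples voxels, matching per-voxel
  parameter maps.

### Identifiability and the brute-force oracle

`brute_force_monoexp()` and `brute_force_ivim()` are independent
exhaustive-grid minimisers of the same least-squares objective, used to
verify that the gradient-based fits find the global basin. The amplitude
$S_0$ is linear in both models and is profiled out exactly at every grid
node, so the search is exhaustive over the nonlinear parameters without
amplitude-quantisation artefacts. For the mono-exponential model the
gradient solution agrees with the grid argmin to within one grid spacing
in every parameter. For the two-compartment model the pair
($T_{2,\mathrm{fast}}^*$, $D^*$) lies on a shallow ridge of the
objective — refining the grid shrinks the spacing as fast as it shrinks
the argmin's wander along the ridge, so argmin *location* is not a
meaningful comparison there at any affordable grid. On the ridge the
oracle comparison is made on the objective value (the gradient fit must
match or beat the exhaustive minimum), alongside within-one-spacing
agreement on the identifiable parameters ($f$, $T_{2,\mathrm{slow}}^*$,
ADC, $S_0$). $D^*$ is weakly identifiable in general and is excluded
from bias guarantees.

## The ROI stage

Fitted $T_2^*$ maps are thresholded to exclude supraphysiological
values: voxels with $T_2^*$ strictly greater than 200 ms are removed; a
voxel at exactly 200 ms is retained. The threshold is applied to the
$T_2^*$ map of whichever model is being summarised — the
mono-exponential map for the T2\*-ADC summaries and each compartment's
map for the two-compartment summaries — through one shared code path
taking the map as input. Summaries are arithmetic means over retained
voxels (a median is available, never the default), with retained/total
voxel counts carried alongside so exclusions are auditable. An empty
retained region flags the subject for exclusion instead of failing.

## The synthetic cohort: what it emulates

No scan data accompany the underlying study, so a generator provides the
statistical structure the analysis assumes. All population settings live
in one editable block, `phantom_config()`; they are physiologically
plausible choices, not measured claims:

* control slow-compartment $T_2^*$ declines linearly from 70 ms at 20
  weeks by 2.5 ms/week (≈ 40 ms at 32 weeks); the fast compartment sits
  30 ms above the slow one;
* preterm cases scale $T_2^*$ down in both compartments when membranes
  have ruptured (×0.72) and predominantly in the slow compartment when
  intact (slow ×0.82, fast ×0.95), so the rupture subgroup carries the
  stronger effect;
* $f$ = 0.25, $D^*$ = 0.05 mm²/s, ADC = 2×10⁻³ mm²/s and FA = 0.15
  carry no gestational-age or group effect;
* between-subject SDs (5 ms for $T_2^*$, 0.03 for $f$, …) set the
  effect-to-noise ratio of the cohort statistics.

`make_phantom()` realises one subject as an ellipsoidal parenchyma mask
in a 32³ grid (kept small for desk-scale runtimes; tests use 10–16³)
with smooth low-frequency spatial modulation of the parameter maps.
`simulate_subject_data()` evaluates the two-compartment forward model
per voxel and adds Rician noise (Gaussian available for oracle tests),
with SNR defined at the shortest echo time and lowest $b$-value.

The cohort generator reproduces the study's design margins: cases
deliver before 32 weeks (14 of 23 with ruptured membranes), controls at
or after 37 weeks, and onset ≤ MRI ≤ delivery always holds.
MRI-to-delivery latency is drawn from a gamma distribution
moment-matched to mean 8 days, SD 8.7 days. A gamma rather than a
lower-truncated normal is a deliberate choice: a normal truncated at
zero can never carry a coefficient of variation above 1, and these
moments have CV ≈ 1.09 — truncating N(8, 8.7²) at zero would shift the
mean to ≈ 10.8 days, whereas the gamma reproduces both stated moments
exactly. Case draws whose latency would push delivery past 32 weeks are
resampled, with the retry count recorded; the latency *distribution*
itself (exposed as `rlatency()`) is unaffected by that rejection step.

With `roi = "analytic"`, `make_cohort()` fills the per-subject ROI means
directly from subject-level ground truth plus small ROI-estimation
noise. This is the fast path used for cohort-scale statistics and
calibration experiments (hundreds of simulated cohorts in seconds); the
full imaging path — phantom, 4D signal, voxel-wise fits, thresholding,
ROI averaging — is exercised by `run_end_to_end()` at miniature sizes
(e.g. 12 subjects on 10³ grids) so the two paths can be checked against
each other. What passing tests show is therefore that the *pipeline*
recovers the structure the generator injects; the generator does not
emulate motion, slice-to-volume reconstruction artefacts, segmentation
error, fetal anatomy or inter-site protocol drift, so agreement here
does not certify performance on real scans.

## Cohort statistics

All group-level models are ordinary least squares. Gestational-age
trends are fitted among controls only (ROI mean against GA at MRI).
Case-control contrasts regress the ROI mean on a case indicator with
controls as reference; GA at MRI is included as a covariate by default —
the underlying comparison plots parameters against gestation, and the
case and control scan windows differ, so unadjusted contrasts would
absorb the GA trend — with `adjust_ga = FALSE` available. Subgroup
contrasts use only the ruptured-membranes or intact-membranes cases
against all controls. Significance is two-sided at 0.05 with no
multiple-testing correction, matching the pilot-study analysis style.

For cases, the latency ratio is
$(GA_{\mathrm{delivery}} - GA_{\mathrm{MRI}}) / (GA_{\mathrm{MRI}} -
GA_{\mathrm{onset}})$: the remaining interval to delivery over the
elapsed interval since first symptoms, both measured from the scan. The
verbal description of this ratio in the source study reads
"[onset to MRI] to [delivery to MRI]", which taken literally *increases*
toward delivery and contradicts the stated interpretation that
decreasing scores mean a scan closer to delivery; this package follows
the stated direction (the formula above) and documents the
discrepancy here rather than silently resolving it — inverting the ratio
only relabels the two sides of the split. Ratios are standardised to
z-scores over the scored cases and split at zero; a score of exactly
zero goes to the above-zero side (measure-zero for continuous ratios). A
case scanned at symptom onset has an undefined ratio and is excluded
with a warning; all-equal ratios make the split undefined and raise an
error.

## Numerical and reproducibility choices

* Every stochastic routine takes a seed; library code never perturbs the
  caller's RNG state (seeds are applied in a local scope and restored).
  Stage seeds in the pipeline are derived deterministically from one
  master seed and stay within 32-bit integer range.
* Measurement ordering in schemes is fixed (shells ascending in $b$,
  directions in generation order, echo time innermost) so sidecar files
  diff cleanly; sidecars are FSL-dialect `bval`/`bvec` plus an
  equal-length TE file in ms, written to 6 significant digits.
* Test and calibration problem sizes (10–16³ phantoms, 500-replicate
  calibration, 500-voxel bias studies, 20-replicate pattern checks) are
  the package's chosen desk-scale defaults; they complete in minutes on
  one CPU.

## Known limitations

* The Rician correction is first-moment only; a full Rician likelihood
  (or phase-preserving fitting) would be needed at SNR below ≈ 5.
* $D^*$ is weakly identifiable on this protocol and carries no bias
  guarantee.
* The latency-effect analysis operates on ROI summaries; the generator
  injects no latency-dependent tissue effect by default, so
  latency-split power experiments inject effects at the cohort-table
  level.
* Sub-regional analyses (basal plate, periphery) and histopathology
  subgroups are out of scope.
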