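---
title: "Modelling seat interface pressure from seated centre of pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seat interface pressure from seated centre of pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipcop)
```

## The problem

Manual wheelchair users offload their sit bones by leaning forward or
sideways. A seat pan on four corner load cells tracks the seated centre of
pressure (CoP) robustly in daily use, but the quantity that matters for
pressure-injury prevention is the proportional reduction of seat interface
pressure (SIP) under the ischial tuberosities (ITs). `sipcop` provides the
forward models that connect posture, CoP and SIP, a seeded simulator that
generates complete sensor recordings of leaning manoeuvres, and the
estimation pipeline that recovers per-individual SIP–CoP slopes, cohort
mixed-effects models and CoP thresholds for target offloading.

## The lean model and its assumptions

The body is three rigid segments joined by hinges: trunk, upper legs, and
lower legs. The lower legs rest on the footrests and carry no seat load,
so the seat-borne mass is `T t_m + U u_m`, with `T` and `U` the trunk and
upper-leg CoM vectors in a body frame whose origin sits at the trunk/thigh
hinge near the sacrum (x left–right with left negative, y back–front with
forward positive, z up).

* A **forward lean** rotates the trunk term about the x-axis through θ;
  the upper legs stay put (their distal ends sink into the cushion, which
  the pressure model absorbs).
* A **leftward lean** rotates both terms about the axis parallel to y
  through the left femur at (−r, 0, 0) through φ, with `r` the hip
  half-width. Rightward leans are the x-mirror image.

On level ground the CoP is the vertical projection of the CoM onto the
seat plane; the 8° rearward dump angle of the study chair is carried as
metadata and does not tilt the projection (hardware-calibration error on a
tilted pan is an empirical matter outside this package's scope). With `T`
vertical at upright the closed-form displacement magnitudes are
`|T| t_m sin θ` for a forward lean and, for a combined lean,

$$\sqrt{(|T| t_m \sin\theta)^2 + \big(r(t_m+u_m)(1-\cos\varphi) +
|T| t_m \cos\theta \sin\varphi\big)^2}.$$

Both lateral contributions move the CoP toward the lean side, so they add;
the package validates the closed forms against the explicit
rotation-matrix pipeline to 10⁻⁹ on random poses (the typeset closed form
this expression descends from is ambiguous about grouping, and the
kinematic pipeline is treated as ground truth).

## The interface-pressure model

For a forward lean, torso and thighs are a rigid beam of length `L` on a
cushion of uniform elasticity. The restoring-force density `f(y)` must be
affine for a non-deforming beam, and static force and torque equilibrium
determine it completely:

$$f(y) = -2 g m\left(\frac{3\,\mathrm{CoM}_y - 2L}{L^2} -
\frac{3(2\,\mathrm{CoM}_y - L)\,y}{L^3}\right),$$

which integrates to `m g` and has first moment `CoM_y m g` by
construction. Dividing `f` at the IT position `y` after a CoM shift Δ by
its upright value gives the proportional pressure

$$p(\Delta) = 1 + \frac{3(L-2y)}{3\,\mathrm{CoM}_{y0}(L-2y) - L(2L-3y)}\,
\Delta,$$

reducing at `y = 0` to `1 + 3/(3\,\mathrm{CoM}_{y0} - 2L)\,\Delta`. The
coefficient of Δ is the individual's theoretical SIP–CoP slope; it is
negative and finite whenever `CoM_y0 < 2L/3` and `y < L/2`, which the
`anthropometry()` validator enforces. The slope steepens when the upright
CoM sits further forward, the IT position is closer to the hip, or the
upper leg is shorter. Negative `f` (possible at extreme shifts) is clipped
to zero in `proportional_pressure()`: contact pressure cannot be negative,
and the pipeline only ever fits the first 95% of the reduction, which the
clip cannot reach.

Lateral-lean pressure is **not** modelled analytically — whether the IT
lifts off or the spine curves cannot be separated without assumptions the
data cannot check. Instead the simulator imposes the forward-lean slope
scaled by a configurable multiplier ≥ 1 on the offloaded side, consistent
with sideways leans producing steeper SIP–CoP responses, and a small
configurable pressure rise on the loaded side.

## What the simulator emulates — and what it does not

`simulate_trial()` composes the two models forward into three raw sensor
streams plus tare frames:

| stream | rate | noise default | notes |
|---|---|---|---|
| corner load cells | 125 Hz | 0.5 N | bilinear corner distribution; cushion+mat weight superimposed at seat centre |
| pressure mat (16×16) | nominal 15 Hz | 1.5 units/cell | uniform positive timestamp jitter (default 5% of the period) emulating acquisition slowdowns |
| IMU pitch/roll ×4 | 100 Hz | 0.3° | upright reads ≈ 90° so lean angles never cross 0°; pelvis/femur channels are scaled copies of the trunk trajectory |

No noise magnitudes are published for the emulated instruments; the
defaults above are this package's choices, are stated in
`simulation_config()`, and are varied in the tests. Trials run through
tare, optional backrest-to-upright transition, still sitting, a linear
angle ramp (default to 40° over 6 s) and a hold. Sideways trials ramp θ
and φ together (default θ = 0.5 φ), since sideways manoeuvres typically
carry some forward lean. An optional additive CoP bias emulates weight
transfer through the knees (off by default).

Two deliberate idealisations matter for interpreting test results:

* **Piecewise-constant pose.** The underlying posture is held constant
  over each nominal mat frame interval (1/15 s). Nearest-timestamp
  alignment pairs samples at most 4–5 ms apart, well inside the 66.7 ms
  plateau, so every stream observes the identical pose at paired
  timestamps and noiseless end-to-end recovery is exact rather than
  limited by interpolation error. Real posture is continuous; at the
  manoeuvre speeds simulated the difference is far below sensor noise.
* **Exactly linear SIP response with an ambient floor.** IT mat cells
  render as `max(ambient, peak × p)`; the ambient floor mimics residual
  tissue contact at full offload. The 95% truncation keeps the fitted
  region above the floor.

Consequently, passing recovery tests show the *pipeline* is unbiased under
the model's own assumptions. They cannot show that real bodies are rigid
beams on uniform cushions — hand support on the knees, footrest force
transfer, spine curvature and cushion nonlinearity all bend real responses
away from the line, and are listed as non-goals.

## Pipeline numerical choices

* **CoP from forces** uses the corner-force weighted centroid; a
  nonpositive force sum (pre-transfer, or sensor fault) is an error.
* **Alignment** pairs each mat frame with the nearest load-cell and IMU
  samples; frames without a partner within `max_gap_s` (default 20 ms) in
  every stream are dropped with a warning.
* **IT regions** are 2×2 blocks ("4 contiguous cells" read as the compact
  4-connected footprint an IT makes at 2.54 cm cell pitch), found by
  exhaustive window search per seat half; ties within 2% fall back to the
  persistence criterion (longest time above half-max during the first
  forward trial), then to the lowest (row, col). This is deterministic
  and oracle-testable.
* **Normalization** divides all pressures by the maximum of the mean-IT
  trace and re-bases the CoP origin and angle zeros at the peak-time
  sample (for upright starts this is the first sample, so nothing
  changes). The peak is located on — and the constant taken from — a 0.5 s
  moving-average window, matching the initial zeroing window, so that a
  single noisy sample defines neither. The operation is idempotent.
* **Truncation** keeps the contiguous prefix from the re-zero sample to
  the first sample completing 95% of the total reduction of the tracked
  pressure. The tracked pressure is the mean of both ITs for forward
  leans and the **offloaded** side for sideways leans (left lean → right
  IT); the published analysis plots both but does not name its regression
  target, so this package follows the offloading focus and makes the
  choice overridable. A trial with no reduction is excluded, not fitted.
* **Regression** pools the raw samples of the repetitions (rather than
  averaging per-repetition slopes), matching the description of fitting
  the combined data of the three repeats. The reported slope standard
  error adds, in quadrature to the OLS term, the propagated uncertainty
  of the shared normalization constant: every sample in a trial is
  divided by one noisy estimate, so ignoring it makes the naive SE
  anticonservative and recovery z-scores miscalibrated.
* **Sine fits** use the first 90% of the post-re-zero samples *by count*
  — deliberately different from the 95%-of-reduction rule, which the
  analysis contrasts it with — to avoid range wrap and end-of-lean
  plateaus.
* **Bland–Altman** limits of agreement use the conventional 1.96
  multiplier (none is stated in the source analysis).

## Mixed models

`build_lmm_design()` centres CoP on its grand mean, codes treatment
contrasts with baselines forward / air / backrest / AB, and adds a
CoP-by-factor interaction for every categorical factor with more than one
level. `fit_sip_lmm()` delegates the numerical fit to `lmerTest::lmer()`
(REML, Satterthwaite degrees of freedom) — the one off-the-shelf stage of
the analysis; re-deriving mixed-model machinery is explicitly out of
scope. Confidence intervals are Wald (estimate ± 1.96 SE), the source
analysis not stating its method. Candidate random structures are `(1)`,
`(1 + CoP)`, `(1 + CoP + PR + CoP:PR)` and a "maximal" structure adding
random slopes for every CoP interaction present; singular (boundary) fits
are flagged separately from optimizer failures, and `compare_lmm_models()`
refuses to rank fits on differing data. `total_slope()` composes
direction-specific slopes as CoP plus the matching interaction estimate —
pure arithmetic, usable on any published fixed-effect table.

## Problem sizes and test design

The recovery and model-selection tests run on a seeded 10-participant
synthetic cohort (3 directions × 3 repetitions = 90 trials, roughly 6,000
pooled regression samples), with per-participant anthropometry drawn from
the ranges in `cohort_default_ranges()`; these sizes give stable AIC/BIC
orderings and tight recovery checks while keeping a full run in tens of
seconds. Noiseless recovery is asserted to 10⁻⁶ (it holds to machine
precision); noisy per-participant slopes must fall within 3 propagated
standard errors, and the mixed model's CoP effect within 2 standard errors
of the generating mean. The lateral slope multiplier varies across
simulated participants (1.25–1.55): individuals genuinely differ in how
much forward lean their sideways manoeuvres carry, and a cohort-constant
multiplier would make the random CoP and CoP:direction effects perfectly
collinear.

## Open decisions taken

* **Bed-mat mass fractions.** Whether head and lower-leg mass fold into
  the trunk fraction is not specified anywhere; `mass_fractions()` folds
  the head into the trunk (it rides on the trunk segment when leaning)
  and excludes the lower legs (footrest-supported). The simulator treats
  the fractions as free parameters regardless.
* **Upright CoM `CoM_y0`** is treated as a measured input (from the
  supine bed-mat frame) rather than derived from `T` and `U`: the two
  descriptions normalize the seat-borne CoM differently, and the measured
  value is what a practitioner has.
* **"Maximal" random structure** is defined as random intercept + CoP ×
  direction terms + a random slope for each additional CoP interaction
  present; the output labels the structure explicitly so users can see
  exactly what was fitted.

## Limitations

The simulator shares the analytic model's idealisations, so it cannot
probe rigid-trunk or uniform-elasticity violations; lateral pressure
behaviour is imposed, not derived; knee contractures and raised limbs on
the bed mat are not modelled; and the published per-participant human
tables are not reproducible from synthetic data — the package checks
signs, structure and arithmetic against them, never the human estimates
themselves.
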