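# sipcop

Tools for relating **seat interface pressure (SIP)** under the ischial
tuberosities (ITs) to the **seated centre of pressure (CoP)** while manual
wheelchair users perform leaning pressure-redistribution (PR) manoeuvres.

Wheelchair users are at high risk of pressure injuries from prolonged
sitting; clinical guidelines recommend periodic leans that offload the sit
bones. A seat pan instrumented with four corner load cells can track the
CoP cheaply and robustly — but the clinically meaningful quantity is the
proportional reduction in SIP at the ITs. `sipcop` implements the models
and the estimation pipeline that connect the two, so that a CoP threshold
can stand in for a target SIP reduction.

## What is implemented

**Lean kinematics.** A three-segment body model (trunk, upper legs; lower
legs ride on the footrests). A forward lean rotates the trunk about the
x-axis through θ; a sideways lean rotates trunk and upper legs about the
femur axis at (−r, 0, 0) through φ. With the trunk CoM vertical at upright,
the CoP displacement magnitude is

    forward:   |T| t_m sin(θ)
    combined:  sqrt( (|T| t_m sin θ)^2 +
                     (r (t_m + u_m)(1 − cos φ) + |T| t_m cos θ sin φ)^2 )

where `T` is the trunk CoM vector, `t_m`, `u_m` the trunk and upper-leg
mass fractions, and `r` the hip half-width.

**Interface pressure.** The seated body is a rigid beam of length `L` on a
uniformly elastic cushion. Static force and torque equilibrium pin down an
affine restoring-force profile `f(y)`, giving the proportional IT pressure
as an affine function of the forward CoM shift Δ:

    p(Δ) = 1 + 3 (L − 2y) / (3 CoMy0 (L − 2y) − L (2L − 3y)) · Δ

with `CoMy0` the upright CoM position and `y` the IT position along the
thigh; at `y = 0` this is `1 + 3/(3 CoMy0 − 2L) · Δ`. The coefficient of Δ
is the individual's **theoretical SIP–CoP slope** (negative: pressure
falls as the CoP moves forward).

**Synthetic trials.** A deterministic, seeded simulator renders complete
trials: 125 Hz corner load cells, a 16×16 pressure mat at a nominal 15 Hz
with timestamp jitter, four IMU pitch/roll channels at 100 Hz, and
pre-transfer tare frames — for forward, leftward and rightward leans from
upright or backrest starts.

**Estimation pipeline.** CoP from corner forces, taring, nearest-timestamp
multirate alignment, exhaustive 2×2 IT-region search, max-pressure
normalization with re-zeroing at the pressure peak, truncation to the
first 95% of the SIP reduction, pooled per-condition ordinary least
squares, `CoP = b·sin(pitch)` fits, CoP thresholds for target reductions,
and Bland–Altman agreement between fitted and theoretical slopes.

**Mixed models.** Linear mixed-effects models (REML via `lmerTest`,
Satterthwaite degrees of freedom) of proportional SIP on CoP magnitude
with direction, cushion, start-position and group fixed effects and
increasingly rich participant random-effects structures, compared by AIC
and BIC, plus composition of direction-specific total slopes.

## Worked example

```r
library(sipcop)

anthro <- anthropometry(
  trunk_com = c(0, 0, 42), upper_leg_com = c(0, 20, 0),
  trunk_mass_fraction = 0.58, upper_leg_mass_fraction = 0.22,
  upper_leg_length = 42, hip_half_width = 9, it_offset = 1.5,
  upright_com_y = 12, body_mass = 75)

theoretical_slope(anthro)            # -0.06047  (prop. SIP per cm of CoP)
theoretical_sine_coefficient(anthro) #  24.36    (cm; CoP = b sin(pitch))

cfg    <- simulation_config(anthro, seed = 42)   # default sensor noise
trial  <- simulate_trial(cfg, trial_condition("forward"))
geom   <- seat_geometry()
region <- select_it_regions(align_streams(trial, geom))
series <- process_trial(trial, geom, region)
fit_sip_cop_line(series)
#> SIP-CoP regression: slope -0.0601 /cm (SE 0.0003), intercept 0.9906,
#> R^2 0.9989, n 90

cop_threshold(fit_sip_cop_line(series)$slope, 0.90)
#> 14.97   # cm of CoP displacement for a 90% SIP reduction
```

The fitted slope (−0.0601) recovers this individual's theoretical slope
(−0.0605) from a single noisy trial; with zero sensor noise the recovery
is exact. The threshold says this person must move their CoP about 15 cm
to offload 90% of their IT pressure.

A whole-cohort run (simulate → process → mixed models → thresholds):

```r
run_all("myrun", seed = 1, n_participants = 10)
# writes trials/, regressions.csv, samples.csv, model_comparison.csv,
# thresholds.csv, bland_altman.csv under "myrun/"
```

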