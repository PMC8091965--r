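---
title: "A neuromuscular-model ankle exoskeleton controller at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuromuscular-model ankle exoskeleton controller at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmmexo)
```

## The model

`nmmexo` simulates a *neuromuscular-model* (NMM) controller for a powered
ankle exoskeleton. The controller embeds a virtual, lumped plantarflexor
muscle-tendon unit (MTU): a Hill-type contractile element (CE) in series
with an elastic tendon (SEE). The user's ankle angle drives the virtual
MTU through a musculoskeletal geometry map; the virtual muscle is
stimulated by a *positive force-feedback reflex* — its own normalized
force, multiplied by a Gain and delayed by a neural-latency Delay — and
the resulting MTU force, acting through the virtual moment arm and scaled
by a torque fraction $\psi$, becomes the commanded exoskeleton torque.

Per control step $i$ (1 kHz by default):

1. **Geometry.** $L_{MTU,i} = L_{ref} - r_0 \sin(\theta_i - \theta_{ref})$,
   with plantarflexion positive, so dorsiflexion stretches the MTU. The
   moment arm is $r(\theta) = r_0\cos(\theta - \theta_{ref})$, which equals
   $-\,dL_{MTU}/d\theta$; a constant-arm variant ($r \equiv r_0$) is
   selectable because a single moment-arm symbol in the torque map is also
   a defensible reading of the control law.
2. **Tendon.** $L_{SEE,i} = L_{MTU,i} - L_{CE,i}$ (exactly, at every
   step). The SEE force is zero when slack, quadratic up to the toe strain
   $\varepsilon_{ref} = 0.04$, then linear with stiffness
   $k_{SEE} = 315.4$ N/mm; force and tangent stiffness are continuous at
   the junction. The full MTU force is the SEE force.
3. **CE velocity.** The force balance
   $F_{MTU} = F_{max}\,(a\,f_L(L_{CE})\,f_V(v) + f_P(L_{CE}))$ is inverted
   for $v$ (shortening positive). $f_L$ is the Gaussian-type bell
   $\exp\!\big(c\,|{(L/L_{opt}-1)}/{w}|^3\big)$ with $c = \ln 0.05$,
   $w = 0.56$; $f_V$ is the Hill hyperbola
   $(V_{max}-v)/(V_{max}+Kv)$ with $K = 5$ on the concentric side and a
   saturating eccentric branch approaching the plateau $N = 1.5$; $f_P$
   is quadratic in strain above $L_{opt}$. These curve shapes and
   constants are the standard reflex-walking-model forms; all are exposed
   in `mtu_params()`.
4. **Integration.** $L_{CE}$ is advanced by Heun's method (explicit
   trapezoid; see *Numerical choices*), activation by the exact
   exponential update of the first-order lag
   $\dot a = (S - a)/\tau_{act}$, $\tau_{act} = 10$ ms.
5. **Reflex.** The normalized force $F_{MTU}/F_{max}$ enters a delay
   line; stimulation is
   $S(t) = \mathrm{clamp}\,(S_0 + G\,\hat F(t - \Delta),\,0,\,1)$ during
   stance and the baseline $S_0$ during swing.
6. **Torque.** $\tau_{exo} = F_{MTU}\, r(\theta)\, \psi$ during stance;
   zero during swing, emulating the hardware slack-adjustment behaviour
   that pays out the drive cable.

The study grid couples this controller to fixed treadmill-walking
kinematics: Gains 0.8–2.0 at 10 ms Delay, Delays 10–40 ms at Gain 1.2, a
zero-torque reference (`NoPwr`, $\psi = 0$) and a high-Gain/high-Delay
combination — ten named conditions in `study_conditions()`.

## Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `f_max` | 6000 | N | maximal isometric CE force of the lumped plantarflexors |
| `l_opt` | 0.04 | m | optimal CE length |
| `v_max` | 0.326 | m/s | maximal shortening velocity |
| `k_see` | 315.4 | N/mm | SEE linear-region stiffness |
| `l_slack` | 0.26 | m | SEE slack length (soleus-scale stand-in; not printed with the study set) |
| `eps_ref` | 0.04 | – | SEE toe-region strain |
| `tau_act` | 0.01 | s | activation time constant (single constant for rise and fall, keeping the fixed point $a = S$ exact) |
| `gain`, `delay` | 1.2, 0.010 | –, s | reflex loop parameters (the swept pair) |
| `prestim` | 0.01 | – | baseline stimulation; positive force feedback needs a nonzero seed |
| `psi` | 0.5 | – | fraction of the virtual ankle moment commanded as exoskeleton torque |
| `r0` | 0.05 | m | virtual moment arm at neutral (configurable; the physical drive lever is a different quantity) |

Two deliberately open choices are exposed as flags rather than decided
silently. The reflex normalization divides by $F_{max}$; dividing by
$a F_{max}$ (the other grammatical reading of the pathway description) is
available via `norm_by_activation`, but is not the default because
reflex controllers of this family normalize by maximal isometric force
and division by activation is singular as $a \to 0$. The moment arm in
the torque map is angle-dependent by default with `constant_arm`
available, since the control law's single symbol does not disambiguate.

## The synthetic gait generator

`synth_gait()` emulates steady treadmill walking at about 1.25 m/s:
stride time 1.1 s, stance fraction 0.60, and a plantarflexion-positive
ankle-angle keyframe shape — slight plantarflexion after heel strike,
progressive stance dorsiflexion to about −10°, rapid push-off
plantarflexion to about +15° just after the stance–swing transition,
return to neutral in swing. Keyframes are linearly interpolated
periodically and truncated to 8 Fourier harmonics, giving a smooth
(C¹-periodic) trajectory whose residual against the keyframe polyline is
reported as `fourier_trunc_error`. Events are exact: heel strikes sit on
stride boundaries by construction.

What the generator does *not* emulate matters for interpretation:
stride-to-stride variability beyond white angle noise, within-subject
kinematic adaptation to assistance (except through the admittance plant
below), ground-reaction mechanics, and any coupling of EMG or gas
exchange to the controller. Synthetic EMG is amplitude-modulated
band-limited (20–450 Hz) noise with per-stride burst windows — enough to
exercise the envelope pipeline, not a motor-unit model. Gas exchange is a
breath-wise (≈ 0.33 Hz) first-order rise to steady state with Gaussian
breath-to-breath noise; defaults (17.5 / 14.9 ml/s at 71.3 kg) give
walking-scale net metabolic rate near 5 W/kg at a respiratory exchange
ratio of 0.85. Tests passing on these fixtures certify the *pipeline
algebra* (filters, integrals, normalizations, statistics), not
physiological realism.

## Outcome metrics

Stride-averaged torque is the trapezoidal integral of the torque series
over each gait cycle divided by the stride time, body-mass normalized,
averaged over the last (up to) 10 complete strides after discarding the
first 2 as controller transient (delay-line and activation warm-up). Net
mechanical power applies the same average to the pointwise
torque × angular-velocity product; positive values are energy delivered
to the user. EMG envelopes are zero-phase 2nd-order Butterworth
high-pass (20 Hz), full-wave rectification, zero-phase 2nd-order
Butterworth low-pass (6 Hz), normalized per muscle to the peak
stride-averaged envelope of the zero-torque condition, summed over
SOL + MG + LG + TA (optionally volume-weighted). Metabolic rate converts
oxygen uptake and carbon-dioxide output with the Brockway coefficients
(16.58 J/ml O₂, 4.51 J/ml CO₂) and averages the final 2 minutes of a
7-minute trial.

## The admittance plant

Open-loop playback cannot reproduce the human response to assistance, so
`run_adaptive()` adds the smallest model that exhibits the relevant
negative feedback loop: low-pass-filtered exoskeleton torque maps through
a compliance `alpha` (rad/Nm) to a plantarflexion offset of the whole
trajectory, iterated to a fixed point. Early assistive torque then
plantarflexes the posture, shortens the virtual muscle, and reduces its
force and ongoing reflex activation — qualitatively the loop observed
when humans wear such controllers. This is a quasi-static emulation, not
a forward-dynamic musculoskeletal model; `alpha` has no calibrated
value, and the default (0.001 rad/Nm) is chosen only to keep the
iteration contractive (loop gain well below 1 for the default
geometry). Divergence is detected at runtime from the residual history.

## Numerical choices

* **Integrator.** The CE length update uses Heun's method at a fixed
  1 ms step (the real-time controller's command-rate scale). A plain
  forward-Euler step at 1 ms leaves a ~0.6% force discrepancy against a
  0.01 ms reference on smooth sinusoidal inputs; Heun brings this to
  ~10⁻⁴ relative while preserving the fixed-step, two-evaluation
  structure an embedded implementation could use. The second stage is
  evaluated at the end-of-step angle and activation.
* **Activation.** The first-order lag is advanced with its exact
  exponential one-step solution, so constant stimulation matches the
  closed form at any step size and $a = S$ is an exact fixed point.
* **Velocity inversion.** The concentric/eccentric inversion is
  algebraic (round-trip residual < 10⁻⁹ by construction). The active
  capacity $a f_L$ is floored at 10⁻³: as activation vanishes the force
  balance degenerates to a relay, and without the floor explicit
  integration chatters at ±`v_max` around the passive equilibrium.
  Velocity is clamped to ±`v_max`.
* **Delay line.** Linear interpolation between samples makes the delay
  exact (to machine precision) also when it is not an integer multiple
  of the step; reads before the first sample return 0 (cold start).
* **Filters.** Both EMG filters (and the torque low-pass of the
  admittance plant) are 2nd-order Butterworth applied forward-backward.
  Design cutoffs are pre-warped by Winter's double-pass factor
  $(\sqrt{2}-1)^{1/4} \approx 0.802$ so the stated cutoff is the −3 dB
  point of the combined zero-phase filter; without the correction a
  50 Hz tone loses 2.5% through the 20 Hz high-pass, with it ~1%.
* **Initial state.** `controller_reset()` solves the static equilibrium
  CE length for the initial angle by bisection (`uniroot`, tolerance
  10⁻¹²), falling back to `l_opt` with a warning.
* **Statistics.** The repeated-measures ANOVA uses the classical
  within-subject sum-of-squares decomposition with no sphericity
  correction by default (Greenhouse–Geisser available as `gg = TRUE`);
  pairwise comparisons are two-sided paired t-tests with the Bonferroni
  product-cap adjustment; identical columns are reported as p = 1 with a
  degeneracy flag rather than an error.

## Problem sizes

The test suite and the acceptance script run desk-scale problems chosen
to keep every check sharp: 6–10-stride noiseless trials at 1 kHz for the
controller sweeps, a 100-stride run for the boundedness property, a 2-s
sinusoid at 1 ms vs 0.01 ms steps for the integrator reference, 10,000
simulated 9 × 4 null matrices for the ANOVA type-I rate, and 10-s tones
at 960 Hz for the envelope oracles.

## Known limitations

* Under **fixed** kinematic playback, increasing the reflex Delay at
  fixed Gain *attenuates* the within-stance force build-up as well as
  shifting it: activation during the stance dorsiflexion ramp is lower,
  the CE yields faster at equal force, and the torque peak — pinned near
  the kinematic dorsiflexion peak — moves one or two milliseconds
  *earlier* per 10 ms of added delay, even though the activation peak
  moves later. A later torque peak under longer Delay therefore should
  not be expected from open-loop playback; it emerges only when the
  kinematics themselves respond to assistance. The package's own
  acceptance test of the naive shift expectation documents this
  (deliberately) as a failing property.
* The admittance plant is quasi-static and stride-global; it cannot
  capture within-stride timing changes of the human response, so
  Delay-condition effects that depend on those remain out of reach.
* The virtual muscle is a single lumped compartment without pennation,
  history dependence, or separate soleus/gastrocnemius paths; its
  metabolic cost is not modelled.
* Swing-phase hardware behaviour is idealized to exactly zero torque;
  cable-payout dynamics and any residual dorsiflexion resistance are not
  simulated.

## A worked sweep

```{r sweep, eval = FALSE}
trial <- synth_gait(gait_spec(), n_strides = 10)
sw <- run_sweep(trial)
sw$metrics
autoplot(sw)
```

On the default synthetic kinematics the sweep reproduces the expected
open-loop structure: zero torque and power in `NoPwr`, stride-average
torque increasing monotonically in Gain, and average torque decreasing
with Delay.
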