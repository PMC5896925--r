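---
title: "The stoopsim flight and pursuit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stoopsim flight and pursuit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoopsim)
```

stoopsim simulates aerial attacks by a peregrine falcon on a
starling-like prey bird in open, unbounded 3-D space, to ask when and why
the high-speed stoop pays off. This vignette is the package's account of
the model: the force law, the guidance and control chain, the prey
forcing functions, the numerical choices, and — importantly — what the
reduced model can and cannot reproduce.

## Flight mechanics

Each bird is a rigid body with six degrees of freedom, its roll axis
pinned to its velocity (perfect pitch/yaw stability; birds bank to
turn). Translation integrates

$$\vec F = TD\,\hat e_{x'} + L\,\hat e_{z'} - m g \hat e_z$$

by velocity Verlet; roll follows explicit Euler on the bank angle and
roll rate. The aerodynamic pair $(L, TD)$ — lift and net
thrust-minus-drag, both wingbeat-averaged — comes from a quasi-steady
closed-form force law:

* **Flapping** (full span, maximum wingbeat frequency $f$): thrust
  $(1 - c_l^2/c_{l,max}^2)\,\tfrac{\pi^3}{16}\rho b^2 \sin^2(\theta/2)
  f^2 l_w^2\,c_{torque}$, with $c_{torque} = \min(1, v_{thresh}/v)$
  capping sustainable muscle torque above a species speed threshold
  (equivalent to a roughly constant available flight power), minus
  parasite drag $(c_{d,body}S_b + c_{d,fric}S_w)\tfrac12\rho v^2$ and
  lifting-line induced drag $c_l^2 S_w \rho u^2 / (2\pi AR)$.
* **Gliding**: no thrust; the bird retracts its wings. Wing area shrinks
  linearly with span, $S_w = S_{w,max}(b - b_{min})/(b_{max} -
  b_{min})$, and the drag-optimal span for a lift demand $L^*$ has the
  closed form $b^* \propto (L^{*2})^{1/3}$, truncated by the span range,
  the muscle-torque bound and the stall limit $c_l \le c_{l,max}$.

Two quantities use a dynamic pressure augmented by the mean-square
flapping speed of the wing, $u^2 = v^2 + \tfrac12(\pi f
\sin(\theta/2)\,l_w)^2$: the stall-limited lift while flapping, and the
lift coefficient entering the flapping thrust/induced terms. Without
this, level flight below about 8 (falcon) / 5.7 (starling) m/s would be
aerodynamically impossible, contradicting both wind-tunnel observations
of slow flight and the model's intended minimum speeds; with it, the
starling's maximum level acceleration at 8 m/s is about 5.6 m/s²,
matching the 5–6 m/s² reported for released starlings. Gliding uses
$v^2$ unmodified.

Maximum lift is capped physiologically at $L_0 = 1.7\,m g$ at full span
(an allometric limit on shoulder torque); retraction shortens the moment
arm, so the torque-limited lift *grows* as the wing tucks, which is why
a diving falcon can pull many times its weight. Throughout the package
the torque bound uses the moment-arm convention $L\,(b - b_{min}) \le
L_0\,(b_{max} - b_{min})$ — the convention embedded in the closed-form
maximum-lift span — so that every demand below the maximum-lift envelope
is actually achievable by the retraction cascade (the alternative
full-span-referenced arm produces a non-monotone feasible set at high
speed).

Roll torque comes from antisymmetric lift applied at quarter-span,
$M = L\,b/4$; the span that maximizes lift also maximizes roll
acceleration, and the roll inertia combines the measured body inertia
with wing inertia transferred to the centre of mass at the current
retraction.

### Morphology and calibration

Species parameters (`falcon_morphology()`, `starling_morphology()`) are
empirical: wingbeat frequency, wing length/span/area, masses, inertias,
flapping amplitude, body area, drag coefficients, the torque-threshold
speed and the stall lift coefficient. Three choices deserve note:

* **Flying mass** is $m_b + 2 m_w$. This reproduces published terminal
  dive speeds (126 vs ~123 m/s falcon; 49.6 vs ~52 m/s starling) at the
  cost of slightly high minimum level speeds.
* **Wing friction coefficients** default to fixed species constants
  (falcon 9.35e-3, starling 14e-3), assigned so that the smaller,
  slower, lower-Reynolds-number bird carries the larger laminar
  coefficient — the ordering Blasius scaling requires — and calibrated
  so the maximum level speeds reproduce published estimates (≈28.6 and
  23.9 m/s). A dynamic Blasius mode (`friction = "blasius"`) is
  available; it overshoots both top speeds by 7–11%.
* **Air** is ISA sea level ($\rho$ = 1.225 kg/m³, $g$ = 9.81 m/s²,
  $\mu$ = 1.81e-5 Pa s), overridable via `flight_constants()`.

```{r envelope}
envelope_speeds(falcon_morphology())
envelope_speeds(starling_morphology())
```

The minimum sustained speeds come out 8.6 and 5.1 m/s — 10–20% above the
7.3 / 4.5 m/s the full blade-element treatment yields, because in the
closed form the flapping thrust vanishes quadratically as the lift
coefficient approaches stall. This is a known bias of the reduced force
law, not a tunable.

## Vision and guidance

The falcon senses only the line of sight to its prey. Every $\tau$
seconds (default 50 ms) it measures the relative position with an
angular error of magnitude uniform in $[0, \xi]$ and direction uniform
on the circle perpendicular to the true line of sight, differences two
successive measurements into a relative velocity, and forms the
line-of-sight rate $\dot{\vec\lambda} = \hat r_d \times \hat v_d /
|\hat r_d|^2$, held constant between samples. Guidance is pure
proportional navigation, $\vec a^* = N\,\dot{\vec\lambda} \times \vec
v$ — perpendicular to the velocity by construction, steering the
attacker onto a constant-bearing collision course at a rate set by the
navigation constant $N$.

The error bound $\xi$ is physically a *rate* threshold: the minimum
detectable retinal image motion (~8°/s ≈ 0.14 rad/s) accumulated over
one differencing interval. The default therefore scales as $\xi =
0.14\,\tau$ (0.007 rad at the 50 ms baseline). This matters: with a
fixed 0.007 rad bound, finite differencing over $\tau$ = 0.1 ms would
turn the rate estimate into pure noise (~140 rad/s), and
near-instantaneous vision would paradoxically be the *worst* setting.
An explicit `xi` can still be fixed independently for robustness
studies. A continuous-delay mode is deliberately not implemented beyond
this sample-and-hold; the hook is the `tau`/`xi`/`error_mode` triple of
`engagement_config()`.

## Control

The commanded acceleration is gravity-compensated ($\vec a^* + g\hat
e_z$; the component along the flight direction is discarded — thrust is
always maximized) and projected onto the body's lateral/dorsoventral
plane. Its magnitude times mass is the lift demand, resolved by
whichever flight mode meets it most closely with the largest net
thrust; unattainable demands saturate at the maximum attainable lift.
Its direction sets the roll target: the signed angle
$-\mathrm{atan2}(a_{y'}, a_{z'})$ that aligns the lift axis with the
demand under the package's right-handed axis convention.

Roll control is minimum-time (bang-bang): maximal roll acceleration
toward the target bank, switching to maximal braking once
$\omega^2 > 2\dot\omega_{max}|\gamma|$. Discretely, a pure switching
law chatters at $\pm\dot\omega_{max}$ around the target, which would
inflate the mean roll acceleration of a gently maneuvering bird a
hundredfold; inside a 0.02 rad zone the engine therefore switches to a
critically damped linear law (a proximate time-optimal servo,
gain-limited for coarse time steps). Far-field behavior — the switch at
half the angle, the $2\sqrt{\gamma/\dot\omega_{max}}$ maneuver time —
is unchanged.

## Prey forcing functions

The model-starling does not react to the falcon; it flies one of three
open-loop programs, each scaled by its currently attainable normal
acceleration $a_{max}(v)$ and each with a vertical restoring term
$c_7\kappa$ (or $c_4\kappa$) that holds it near its starting altitude:

* **straight**: steer onto a fixed random heading (elevation within
  ±2.5°) and hold it;
* **smooth**: lateral harmonic forcing $\hat h\,(c_1\sin c_2 t +
  c_1)^{c_3} a_{max}$ with $\hat h$ horizontal and perpendicular to the
  velocity. The exponent $c_3 = 0.13$ produces a near-saturating,
  smoothly pulsing command; read multiplicatively the same constant
  would cap the command at 18% of $a_{max}$ and the calibrated maneuver
  regime could not arise;
* **nonsmooth** (jinking): $\vec q\,c_6 a_{max}$ where the unit
  direction $\vec q$ is re-drawn (blended by $c_8$ with a random
  near-horizontal direction, elevation within ±20°) at ~80 switches per
  second. The switch probability is defined per reference step (1e-4 s)
  and rescaled with the integration step, so the switching *rate* is a
  property of the prey, not of the integrator.

```{r prey}
prey_flight_stats(starling_morphology(), prey_params("smooth"),
                  duration = 30, dt = 1e-3, seed = 2)[1:4]
```

### Fidelity limits of the prey regime

Under the closed-form force law, saturated maximum-lift gliding costs
about 5 m/s² of deceleration at 15 m/s, and no flap/glide duty cycle
sustains a mean load factor above ≈2.5; the closed-loop prey therefore
equilibrates near 6 m/s at a mean load factor of ≈1.1, rather than the
~15 m/s, 3.4-load regime a time-resolved blade-element optimization
(which trades wing twist against induced loss within the stroke)
sustains. Smooth-mode mean roll acceleration (~20–25 rad/s²) is
reproduced; mean load factor and the jinking roll statistic (~1000 vs
~2000 rad/s²) are not. Downstream, a slower prey is easier to catch
from low-altitude attacks, which flattens the advantage of the
high-altitude stoop in the strategy optimization: the package's sweeps
locate the catch-probability optimum at low N but low starting
altitude, and the catch fraction at the steep-dive optimum is ~0.3–0.45
rather than ~0.64. Tests assert the published regime at full strength
and fail where the reduced model cannot reach it, so the gap is
measured, not hidden.

## Engagements and experiments

An engagement starts with the prey at the origin (random orientation,
11 m/s — its minimum-cost-of-transport speed) and the falcon at a given
altitude and horizontal distance, flying at 16 m/s straight at the
prey, wings level. Each step: prey forcing → prey control/physics;
falcon vision (every $\tau$) → PPN → control/physics; then termination
checks in order — catch (within 0.2 m), unrecoverable near-miss (was
within 5 m, now farther with the prey in the falcon's rear 45° blind
cone), timeout (40 s). One seed fully determines one engagement.

`sweep_strategies()` draws attack strategies uniformly ($N \in [1,20]$,
altitude $[-200, 1500]$ m, distance $[0, 800]$ m), and
`fit_catch_surface()` interpolates catch probability with a logistic
GAM (additive thin-plate smooths of the three coordinates, penalized
likelihood smoothness selection, no EDF cap — mgcv); optima are read
off a 50³ grid. Additive smooths were chosen over a full tensor
interaction for stability at the desk-scale sample sizes; the optimum
location was insensitive to this choice in our checks.
`robustness_sweep()` repeats this over $\tau$, $\xi$ or $\chi$;
`capped_performance_experiment()` re-runs stoops with the falcon's lift
and/or roll acceleration capped at their sustained-level-flight (30
m/s) values, including a level 112 m/s attack variant.

## Numerical choices

* **Time step** 1e-4 s by default (convergence verified by the
  `convergence_report()` discrepancy, which contracts strongly per dt
  decade); sweeps may use 1e-3 s, which changes catch fractions by well
  under the between-condition differences of interest. The bundled
  strategy-optimization check runs 2000 engagements per condition at
  dt = 1e-3 and stochastic checks at 50–60 engagements; confidence
  intervals are reported with every catch fraction.
* **Axes** are recomputed from the velocity each step and rolled by the
  carried bank angle; the wings-level datum keeps the lateral axis
  horizontal, falling back to the previous lateral axis when the
  velocity is vertical. Orthonormality is maintained to 1e-12.
* **Degenerate wing** at $b = b_{min}$: zero area, induced and friction
  terms vanish, aspect ratio unused; the friction coefficient falls
  back to the species constant.
* **First $\tau$ window**: no rate estimate exists, so the guidance
  command is held at zero until two sightings are available.
* **Measurement noise** is redrawn per visual sample (not per
  integration step), so the number of random draws is independent of
  dt and seed-matched runs at different step sizes remain comparable;
  the convergence scenario uses smooth-maneuvering prey for the same
  reason.
* **Caps below 2^31** on all derived seeds.

## Known limitations

No unsteady aerodynamics, no within-wingbeat force variation, no tail
or pitch/yaw dynamics, no wind, no ground, no talon-strike mechanics,
no reactive evasion by the prey. The force law is a wingbeat-averaged
reduction whose high-load thrust penalty is harsher than a full
blade-element optimization; the consequences for the prey's attainable
maneuver regime and for the strategy-optimum location are quantified
above and in the test suite.
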