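---
title: "Methods: dynamics, calibration and synthetic trials for a counterweighted fall simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics, calibration and synthetic trials for a counterweighted fall simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallfit)
```

## The apparatus and its idealization

The device this package models is a fall-simulation platform: an inverted
pendulum the participant lies on in a prone position, held at an
adjustable lean angle by an electromagnet and released at an
unpredictable time. A cable from a sprocket on the platform axle (radius
`r`) runs over four ceiling pulleys to a hanging counterweight, so that
raising the counterweight load lowers the fall acceleration. Releasing
the platform forces a rapid protective arm reaction; varying lean angle
and counterweight decouples impact velocity from fall height.

The idealization is deliberately minimal:

* the participant + platform are a point mass `m1` at height `L` from the
  axle, so the moment of inertia is `m1 * L^2`. This is forced by the
  governing equation's structure — dividing the moment balance through by
  `m1` leaves the masses only as the ratio `rho = m2/m1` — and matches
  how single-segment inverted-pendulum models of standing posture are
  normally written;
* the cable is inextensible and massless, the pulleys inertialess; the
  counterweight rises exactly four times faster than the cable attachment
  point moves;
* each of the four pulley wraps spans a fixed angle of pi radians and
  multiplies cable tension by the capstan factor `exp(mu_F * pi)`; the
  total resisting force at the sprocket is the *sum* of the four wrapped
  tensions, giving the aggregate factor
  `C1 = sum_k exp(k * mu_F * pi)`, `k = 1..4`;
* nothing after mat contact is modelled. The platform meets the gym mats
  near 85 degrees from vertical and the shock absorbers at 90; both are
  annotated as events, but the rigid-body model simply stops being a
  description of the system there.

One modelling note deserves emphasis: with the friction cascade written
this way, friction *amplifies* the resisting force transmitted from the
counterweight (each wrap multiplies the tension by `exp(mu_F * pi) > 1`).
A capstan holding a load normally attenuates the tension felt on the far
side. We implement the amplifying form deliberately, because it is the
form under which the calibration below is defined and the fitted friction
coefficient interpreted; readers who prefer the attenuating sign can
negate `mu_F`'s role by reading `C1` as a four-term geometric factor in
`exp(-mu_F * pi)`. Nothing else in the package changes. For the same
reason the tension equation uses the gravity-included form
`F = 4 m2 r theta_ddot + m2 g` throughout.

## Equations of motion and the closed-form speed

With `theta` measured from vertical (0 upright, pi/2 horizontal), the
angular acceleration is

$$\ddot\theta \;=\; \frac{gL\sin\theta - C_1 r g \rho}{L^2 + 4 C_1 r^2 \rho},
\qquad \rho = m_2/m_1 .$$

Two consequences the code leans on:

* **Balance threshold.** The fall starts iff
  `g L sin(theta0) > C1 r g rho`. Because `sin(theta)` only grows on the
  way to horizontal, a fall that starts never stalls before 90 degrees;
  "balanced" and "readout unreachable" coincide for readouts at or below
  horizontal. `simulate_fall()` flags balanced configurations instead of
  integrating them.
* **First integral.** The coefficients are angle-independent except for
  the gravity term, so multiplying by `theta_dot` and integrating from
  release at rest gives
  $$\tfrac12\,(L^2 + 4C_1r^2\rho)\,\dot\theta^2
    = gL(\cos\theta_0-\cos\theta) - C_1 r g\rho\,(\theta-\theta_0).$$
  `closed_form_speed()` evaluates this directly. It is used as the
  forward model inside the fit (fast, exact) and as the *oracle* against
  which the numerical integrator is verified — two routes to the same
  quantity that are kept strictly separate in the tests.

A subtle corollary: as `m2` approaches the balance threshold from below,
the readout speed does **not** approach zero. The gravity integral still
exceeds the counterweight integral over the whole fall, so the speed at
70 degrees tends to a strictly positive limit and then drops
discontinuously to "no fall" at the threshold. `solve_counterweight()`
therefore reports targets between zero and that limit as infeasible, and
reserves a target of exactly zero for "the smallest mass that prevents
the fall".

## Numerical integration

`simulate_fall()` integrates the two-state system with `deSolve::lsodar`
(adaptive, `rtol = 1e-10`, `atol = 1e-12`). Angle landmarks (70-degree
readout, 85-degree mat contact, 90-degree horizontal by default) are
located by the solver's own root-finding on `theta(t) - theta_landmark`,
never by nearest-sample lookup; integration proceeds landmark to
landmark, restarting from each crossing. Monotonicity of `theta` on the
falling branch is asserted as an internal-consistency check. Across a
5-dimensional grid of `L`, `r`, `mu_F`, `rho` and release angle the
integrated readout velocity agrees with the closed form to about 1e-9
rad/s — four orders tighter than the 1e-6 the package promises.

## Signal processing

The trial-processing chain mirrors standard motion-capture practice for
150 Hz kinematics:

1. dual-pass (zero-phase) 2nd-order Butterworth low-pass at 10 Hz. The
   filter is designed with `signal::butter` and applied forward and
   backward by an implementation that odd-reflects the series at both
   ends and starts each pass in steady state at the first sample, so a
   constant passes through exactly and edge transients are strongly
   suppressed (the same construction scipy's `filtfilt` uses);
2. differentiation by central differences (one-sided at the ends),
   second-order accurate at 150 Hz;
3. linear interpolation of the angular-velocity trace at the single
   upward crossing of the readout angle (at 150 Hz the platform moves
   well under a degree per sample near the readout, so linear
   interpolation is ample);
4. impact as the first sample with vertical ground reaction force
   strictly above 10 N; release as the first sample 0.5 degrees above
   the initial angle (the angle-based onset rule is this package's
   choice; the differentiation scheme likewise).

Sampling a simulated fall at 150 Hz and running this chain reproduces the
integrator's readout velocity to about 6e-4 rad/s, within the 1e-3
budget; the residual is dominated by the filter's treatment of the series
end just past the readout.

## Calibration

The fit maximizes the variance accounted for,
`r2 = 1 - SS_res/SS_tot`, between measured readout velocities and the
closed-form prediction. Since `SS_tot` is fixed by the data, the
implementation minimizes `SS_res` — same optimum, better conditioning.
Two designs are supported:

* **Experiment 1** (varying lean angle, no counterweight): one global `L`
  over all participants, seeds 0.8–1.8 m in 0.2 m steps, bounds
  [0.5, 2.0] m.
* **Experiment 2** (fixed lean angle, varying counterweight): joint
  `(L, mu_F)` with `mu_F` seeds {0, 0.1, 0.2, 0.4} and bounds [0, 1];
  per-trial `rho` uses participant mass plus the 14.4 kg effective
  platform mass.

Each start runs bounded L-BFGS-B; a final polish from the best start uses
a tight convergence target and a 1e-6 finite-difference step, which is
what lets noiseless self-fits reach `r2 = 1` to near machine precision
rather than ~1e-8. Configurations a candidate parameter vector renders
unreachable predict zero velocity, which keeps the objective finite and
repels the optimizer. Balanced trials carry no readout observation and
are excluded with a message, never silently. An optional mode fits the
proportionality constant `k` in `L = k * height` instead of a global
`L`, reflecting the center-of-mass-at-fraction-of-height reading of the
pendulum length; the global-`L` default matches how the apparatus is
calibrated in practice.

`m1` is participant mass plus 14.4 kg of effective platform mass by
default. Only `rho = m2/m1` enters the dynamics, so an alternative `m1`
convention rescales the fitted `mu_F` and `L` rather than invalidating
them; the convention is an explicit, documented argument everywhere it
matters.

## Synthetic cohorts and trials

The generator emulates the two validation protocols so that processing
and fitting are testable end to end:

* **Cohorts.** Heights and masses are truncated-normal draws matching
  the published cohort summaries: experiment 1 pools 14 younger adults
  (173.9 ± 10.0 cm, 159–191; 78.9 ± 4.6 kg, 54.4–103.0) and 13 older
  adults (175.2 ± 9.0 cm, 157–189; 77.3 ± 15.0 kg, 56.3–104.8);
  experiment 2 has 13 younger adults (185.7 ± 6.1 cm, 174–193;
  82.4 ± 5.6 kg, 77.4–92.1). Truncation to the printed ranges shifts the
  realized means slightly off the nominal ones where the ranges are
  asymmetric; the tests check against the analytic truncated-normal
  moments.
* **Designs.** Experiment 1: two falls from each of 65, 52, 45, 39
  degrees (jitter sd 3 degrees); experiment 2: lean angle 37 ± 1 degrees
  with counterweights 6.8, 12.4, 17.9, 29.1 %BW (sds 0.4, 0.8, 1.1,
  1.7). The published condition tables report these spreads as achieved
  mean ± sd, so the generator treats them as Gaussian jitter. Condition
  order is a random permutation per participant. %BW converts to
  kilograms against the corrected total mass (body + platform) by
  default; a `pct_mode` flag switches to body mass alone, since the
  protocol's wording supports either reading.
* **Observation model.** The angular velocity at the readout is the
  closed-form value plus independent Gaussian noise (sd 0.05 rad/s by
  default — a few percent of typical readout speeds, chosen once as a
  plausible marker-based measurement error; no empirical noise model is
  published). Optional raw traces emulate a capture window: 0.5 s
  pre-release hold, the integrated fall resampled at 150 Hz by cubic
  Hermite interpolation, an 80 ms raised-cosine deceleration after the
  90-degree contact (a hard stop would put an unphysical velocity step
  under the filter), and a 1 s hold; the ground-reaction channel is a
  minimal 50 N step at the contact sample over bounded sub-threshold
  noise — only the 10 N rule is exercised, no impact-force realism is
  attempted.

Under the fitted counterweight-experiment parameters, the largest
counterweight level exceeds the balance threshold at the 37-degree lean:
the printed equations predict those configurations do not fall. The
generator flags them balanced (about a quarter of experiment-2 trials),
and the fit proceeds on the remaining levels. This is a property of the
equations plus the published operating point, not an implementation
choice, and it is the main respect in which the synthetic data are *less*
rich than the laboratory data, where all four levels produced falls —
passing recovery tests here demonstrates correctness of the pipeline, not
fidelity of the amplifying-friction cascade at high loads.

What the synthetic data deliberately do not contain: per-participant
deviations from the global `L` (unless generated in height mode),
serially correlated noise, marker dropout, trial-to-trial fatigue
effects, or any post-impact dynamics. Parameter-recovery results should
be read with those absences in mind.

## Verification problem sizes

The shipped checks use the protocol-sized designs: 27 × 8 lean-angle
trials and 13 × 8 counterweight trials for recovery (noise sd 0.05
rad/s), a 4^5-point grid for the integrator oracle, 300 randomized
configurations for the balance threshold, and five representative
configurations for the sampled-data round trip. With these sizes the
recovery errors are roughly 0.003 m in `L` (experiment 1) and
(0.02 m, 0.001) in `(L, mu_F)` (experiment 2), comfortably inside the
±0.02 m / (±0.05 m, ±0.03) bands the package asserts; noiseless
self-fits return `r2 = 1` to better than 1e-9.

## Known limitations

* The counterweight-pulley (outer sprocket) radius is not published; the
  default `r = 0.1875` m is half the printed 14.76-inch inner-sprocket
  diameter and is configurable everywhere.
* The amplifying direction of the capstan cascade (above) is retained as
  defined; at large `mu_F` and load it produces the balance behaviour
  described in the synthetic-trials section.
* `r2` is computed on pooled trials, one global parameter vector per
  experiment; no per-participant random effects, and no confidence
  intervals on `(L, mu_F)` beyond the residual tables.
* The balance threshold is a knife edge in `m2`; near it, tiny mass or
  angle jitters flip trials between falling and balanced, which is why
  the generator flags rather than drops.
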