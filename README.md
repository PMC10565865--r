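# fallfit

Dynamics, fitting and prediction for counterweighted inverted-pendulum
fall simulators.

Forward-fall experiments in biomechanics and rehabilitation research often
drop participants from a fixed height, which makes the impact velocity
predictable and lets participants pre-plan their protective arm reaction.
An instrumented release platform — an inverted pendulum the participant
lies on, released by an electromagnet from an adjustable lean angle and
coupled through a four-pulley cable system to a counterweight — breaks
that predictability: the counterweight modulates the fall acceleration in
a way the participant cannot anticipate. The price is that the impact
velocity is no longer a simple function of drop height. This package
implements the dynamic model of that apparatus, the signal-processing and
fitting pipeline that calibrates it against motion-capture trials, and the
inverse design problem (what counterweight gives a prescribed impact
velocity), together with a synthetic-cohort trial generator so the whole
chain is testable without access to laboratory recordings.

## The model

The participant and platform are idealized as a point-mass inverted
pendulum (mass m₁, center-of-mass height L) rotating about the axle, so
I = m₁L². The counterweight m₂ hangs from a cable that leaves a sprocket
of radius r and wraps four pulleys, each through angle π. Capstan
(Euler–Eytelwein) friction multiplies the cable tension by e^{μ_F π} per
wrap, and the total force at the counterweight pulley sums the four
wrapped tensions, giving the aggregate factor

    C1 = e^{μπ} + e^{2μπ} + e^{3μπ} + e^{4μπ}   (C1 = 4 when μ = 0).

The counterweight rises four times faster than the cable attachment point
moves, so its tension is F = 4 m₂ r θ̈ + m₂ g, and the moment balance about
the axle yields, with ρ = m₂/m₁,

    θ̈ = ( g L sin θ − C1 r g ρ ) / ( L² + 4 C1 r² ρ ).

With no counterweight this is the familiar θ̈ = g sin θ / L. Because the
coefficients do not depend on time, the equation has an exact first
integral (an energy balance),

    ½ (L² + 4 C1 r² ρ) θ̇² = g L (cos θ₀ − cos θ) − C1 r g ρ (θ − θ₀),

which the package uses both as the fast forward model for fitting and as
an independent oracle for the numerical integrator. A configuration with
g L sin θ₀ ≤ C1 r g ρ is *balanced*: the platform does not fall.

Calibration maximizes the variance accounted for (r² = 1 − SSres/SStot)
between model-predicted and measured angular velocity at the 70° readout
angle — the largest angle before anything touches the landing mats — over
L alone (lean-angle experiments, no counterweight) or (L, μ_F) jointly
(counterweight experiments), by bounded multi-start quasi-Newton
optimization.

## Worked example

```r
library(fallfit)

## a 78.9 kg participant on the 14.4 kg platform, CoM height 1.21 m
p <- fall_params(L = 1.21, m1 = 78.9 + 14.4)
simulate_fall(p, theta0_deg = 65)
#> Simulated fall trajectory
#>   release: 65.00 deg from vertical
#>   54 states over 0.340 s
#>   readout_70deg       70.0 deg at t = 0.1536 s, theta_dot = 1.1432 rad/s
#>   mat_contact_85deg   85.0 deg at t = 0.3048 s, theta_dot = 2.3323 rad/s
#>   horizontal_90deg    90.0 deg at t = 0.3401 s, theta_dot = 2.6178 rad/s
```

The fall from a 65° lean crosses the 70° readout at 1.14 rad/s and meets
the mats (85°) at 2.33 rad/s a third of a second after release.

```r
## synthetic lean-angle experiment: 27 participants x 8 falls,
## measurement noise sd 0.05 rad/s on the readout velocity
roster <- generate_cohort(cohort_exp1(), seed = 1)
trials <- generate_trials(roster, experiment_design("exp1"), L = 1.21, seed = 2)
fit <- fit_fall_model(trials, experiment = 1)
fit
#> Fall-model fit (experiment 1, 216 trials)
#>   L_hat    = 1.2062 m
#>   r2       = 0.9941  (variance accounted for)
```

The fit recovers the generating pendulum length (1.21 m) to well under a
centimetre; `coef`, `predict`, `residuals`, `plot`, `summary` and
`simulate` methods give the usual modelling workflow.

```r
## inverse design: counterweight for a 1.8 rad/s readout velocity at 37 deg
pcw <- fall_params(L = 1.30, m1 = 96.8, mu_F = 0.18)
solve_counterweight(pcw, theta0_deg = 37, target_speed = 1.8)
#> [1] 11.65  # kg
```

A command-line surface wrapping the same functions is installed at
`exec/fallfit` (subcommands `simulate`, `fit`, `generate`, `predict`);
see `?fallfit_cli`.

## Scope

The model covers the released fall up to mat contact: no impact
mechanics, cable elasticity, pulley inertia, or electromyography-related
outcomes. Counterweight loads are expressed in percent of body weight,
with the corrected convention (body mass + 14.4 kg effective platform
mass) by default. See the methods vignette
(`vignettes/fall-model-methods.Rmd`) for assumptions, parameter defaults
and known limitations.
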