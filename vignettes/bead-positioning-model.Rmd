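---
title: "Modelling magnetic capture of a ferrogel bead in tube flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling magnetic capture of a ferrogel bead in tube flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrobead)
```

## The problem

A millimetre-scale calcium-alginate ferrogel bead — a swollen biopolymer
sphere filled with magnetite particles — travels with a water stream through
a horizontal tube. An electromagnet pressed against the tube wall tries to
pull the bead out of the stream and hold it in place. Depending on the
surface field strength the bead either passes, touches the wall and rolls
away ("detached"), or is arrested over the core ("captured"). `ferrobead`
implements the full model chain for this system: the bead's composition and
susceptibility, the magnetostatic attraction force, reduced-order
hydrodynamics, and the force-balance trajectory simulation.

## Composition chain

The bead's magnetic response is set by how much magnetite it carries. From
two routine measurements — the gravimetric swelling ratio
$\alpha = (m - m_0)/m_0$ and the integral thermogravimetric weight losses of
the blank hydrogel ($\Delta_{HG}$) and the ferrogel ($\Delta_{FG}$) — the
chain computes

* the filler weight fraction in the dry gel,
  $\gamma = 1 - \Delta_{FG}/\Delta_{HG}$ (the magnetite survives heating, so
  a filled gel loses proportionally less mass),
* the swelling ratio of the polymer matrix alone,
  $\alpha' = \alpha/(1-\gamma)$,
* the filler weight fraction in the swollen bead,
  $\omega = \gamma/(1+\alpha)$,
* the filler volume fraction $\phi = \omega\,\rho_{gel}/\rho_{particle}$
  (dilute approximation), and
* the bead susceptibility by linear scaling from a reference epoxy-magnetite
  composite, $\chi = \chi_{ref}\,\phi/\phi_{ref}$ with
  $\chi_{ref} = 0.408$ at $\phi_{ref} = 9.57\%$.

```{r composition}
gel_composition(alpha = 4.5, loss_hg = 86.32, loss_fg = 26.07,
                chi_override = 0.13)
```

The magnetite particle density is not part of the measurement set; the
default 5180 kg/m³ (bulk magnetite) is exposed as a parameter. For the
reference bead the chain yields $\chi \approx 0.116$, somewhat below the
measured bead value 0.13; since the volume fraction entering the
calibration is inferred rather than measured, the chain reports its own
value and accepts a measured override, which downstream modules then use.
All public interfaces work in mass/volume fractions in $[0,1]$; percentages
appear only in formatted output, which avoids silent factor-100 errors.

## Magnetics

The electromagnet's axial field follows the calibrated linear decay
$H(z) = H_0(1 - 0.073\,z)$ with $z$ in millimetres from the core surface,
clamped at zero. The attraction force on a single linearly magnetizable
sphere between face fields $H_1$ (far) and $H_2$ (near) is

$$F \;=\; \mu_0\,\frac{\chi}{1 + N\chi}\,\frac{V}{d}\,\frac{H_2^2-H_1^2}{2},$$

with demagnetization factor $N = 1/3$ for a sphere. For the linear field
law this expression equals the volume average of
$\mu_0\chi_{\mathrm{eff}}H\,\mathrm{d}H/\mathrm{d}z$ over the sphere — the
test suite checks it against a brute-force slice integral — and it scales
exactly quadratically in $H_0$. At 37.4 kA/m surface field and a 4 mm gap
the single-bead prediction is about $7\times10^{-5}$ N, well below the
per-bead force measured on a dense bead monolayer (0.178 mN): neighboring
magnetized beads add to the field each bead feels.

`array_force_curve()` corrects for this. Each neighbor of induced moment
$m$ at spacing $s$ contributes an axial dipole field $2m/(4\pi s^3)$
(first-type, adjacent along the field-projected chain; second-type
neighbors contribute exactly one eighth). The moments are solved
self-consistently by damped fixed-point iteration (damping 0.5, relative
tolerance $10^{-9}$, at most 100 iterations) — for constant $\chi$ the
fixed point is linear and the damping guarantees convergence for
$\chi \le 1$. Correction levels `none`, `first` and `first_and_second` are
ordered pointwise, and because the enhancement factor is field-independent
for constant susceptibility, every curve remains exactly quadratic. The
corrections are enhancing (the axial dipole term), matching the observation
that interaction raises the per-bead force toward the measured values; an
in-plane (opposing) geometry can be configured via the neighbor counts.
The optional `first_plus_curve` level replaces the constant susceptibility
by the field-dependent anhysteretic value $\phi\,M(H)/H$ from the filler
loop, for studies of magnetization-curve effects.

Magnetization loops are parameterized as two hyperbolic-tangent branches
$M_\pm(H) = M_s\tanh((H\pm H_c)/H_s)$, with the shape field
$H_s = H_c/\operatorname{artanh}(M_r/M_s)$ chosen so each branch passes
through both the coercive point and the remanence point. For the reference
magnetite ($M_s = 388$, $M_r = 30$, $H_c = 6.2$ kA/m) this gives
$H_s \approx 80$ kA/m; a consistency check links the loop back to the
composition chain, since $\phi\,M_s/H_s \approx 0.13$, the measured bead
susceptibility. Loop-parameter extraction recovers $H_c$ from interpolated
branch zero crossings and $M_r$ from the branch intercepts at zero field.
For $M_s$, the mean of $|M|$ over the top 5% of $|H|$ is only a starting
value: on a ±200 kA/m grid the loop is not saturated at the edge and that
tail mean sits about 2% low, so the estimate is refined by solving the
one-parameter branch-model equation
$M_s\tanh((H_{max}-H_c)/H_s(M_s)) = M_{obs}(H_{max})$, which round-trips
generated loops to well under 0.5%.

## Hydrodynamic closures

The full moving-body computational fluid dynamics of the original study is
replaced by analytic closures — the central, acknowledged simplification of
this package. The undisturbed flow is the laminar tube profile
$u(r) = 2U(1 - r^2/R^2)$ (the tube Reynolds number, ~2500, is transitional,
but the reference model also treats the medium as laminar; a plug profile
is available as a configuration switch). On the bead act:

* **Drag**: Schiller–Naumann, $C_D = (24/Re)(1 + 0.15\,Re^{0.687})$, on the
  slip velocity, times a Faxén-type near-wall factor
  $1/(1 - \tfrac{9}{16}\xi + \tfrac{1}{8}\xi^3)$, $\xi = a/(a+gap)$, capped
  at 3 so it stays bounded and continuous at contact. The correlation is
  validated to $Re \approx 800$; beyond that a warning is issued and the
  value still returned.
* **Lift**: a Saffman-form magnitude
  $C_L\,\mu d^2 |V_{rel}| \sqrt{S/\nu}$ with a wall-decay factor
  $(d/(d+gap))^2$, directed away from the nearest wall. The coefficient
  $C_L = 2.6$ exceeds Saffman's small-Reynolds value 1.615 because at the
  bead's slip Reynolds numbers (order $10^2$–$10^3$) the wall-induced
  inertial lift is stronger than the unbounded-shear asymptote; it is set
  so that the reference bead travels suspended in the stream rather than
  rolling along the wall, which is how the experiment was operated.
* **Net weight**: $(\rho_{bead}-\rho_{fluid})\,V g$, about
  $7.6\times10^{-6}$ N for the reference bead.

Two finite-size refinements connect the point closures to a bead whose
diameter (2.38 mm) is a third of the tube bore:

* the profile velocity the bead samples is shielded near the wall by
  $(1 - 0.85\,a/(a+gap))$ — a bead rolling on or skimming the wall sees
  much slower fluid than the profile value at its center height (blockage,
  boundary layer, rolling kinematics; the classic rolling-sphere results
  put the translation speed of a free sphere at roughly half the shear
  velocity at its center). A welcome side effect is that transit speeds
  come out near 0.3 m/s, the scale observed on video;
* the slip driving the lift includes the shear sampled across the bead
  radius, $S\,a \cdot gap/(gap+a)$, fading at the wall where the lower
  face sits in nearly stagnant fluid.

All closure forces are continuous in the wall gap at contact, so the
integrator sees no force jumps.

## Dynamics

The bead state is $(x, y, v_x, v_y)$ in the vertical symmetry plane, with
$y$ the height of the bead center above the inner wall nearest the magnet.
A classical fourth-order Runge–Kutta scheme integrates Newton's equations
with an added-mass coefficient of 0.5 (the bead is nearly neutrally
buoyant, so unsteady fluid inertia matters). Wall contact is inelastic:
penetration is projected back to $y = a$ and the wall-normal velocity
zeroed; tangential motion is frictionless, rolling resistance being
absorbed into the drag calibration. The magnetic force uses the local field
magnitude — axial decay times a Gaussian lateral roll-off over the core
footprint (weight 0.05 at 1.5 core radii) — with central finite differences
over the bead extent supplying both force components.

A single drag-calibration constant (default 0.6) multiplies the drag
closure in trajectory runs only; it absorbs what the bare unbounded-flow
correlation overestimates near the wall. It was fixed, once, at the value
for which the simulated phenomenology reproduces the experimentally
observed ladder at the reference flow (0.32 m/s inflow): captured at
40 kA/m, touch-and-detach at 32 kA/m, and an untouched passage with a clear
velocity dip over the core at 24 kA/m. The same constant yields a monotone
outcome ladder over the whole field range. The settling and Stokes-limit
checks use the uncalibrated closure (calibration 1), since they probe the
bare correlation far from walls.

Capture is detected when the bead's net drift speed over a trailing 0.05 s
window falls below $10^{-3}$ m/s with the center over the core footprint —
the drift criterion deliberately ignores the residual ring-down vibration
of a bead pinned in a very stiff magnetic trap. "Detached" means wall
contact occurred over the footprint but the bead ended beyond its
downstream edge. Both thresholds (speed and footprint) are exposed in the
configuration.

Numerical choices: the default step $2\times10^{-5}$ s keeps the
displacement per step about 30 times below the bead radius at transit
speeds (a guard aborts if a step exceeds half the radius); halving the step
changes reference trajectories by well under 1%. Trajectories are sampled
every 20 steps plus at every contact-state transition, so even contacts
briefer than the sampling interval remain visible to the classifier, and
outcomes are invariant to finer sampling.

Two readings of the reference geometry deserve a note. The initial bead
height is quoted in the source description as "0.003 mm", which would put
the bead center inside the wall; it is read here as 3 mm, near the axis of
the 8 mm tube. And the quoted volumetric rate of 400 mL/s is inconsistent
with the 8 mm bore and the 0.32 m/s inflow velocity (which imply about
16 mL/s); the simulator trusts the velocity.

## Synthetic data

No raw experimental data accompany the study, so generators emulate every
input: truncated-Gaussian particle-size distributions (median 248 nm,
dispersion 57 nm — Gaussian, not the more usual lognormal, because that is
what fit the reference batch), bead-diameter populations (mean 2.37 mm,
per-bead standard deviation 0.12 mm, truncated at three standard
deviations; the quoted "standard error" is read as a per-bead spread, since
a standard error of the mean at $n = 100$ would imply an implausibly broad
1.2 mm spread), parametric hysteresis loops, and noisy video tracks
(resampling at 1000 fps plus Gaussian position noise). All generators are
pure functions of their parameters and seed.

These generators emulate the *statistical* structure of the experimental
inputs — distribution shapes, loop parameterization, frame-rate and noise
of the tracking — but not instrument systematics (optical distortion,
segmentation bias, field inhomogeneity). Passing recovery tests therefore
demonstrates that the estimators are consistent on data of the assumed
form, not that they would be unbiased on raw laboratory material. One
concrete illustration: the weight-average diameter of the *fitted* Gaussian
population is ≈284 nm, while the reference histogram itself gave 305 nm —
the real histogram's heavy right tail is not part of the emulation.

## Problem sizes and limitations

Reference trajectory runs integrate 0.08 m of tube at a $2\times10^{-5}$ s
step (about 15,000–60,000 steps); loop analyses use 2001-point field grids;
distribution checks use $10^4$–$10^5$ draws. These sizes make the full
chain reproducible on a laptop in minutes.

Known limitations: no resolved pressure or velocity fields around the bead
(the lift closure only mirrors the sign and ordering of the wall-gap
effect); no bead rotation as a degree of freedom; no turbulence, despite
the transitional tube Reynolds number; remanence is ignored during motion
(the bead is treated as linearly magnetizable); the capture phenomenology
is qualitative by construction — the video-derived trajectories of the
original experiment are not numerically reproducible, and agreement is at
the level of outcomes, deceleration patterns and force scales, which is
also all the original study claims for its own model.
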