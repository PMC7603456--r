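---
title: "Methods: fluid-solid-growth modelling of aneurysm enlargement and stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluid-solid-growth modelling of aneurysm enlargement and stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsgr)
```

`fsgr` simulates the slow, flow-driven evolution of an intracranial-aneurysm
wall on an idealized axisymmetric geometry. This vignette explains the model
and its assumptions, the tunable parameters, what the synthetic inputs do and
do not represent, and the numerical choices behind the solver. Everything is
desk-scale: a full three-year simulation runs in minutes on one CPU.

## Wall constitutive model

The wall is a two-layer (media, adventitia) fiber-reinforced hyperelastic
composite. The deformation gradient is split multiplicatively into volumetric
and isochoric parts, `F = J^(1/3) Fbar`, and the strain energy is

```
Psi = (m_e K_e + m_sm K_sm) (I1bar - 3)      isotropic matrix (per layer)
    + sum_i m_c Psi_c(lambda4bar_i)          two collagen fiber families
    + kappa/4 (I3 - 1 - 2 log sqrt(I3))      volumetric penalty
```

with normalized constituent masses `m_e, m_c, m_sm` (1 at the reference
composition), stiffness-like constants in MPa, and `lambda4bar_i` the
isochoric tissue stretch along fiber family *i*.

Collagen fibers are wavy at rest: a fiber only bears load once the tissue
stretch exceeds its *recruitment stretch*, and recruitment stretches follow a
triangular probability density with parameters `(min, mode, max)`. Each
recruited fiber is linear in its own stretch (1st Piola-Kirchhoff stress
proportional to `lambda_c - 1`, `lambda_c = lambda4 / lambda_r`, clamped
below at 1 because fibers cannot push). Integrating the single-fiber energy
over the triangular density has a closed form: the moments of the density
against `1/s` and `1/s^2` are elementary log/rational antiderivatives,
implemented in `collagen_strain_energy()` and `collagen_dpsi_dI4()` and
validated against adaptive quadrature at 1e-8 relative tolerance in the test
suite. The ensemble response has the characteristic toe region while fibers
recruit progressively, and becomes exactly affine in stretch once all fibers
are recruited. A degenerate distribution (`min == max`) is handled as a
separate single-recruitment branch.

The bulk modulus defaults to `kappa = 100 * K_c`. Because the fiber law has
constant stiffness once fully recruited, this penalty keeps volumetric
changes of equilibrium solutions well below the 2 percent guardrail enforced
by the tests, while avoiding the volumetric-swelling pathology that
exponential fiber laws can exhibit under an isochoric split.

## Flow metrics

The wall shear stress (WSS) vector is the tangential part of the fluid
traction, `tau = sigma n - ((sigma n).n) n`. Over one cardiac cycle, the
*wall shear stress aspect ratio* (WSSAR) measures bidirectionality: two
orthogonal in-plane principal directions are found by sweeping the tangent
angle (0.5 degrees by default) for the extremal time-integrated projection,
the ranges of the WSS projections onto the two directions are computed over
the samples, and WSSAR is the smaller range divided by the larger. It is 0
for uni-directional flow, 1 for fully bi-directional flow, and invariant to
rigid rotations and uniform scalings of the series. Two conventions for the
principal direction are provided (signed projection integral, the default,
and absolute projection integral); when the signed integral is numerically
indistinguishable from zero for every angle - a symmetric rotating series -
the direction of maximal projection range is used and the result is flagged
isotropic. Time integrals use the trapezoid rule on the sampled series, and
extrema are sample extrema; nothing is interpolated between samples, matching
the cadence of CFD output. WSSAR thresholds are treated as dimensionless
(WSSAR is a ratio by construction, even where threshold tables attach a
pressure unit to them).

Two degradation stimuli map flow metrics to `[0, 1]`:

* low WSS: 1 below `tau_L` (0.5 Pa), 0 above `tau_C` (1 Pa), quadratic
  in between;
* high WSSAR: 0 below `tau_C_AR` (0.7), 1 above `tau_H_AR` (0.8), quadratic
  in between.

## Growth and remodelling laws

Four laws evolve the wall, all integrated with explicit Euler at
`dt = 0.02` year (the reference step; refinement factors are exercised by
convergence tests):

1. *Mass degradation*: `dm/dt = -F_X D_max m` for elastin, collagen and
   smooth muscle alike, with `D_max = 1.5` per year and `F_X` the active
   stimulus (low-WSS or WSSAR, exclusive per run).
2. *Recruitment remodelling*: the recruitment triple evolves so that the
   collagen fiber-stretch distribution tracks the *attachment-stretch*
   distribution (the stretch at which new fibers are configured to the
   matrix). The pairing is crossed - fibers recruited first carry the largest
   stretch - and the law is evaluated at whichever of the diastolic or
   systolic configurations maximizes the fiber stretch, pointwise. The raw
   (unclamped) stretch ratio drives remodelling; this is essential for
   protective fabrics whose attachment targets lie below 1 (the healthy
   adventitia), which would otherwise never reach their target. Updates that
   would push a recruitment stretch below 1 are clamped with a warning, and
   such clamp-bound quantiles are treated as inert when convergence is
   measured (they have no achievable remodelling rate).
3. *Collagen growth*: `dm_c/dt = eps m_c (l4f - l4f_att)/l4f_att` at systole,
   with the fibroblast stretch identified with the maximal collagen fiber
   stretch. The tabulated rate is `eps = 0`, so mass changes only through
   degradation by default.
4. *Attachment adaptation* (stabilization): a discrete per-step map,
   `att <- att + alpha_att (lambda4c - att)` per quantile with
   `alpha_att = 0.5`, applied only during the stabilization window. Running
   it throughout would suppress the degradation-driven enlargement phase, so
   the phases are kept distinct (this was an open modelling choice; the
   distinct-phase reading matches the three-phase study design).

## Idealized geometry and membrane equilibrium

The geometry is a surface of revolution: a parent cylinder (radius 2 mm)
carrying a Gaussian bulge (height 2 mm, width chosen as
`w^2 = H (R0 + H)` so the apex is locally spherical). Points are labeled
parent / neck / dome by the local bulge fraction, and all material parameters
are blended linearly across the neck. Fibers lie at plus/minus 30 degrees
(media) and 60 degrees (adventitia) from the circumferential direction in the
parent artery and along the principal curvature directions on the dome (for
a surface of revolution: circumferential and meridional); angles interpolate
across the neck, and umbilic points fall back to the same
circumferential/meridional pair with a flag.

Quasi-static equilibrium is the stationary point of the total potential
energy over the nodal positions of the deformed meridian:
through-thickness-integrated strain energy of both layers minus the
pressure-volume work of the follower load, plus a discrete meridional
bending energy `1/2 D (delta kappa)^2` with `D = E_eff h^3 / 12` per layer.
The bending term deserves comment: the wall is thick relative to its radius
(h/R of order 0.1), and a pure membrane is ill-posed wherever the in-plane
stiffness degrades - the physical wall carries such zones on its bending
boundary layer. Without this term, locally degraded zones fold at finite
mass. The stationarity conditions reproduce the membrane Laplace balances
(`sigma_theta h = P r` for the cylinder, `sigma h = P r / 2` for a spherical
cap), which the tests verify against the generic tensor stress path.

Through-thickness response comes in two variants: `"thick"` solves a
plane-stress condition (`sigma_rr = 0`) per layer under the compressible
volumetric law, so the Jacobian deviates slightly from 1 (the deviation is
the incompressibility diagnostic reported by the acceptance script);
`"membrane"` enforces `J = 1` exactly. The envelope theorem at the
plane-stress solution gives the nodal forces directly from the Cauchy
stresses, so the gradient of the energy is analytic. The solver is a damped
Newton iteration with a colored finite-difference Hessian (the gradient
couples each node only to its two neighbors on each side), line search on
the energy, pressure continuation from the reference configuration on cold
starts, and warm starts along the growth-and-remodelling trajectory.
Convergence is declared when the largest out-of-balance nodal force falls
below 1e-8 of the applied load per node. The cut ends of the parent artery
are held at the radius of the free axially-tethered cylinder under the same
pressure (a far-field condition; holding them at the reference radius
instead creates an artificial boundary layer in which fibers can never reach
their attachment stretch).

## Hemodynamic surrogate

The growth laws consume only WSS fields, so the Navier-Stokes solver is
replaced by a reduced-order surrogate (file-based WSS ingestion via CSV is
the alternative source). The parent-vessel WSS follows Poiseuille scaling
`4 mu Q / (pi r^3)` at the current parent radius; inside the sac it is
attenuated exponentially with the local sac depth (computed from the
*current* equilibrium radii), which encodes the central feedback loop:
enlargement deepens the sac, lowers its WSS and spreads the low-WSS region.
An oscillatory circumferential component whose relative amplitude grows with
depth emulates the secondary recirculation of a deep sac and exercises the
WSSAR pathway; its analytic WSSAR equals the imposed cross-amplitude ratio,
which the tests verify through the metric itself.

The attenuation rate (0.19 per unit reference sac height) is calibrated so
that the detected, homeostatic sac sits at the margin of the degradation
window (apex WSS about 0.95 Pa, just inside `tau_C = 1` Pa). This is both
the clinically interesting regime - a detected aneurysm that has just become
unstable - and a structural necessity of the axisymmetric idealization: any
zone of maximal degradation is here a full ring, and a ring cannot shed its
hoop load sideways the way a localized three-dimensional patch in a
patient-specific simulation can. With deep initial attenuation the sac loses
static equilibrium (a genuine membrane fold) before the stabilization phase
begins; the marginal calibration lets degradation grow through the feedback
loop instead, which reproduces the qualitative trajectory of interest:
monotone enlargement during the degradation window, then restabilization.

What the synthetic inputs do **not** represent: azimuthal localization of
the stimulus (everything is a ring), impingement-driven high-WSS patterns,
the spatial complexity of patient-specific CFD, and any biological noise.
Passing tests therefore demonstrate the correctness and stability of the
constitutive, metric and evolution machinery under controlled conditions -
not predictive accuracy for real aneurysms.

## Simulation schedule

Three phases, with the default clock of 0.02 year per step:

1. *Homeostasis search*: fixed-point iteration alternating equilibrium at
   the diastolic and systolic pressures with one remodelling step, until
   every remodelling-capable fiber-stretch statistic is within 1e-3
   (relative) of its attachment target. On the default 200-point sac this
   converges in well under 50 iterations, and the converged dome-adventitia
   fiber-stretch triple equals the prescribed attachment triple
   (1.0 / 1.05 / 1.1).
2. *Degradation*: 100 steps (2 years) of flow-linked mass decay, with the
   surrogate WSS field refreshed from the current geometry every 20 steps.
3. *Stabilization*: 50 steps (1 year) in which degradation is frozen and the
   attachment distribution adapts towards the current fiber stretches,
   driving all remodelling rates towards zero and leaving a spatially
   heterogeneous attachment field.

The 100 + 50 split follows the headline "two years of degradation, one year
of stabilization" description; the alternative reading (degradation onset at
step 50) is available through the schedule configuration. The diastolic and
systolic structural pressures default to 9671.38 and 9833.19 Pa, the
constant outlet pressures of the corresponding steady analyses; the
transient waveform (0.8 s period, 200 samples per cycle, i.e. 600 samples
over the standard three-cycle window) peaks at the configured systolic
timing and reproduces the configured means exactly.

## Parameters with units and defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `K_e`, `K_sm`, `K_c` | matrix / smooth-muscle / fiber stiffness | 0.1, 0.1, 1.0 | MPa |
| `kappa` | bulk modulus | `100 K_c` | MPa |
| `att` (per region, layer) | attachment-stretch triple | tabulated | - |
| `rec` (initial) | recruitment-stretch triple | tabulated | - |
| `alpha0` | recruitment remodelling rate | 10 | 1/yr |
| `eps` | collagen growth rate | 0 | 1/yr |
| `alpha_att` | attachment adaptation per step | 0.5 | - |
| `D_max` | maximal degradation rate | 1.5 | 1/yr |
| `tau_L`, `tau_C` | low-WSS thresholds | 0.5, 1.0 | Pa |
| `tau_C_AR`, `tau_H_AR` | WSSAR thresholds | 0.7, 0.8 | - |
| `dt` | G&R time step | 0.02 | yr |
| `thickness` | uniform wall thickness | 0.35 | mm |
| `media_fraction` | media share of thickness | 2/3 | - |
| `parent_radius`, `sac_height` | geometry scale | 2, 2 | mm |
| `decay_rate` | surrogate WSS depth attenuation | 0.19 | per sac height |
| `mu`, `rho` | blood viscosity, density | 3.5e-3, 1066 | Pa s, kg/m3 |
| `q_mean` | mean inlet flow | 2.54e-6 | m3/s |

`K_sm` is not part of the published parameter set and defaults to `K_e`.
Initial normalized masses are 1 in the parent artery; the dome media is
atrophied (`m_e = m_sm = 0.1`, `m_c = 0.5`), the adventitia carries
`m_e = m_c = 1, m_sm = 0`. One tabulation inconsistency is resolved in favor
of the parameter table: the dome adventitia attachment triple is
1.0 / 1.05 / 1.1 (the accompanying text says 1.01 for the minimum). The
"mean" label on tabulated stretch triples is read as the mode of the
triangular distribution.

## Numerical choices and degenerate inputs

* Explicit Euler everywhere, `D_max dt < 1` enforced so masses stay
  positive; Euler trajectories converge to the closed-form exponentials at
  first order (tested).
* Recruitment triples are re-sorted after every update; values are clamped
  at 1 with a warning.
* A zero-flow WSS series has WSSAR 0 with an explicit degenerate flag
  (no degradation without flow is the conservative choice).
* A zero neck band produces a hard parameter jump with a warning; a zero
  sac height produces a plain cylinder labeled parent everywhere.
* Equilibrium failure inside an evolution run aborts with the trajectory
  saved up to the failing step (`aborted_at`).
* Checkpoints are plain CSV at full double precision; restarting from a
  checkpoint reproduces the remaining trajectory exactly.

## Problem sizes

The default meridian has 200 points; the test suite uses 41-121 points for
solver checks and a 101-point meridian for the full 150-step run, sizes at
which the whole suite completes in a few minutes. The acceptance script runs
the full default study (200 points, homeostasis plus 150 steps) in about two
minutes.

## Known limitations

* Axisymmetry: degradation patterns are rings; secondary blebs are annular
  bulges, not lateral pouches.
* The membrane + discrete bending reduction has no through-thickness stress
  gradient and no true shell kinematics; the bending modulus is an
  order-of-magnitude composite estimate, not a fitted quantity.
* The hemodynamic surrogate is phenomenological; it preserves the sign and
  monotonicity of the geometry-WSS feedback, not actual flow physics.
* The reference configuration is treated as unloaded; recovering an unloaded
  configuration from a loaded, imaged geometry (pre-stressing) is out of
  scope.
* Exponential fiber laws, fiber-angle dispersion, active smooth muscle tone
  and viscoelasticity are out of scope.

## A worked micro-example

```{r}
library(fsgr)

# WSSAR of an elliptical shear rosette with semi-axis ranges 1 and 0.3 Pa
ros <- make_rosette(ratio = 0.3, mode = "rotating")
wssar(ros)

# collagen ensemble stress: toe region, then affine
dist <- recruitment_distribution(1.18, 1.24, 1.3)
lam <- c(1.1, 1.2, 1.25, 1.35, 1.6)
cbind(lambda4 = lam, dPsi_dI4 = collagen_dpsi_dI4(lam, dist, K_c = 1))
```

The full pipeline is

```{r, eval = FALSE}
cfg <- load_config()                # defaults; or load_config("run.yaml")
state <- init_state(cfg)
state <- run_homeostasis(state)
traj <- run_evolution(state, scenario = "low_wss")
summarize_trajectory(traj)
```
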