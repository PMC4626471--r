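---
title: "Simulating magnetic drug targeting in a pulsatile arterial segment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating magnetic drug targeting in a pulsatile arterial segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Magnetic drug targeting (MDT) injects drug-loaded magnetic nanoparticles
into the circulation and retains them at a diseased site with a strong local
magnetic field gradient, usually from an implanted permanent magnet. The
efficiency of this capture is limited by two competing constraints: carriers
must be small (tens of nanometres) to remain superparamagnetic and avoid
embolization and clearance, but the magnetophoretic force scales with the
*cube* of the core radius, so small carriers are barely deflected before the
blood stream carries them past the magnet.

`mdtsim` is a two-dimensional, desk-scale simulator of this trade-off in a
straight arterial segment. It couples four submodels:

1. **Magnetics** — the analytic exterior field of rectangular permanent
   magnets (single magnets or assemblies), calibrated so the field at the
   vessel matches prescribed values.
2. **Hemodynamics** — shear-thinning (generalized power-law) blood rheology
   and a synthesized pulsatile inlet waveform, giving quasi-steady velocity
   profiles across the channel.
3. **Particle model** — core/shell carriers with magnetophoretic, Stokes
   drag, and Brownian forces.
4. **Transport** — Brownian-dynamics trajectory integration with an
   elastic-wall/capture rule and the capture-efficiency statistic
   `eps = (eps_in - eps_out) / eps_in * 100`.

## Magnetics

A uniformly magnetized rectangle is replaced by its equivalent surface
current sheets; the two-dimensional Biot–Savart integral for a finite sheet
has a closed form in `atan`/`log` terms, and its Jacobian is rational, so
both `B` and `grad |H|^2` (the magnetophoretic drive) are analytic. The
solution is exactly divergence-free, curl-free outside the source, and
decays as a two-dimensional dipole (`|B| ~ r^-2`). Arbitrary magnetization
axes are handled by decomposing the magnetization onto the rectangle's
faces; multiple magnets superpose linearly. Blood's diamagnetism
(`chi_b = -6.6e-7`) enters only through the constitutive relation
`B = mu0 (1 + chi_b) H`; its feedback on the source field (relative order
`1e-6`) is neglected, and the linearized magnetization law `M = chi_b H`
stands in for the arctangent saturation law, which is indistinguishable at
these susceptibilities. The interior field of the magnet is never needed
and is not modelled; `field_at()` rejects interior points.

### Field calibration and the default source

The study pins the field at the treated vessel: about 0.5 T magnitude and
1.80 T/cm gradient at the vessel centre. We read "gradient" as
`|grad |B||`. Because magnetostatics is linear in the remanence, the
gradient-to-field *ratio* (360 1/m here) depends on geometry alone:
`calibrate_magnet()` first solves for the stand-off distance that attains
the ratio (a root search; the scan-then-refine bracket tolerates the
non-monotone ratio curves that assemblies produce), then scales the
remanence to hit the field magnitude, failing loudly if that would exceed
the 2 T ceiling of strong NdFeB sources.

A key quantitative finding of building this reconstruction: **no single
rectangular magnet kept outside a 4 mm vessel can produce both 0.5 T and
180 T/m at the vessel centre with a remanence of 2 T or less** (the best
over all widths, heights, offsets and stand-offs needs about 2.4 T). A
field that falls by a factor of ~2 across 2 mm has a decay length no
rectangle of practical size can produce at that distance while staying
strong. The published values come from a branched-artery geometry whose
target vessels are sub-1.5 mm; at those stand-offs the pair is easy. In the
straight 4 mm reduction we therefore use the standard high-gradient
configuration instead: an **alternating pole array** (`pole_array_spec()`,
default four 11 x 20 mm poles with 0.8 mm gaps, faces at the outer wall).
Above such an array the field decays on the scale of the pole pitch
(`|B| ~ exp(-2 pi y / P)` in the periodic limit), so the pitch sets the
gradient-to-field ratio while the array length sets the covered segment.
The default array calibrates to exactly 0.5 T / 180 T/m with a remanence of
about 1.49 T.

```{r}
library(mdtsim)
cfg <- simulation_config(n_particles = 10)
target <- c(mean(cfg$geometry$footprint), cfg$geometry$width / 2)
field_at(cfg$magnet, target)
```

## Hemodynamics

Blood is shear thinning. The generalized power-law model
`eta = lambda(gdot) |gdot|^(n(gdot) - 1)` with the Ballyk whole-blood
constants (`eta_inf = 0.0035`, `d_eta = 0.025` kg/(m s), `a = 50`,
`b = 3` 1/s, `n_inf = 1`, `d_n = 0.45`, `c = 50`, `d = 4` 1/s)
interpolates between a low-shear power-law regime
(`lambda -> 0.0285`, `n -> 0.55`) and the Newtonian plateau
(`eta -> 0.0035` kg/(m s)). Because `eta` diverges as `gdot -> 0`, shear
rates are floored at `gdot_min = 1e-3` 1/s.

The vessel is a plane channel of width 4 mm (the study's inlet diameter),
with blood density 1060 kg/m^3 and mean velocity 0.10 m/s; the resulting
Reynolds number is about 121, well inside the laminar regime. Instead of a
transient Navier–Stokes solve we use **quasi-steady developed profiles**:
at each instant the pressure gradient is found by bisection so that the
cross-sectional mean of the developed shear-thinning profile equals the
waveform value, with the pointwise shear rate obtained by inverting the
monotone stress relation (tabulated once on a log grid). The profile is
flatter than parabolic, satisfies no-slip and symmetry, and reverses sign
with the waveform. Upstream of the magnet footprint the inlet is plug flow,
as stated for the study inlet; `profile_mode` exposes plug/developed/mixed.
Quasi-steadiness is justified a posteriori: capture is controlled by the
near-wall velocity scale, and the Womersley corrections mainly affect
mid-channel phase lags.

### The inlet waveform generator

The study fitted a measured femoral waveform with a degree-9 polynomial but
did not print the coefficients, only landmarks: cycle period 1 s; maximum
reverse velocity at t = 0.12 s; systolic (S) peak at t = 0.35 s, "just
below half" the diastolic (D) peak at t = 0.85 s; mean velocity about
0.10 m/s. `make_waveform()` reconstructs a waveform from exactly these
constraints: ten linear conditions (periodic value and slope, three
stationary points, three landmark values, the cycle mean, and the value at
cycle start) determine the ten polynomial coefficients uniquely, so the
generator is deterministic. Landmark amplitudes are expressed as multiples
of the mean (`v0 = 1.4x`, reverse minimum `-0.7x`, S peak `1.6x`, D peak
`3.2x`), chosen once as a physiologically shaped triphasic femoral pattern
whose global extremes fall at the stated landmark times; a `pulsatility`
factor scales the deviation from the mean, with 0 giving steady flow.
What this emulates is the *phase structure* of arterial flow (fast
systolic transits, slow and reversed diastolic phases); what it does not
emulate is any patient-specific amplitude detail — conclusions that depend
on the exact waveform shape rather than on its landmarks are outside what
passing tests establish.

## Particle model

Carriers are spherical magnetic cores (Fe3O4: chi = 3.1, rho = 5230;
Fe2O3: 2.5, 4890; Fe: 3.9, 7760 kg/m^3) with optional non-magnetic
biocompatible shells (Au 19320, SiO2 2648, PEG 1114 kg/m^3; chi = 0).
The magnetophoretic force acts on the core only,

    F_M = 2 pi mu_b r_core^3 K grad |H|^2,

with the Clausius–Mossotti contrast `K = (mu_p - mu_b)/(mu_p + 2 mu_b)`
bounded in [-0.5, 1] (about 0.508 for magnetite in blood). Drag is Stokes
drag on the whole particle, `F_D = (m_p / tau_p)(u_b - u_p)` with
`tau_p = rho_eff D^2 / (18 eta)` and the volume-weighted effective density;
algebraically this is `3 pi eta D (u_b - u_p)`, which the tests assert as
an identity. The Brownian force is the matching Gaussian noise,
per-component amplitude `sqrt(12 pi r_h eta k_B T / dt)`, which combined
with the Stokes mobility reduces exactly to diffusive displacements
`sqrt(2 D_B dt)` with the Einstein diffusivity `D_B = k_B T/(6 pi eta r_h)`.
The radius in the noise amplitude is the hydrodynamic (total) radius — the
fluctuation must pair with the dissipation it balances. Temperature
defaults to 310 K; `k_B` is the exact SI value.

Two viscosities appear, deliberately distinct. The generalized power-law
apparent viscosity at the *bulk* shear rate shapes the velocity profile.
The drag and Brownian forces on a particle use the constant plateau value
`eta_drag = 0.0035` kg/(m s): a particle migrating through plasma at slip
velocity `v` shears the fluid at its own scale `v / D` (of order
1e3–1e5 1/s, deep in the Newtonian plateau), so applying the bulk low-shear
apparent viscosity (up to ~0.6 kg/(m s) at the centerline, where the bulk
shear vanishes) would freeze transverse migration unphysically.

## Transport, walls, and capture

The default integrator is **overdamped** Brownian dynamics:
`u_p = u_b + F_M / (3 pi eta D)` plus the diffusive kick. This is accurate
because the momentum relaxation time (`tau_p ~ 1e-9 s` for 100 nm carriers,
`~1e-6 s` at 2 um) is far below the 1e-4 s step. An **inertial** mode
integrates the linear drag ODE exactly over the step (exponential
integrator, unconditionally stable); with `tau_p / dt < 1e-3` the two agree
to better than a nanometre over thousands of steps, which the suite checks
both for the scalar reference stepper and the compiled loop.

Particles are injected at the inlet, 1000 per pulse at t = 0, 0.01, ...,
0.05 s (6000 total at study scale), uniformly over the inlet minus one
hydrodynamic radius per wall, at the plug inlet velocity. Each particle
owns an independent noise substream derived from the master seed and its
index (a hashed counter-based generator), so runs replay bit-identically
and changing the particle count does not reshuffle existing particles'
noise. During the reverse-flow phase freshly injected particles can be
advected below x = 0; the artery continues upstream, so they simply return
with the next forward phase (only drift beyond 5 cm upstream retires a
particle).

A particle whose surface touches a wall is **captured** if the contact lies
inside the magnet footprint, on the wall facing the magnet, and the
wall-normal component of `F_M` presses it into that wall; its position is
then frozen (captured carriers are assumed not to perturb field or flow —
one-way coupling in a dilute suspension). Any other wall contact is a
specular elastic reflection. Restricting capture to the magnet-side wall is
our resolution of an ambiguity: the study assumes elastic walls everywhere
yet reports accumulation "at the arterial wall near the field source", and
a rule that allowed far-wall capture would also capture magnetically
*repelled* particles, making the null experiment (no wall-directed force,
no capture) unsatisfiable. With the magnet off, `eps = 0` exactly.

Efficiency bookkeeping: `eps_in` counts particles entering the footprint
section; particles still inside at the end of the 5 s window are reported
separately and excluded from the efficiency denominator (they are neither
captured nor lost). The study's exclusion of particles leaving through the
first branch has no analog in a straight channel; section-entry counting is
the chosen correspondence. A particle-Reynolds-number guard monitors the
Stokes assumption `Re_p << 1` each step and reports the violation count —
micron-scale carriers close to the pole faces do exceed it transiently,
which is a documented limit of the Stokes drag law, not of the integrator.

## Study conditions and desk scale

The default `simulation_config()` *is* the study condition set: bare
Fe3O4 core, 4 mm channel, 0.10 m/s pulsatile mean, 6000 particles, six
injection pulses, 5 s observation, 310 K, calibrated source. The footprint
[0.4, 5.2] cm and the 4.6 cm pole array are this package's reconstruction
of the unprinted implant geometry: the implant should cover the treated
segment, and the pitch is fixed by the calibrated gradient ratio. Desk
runs pass smaller counts; the bundled analyses use N = 1000 (50 nm bound),
N = 500 (2 um bound), N = 300–400 per sweep cell, with binomial Monte Carlo
standard errors carried through every table. At these sizes a capture run
takes seconds to tens of seconds on one core; time step 1e-4 s resolves
the cardiac cycle and the Brownian scaling (the noise amplitude is
step-size aware, so halving `dt` changes only resolution, not statistics).

With these conditions the simulator reproduces the study's qualitative
structure: superparamagnetic-scale carriers (50 nm core) are captured at a
few percent — the near-wall boundary layer where residence time beats the
weak magnetophoretic drift is ~100 um thick — while 2 um carriers cross
the full channel within their residence time and are captured nearly
completely; non-magnetic coatings up to 50 nm shift drag by at most a few
percent and leave efficiency statistically unchanged (the sweep reuses
common random numbers, so a zero-thickness shell reproduces the bare run
exactly).

## Numerical choices

- Waveform fit: 10 x 10 monomial solve on scaled time (condition ~1e7,
  fine in double precision); periodicity asserted to 1e-6 m/s on
  construction.
- Profile solve: stress inversion tabulated on 900 log-spaced points and
  interpolated log-log; outer bisection on the pressure gradient (60
  iterations); profiles tabulated on a 161 x 121 (y, mean-velocity) grid
  and bilinearly interpolated in the loop.
- Field: exact closed form everywhere outside sources, including the
  Jacobian, so no differencing error enters the force.
- Degenerate inputs: zero pulsatility gives steady flow; zero remanence
  gives the magnet-off null; zero shell thickness is bitwise the bare core;
  `eps_in = 0` raises an undefined-efficiency error rather than NaN.
- Tie-breaks: wall contact exactly at the footprint edge counts as inside;
  reflection handles multiple bounces within one step via a bounded loop.

## Known limitations

- Straight-channel reduction: no branching, no flow division, no
  multi-pass recirculation; reported efficiencies are first-pass values
  over 5 s.
- Quasi-steady profiles omit Womersley phase effects.
- The wall is rigid and chemically inert: no glycocalyx resistance,
  adhesion kinetics, or re-entrainment of captured particles.
- One-way coupling only; dilute-suspension assumption.
- `Re_p < 1` is violated transiently for micron carriers at the pole
  faces, where Stokes drag underestimates the true drag; capture there is
  already overwhelming, so the bounds are insensitive to it.
- 2D: out-of-plane gradients and migration are absent; the study makes the
  same reduction.
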