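# mdtsim — magnetic drug targeting simulation in pulsatile arterial flow

`mdtsim` is a two-dimensional, desk-scale simulator of magnetic drug
targeting (MDT): drug-loaded magnetic nanoparticles are carried by pulsatile
blood flow through an arterial segment while an implanted permanent-magnet
assembly pulls them toward the vessel wall. The package answers the central
design question of MDT — *what fraction of injected carriers is captured at
the target, as a function of carrier size and coating?* — with a stochastic
Lagrangian model whose every physical ingredient is testable in isolation.

It is aimed at researchers in nanomedicine and biomedical transport who
want a fast, fully scriptable alternative to a finite-element multiphysics
model for exploring carrier design (core material and radius, biocompatible
shell, field strength) before committing to expensive simulations or
experiments.

## The model

Four coupled submodels, one R function each:

- **Magnetics** (`magnet_spec`, `pole_array_spec`, `field_at`,
  `calibrate_magnet`): the exterior field of uniformly magnetized
  rectangles in closed form (equivalent current sheets), exactly
  divergence- and curl-free, with an analytic `grad |H|^2`. The default
  source is an alternating pole array calibrated so the vessel center sees
  `|B| = 0.5` T and `|grad |B|| = 180` T/m.
- **Hemodynamics** (`viscosity_params`, `make_waveform`,
  `velocity_profile`, `reynolds`): generalized power-law (shear-thinning)
  blood rheology, `eta = lambda(gdot) |gdot|^(n(gdot)-1)`, and a degree-9
  polynomial pulsatile inlet waveform reconstructed from its physiological
  landmarks (reverse minimum at 0.12 s, S peak at 0.35 s at half the D peak
  at 0.85 s, mean 0.10 m/s); quasi-steady developed profiles across the
  4 mm channel (Re ≈ 121).
- **Particle model** (`particle_spec`, `clausius_mossotti`,
  `magnetophoretic_force`, `drag_force`, `brownian_force`): core/shell
  carriers; magnetophoresis acts on the core only,
  `F_M = 2 pi mu_b r_core^3 K grad|H|^2` with the Clausius–Mossotti factor
  `K in [-0.5, 1]`; Stokes drag `3 pi eta D (u_b - u_p)` and its matched
  Brownian noise act on the whole particle.
- **Transport** (`simulation_config`, `run_simulation`, `sweep_core_size`,
  `sweep_coating`): overdamped (or exact-exponential inertial) integration
  of 6000 carriers over a 5 s window, elastic walls with capture on the
  magnet-side wall under a wall-directed force, and the capture efficiency
  `eps = (eps_in - eps_out) / eps_in * 100` with binomial error bars.

## Worked example

Capture of bare 50 nm magnetite cores under the study conditions
(desk-scale N = 1000):

```r
library(mdtsim)

cfg <- simulation_config(
  particle    = particle_spec("Fe3O4", core_radius = 50e-9),
  n_particles = 1000, seed = 1)
run_simulation(cfg)
#> capture result (seed 1): eps_in = 1000, eps_out = 942, captured = 38, in transit = 20
#>   efficiency = 3.88 % (MC se 0.62 %), max Re_p = 2.74e-05 (0 violations)
```

All 1000 carriers entered the magnet section; 38 were pinned to the wall
under the array, 942 escaped downstream, and 20 were still in transit when
the 5 s observation window closed (they are excluded from the efficiency
denominator). The efficiency of 3.9 % — against 100 % for 2 µm carriers
from the same configuration — is the superparamagnetic-size penalty: the
magnetophoretic force scales as `r_core^3`, so 50 nm cores are captured
only from a ~100 µm near-wall boundary layer. The maximum particle
Reynolds number confirms the Stokes-drag regime.

Supporting quantities the package prints along the way:

```r
clausius_mossotti(3.1)               # magnetite in blood
#> [1] 0.5082
reynolds(1060, 0.10, 0.004, 0.0035)  # channel Reynolds number
#> [1] 121.1429
cfg$magnet[[1]]
#> rectangular magnet: B_rem = 1.486 T, 1.1 x 2 cm at (1.03, -1.04) cm, axis (0, 1)
```

Size and coating dependence (writes CSV tables and PNG figures):

```r
reproduce_figures("figs", scale = "desk")
```

A thin command-line front end is provided in `inst/cli/mdtsim.R`
(`simulate`, `sweep-size`, `sweep-coating`, `calibrate-magnet`,
`make-waveform`), driven by YAML configs via `load_config()`.

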