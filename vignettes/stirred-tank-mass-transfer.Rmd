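---
title: "Modelling gas-liquid mass transfer and fermentation kinetics in a stirred tank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gas-liquid mass transfer and fermentation kinetics in a stirred tank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stirredtank)
```

## Scope and model structure

`stirredtank` simulates the coupled physics of a sparged, agitated gas-liquid
bioreactor at desk scale: discrete bubbles rise through a prescribed flow
field, exchange dissolved gases with the liquid, and the dissolved-gas
balances feed reaction kinetics — either constant-rate consumption/production
pairs or a Contois-type fermentation. What the package deliberately does
*not* contain is a Navier-Stokes solver: the turbulent flow and
energy-dissipation fields that a large-eddy CFD code would provide are
replaced by analytic, queryable stand-ins (`make_stirred_tank_field()`),
calibrated by two scalars a process engineer can defend — the impeller tip
speed and the volume-average specific energy dissipation rate. Everything
downstream of the flow field (bubble dynamics, interphase transfer, species
balances, kinetics, flux accounting) is modelled explicitly.

The well-mixed reactor model (`run_scenario()` and its wrappers) advances
four sub-models on one shared timestep:

1. **Injection.** Gas enters through a ring sparger at a set flow
   (standard L/min) as spherical bubbles of fixed initial diameter (2 mm by
   default). The number of parcels per step uses a deterministic fractional
   carry, so the injected gas volume is exact to within one bubble volume
   over any window.
2. **Bubble motion.** Each parcel obeys Newton's second law with
   Schiller-Naumann drag on the slip velocity, a buoyancy/gravity term
   `(rho_b - rho_f) V g`, and pressure-gradient and added-mass forces
   (`Ca = 0.5`) driven by the local fluid material acceleration. Integration
   is velocity Verlet; when the drag relaxation time of small parcels falls
   below the global step the integrator sub-steps internally.
3. **Interphase transfer.** The liquid-side film coefficient around each
   bubble comes from penetration theory,
   `kL = 0.301 (eps nu)^(1/4) Sc^(-1/2)`, with the dissipation rate and
   viscosity sampled at the bubble centre. The molar flow per bubble and
   species is `kL A (S c_g - c_f)` with `A = pi d^2`; positive flux
   dissolves gas, negative flux strips it (this is how CO2 produced in the
   liquid leaves through initially pure-oxygen bubbles). Transferred moles
   are moved conservatively — the bubble and the liquid change by exactly
   opposite amounts — and the bubble diameter is recomputed from its molar
   content and the 22.4 L/mol gas molar volume after every exchange.
4. **Reaction.** Constant-rate pairs are applied directly to the dissolved
   concentrations (clipped at zero with the clipped amount logged as a
   deficit). The Contois fermentation advances by a classical RK4 step of
   the biomass/product/substrate/oxygen system each global timestep.

A four-stream molar ledger (sparge injection, free-surface removal,
gas-liquid transfer, reaction) is accumulated per species at every step;
`ledger_balance_error()` checks the closure
`injection - removal - transfer = moles in flight`, which holds to rounding
because every stream is accounted for with the same arithmetic that moves
the moles.

## The well-stirred transfer model and its closed forms

When the liquid is well mixed and the bubble gas concentration is treated as
constant, the dissolved balance collapses to
`dc/dt = kla (S c_b - c)`, defining the volumetric mass transfer coefficient
`kla` (1/s); `1/kla` is the transfer equilibration timescale.
`fit_global_kla()` recovers `kla` from a gassing-in curve by nonlinear least
squares on `c(t) = sat - (sat - c0) exp(-kla t)` — nonlinear rather than
log-linearised, because log-linearisation amplifies noise near saturation.

With a constant volumetric reaction `R` superimposed, the steady states have
closed forms implemented in `steady_state_dissolved()`: a consumed species
settles at `S c_b - R/kla`, and a produced, stripped species at `R/kla`.
The dimensionless ratio `xi = R / (S c_b kla)` (`xi_ratio()`) measures
consumption against transfer capacity; the consumed-species steady state is
`S c_b (1 - xi)`. One subtlety the closed forms hide: bubbles that accumulate
a produced species are no longer pure sparge gas, so the equilibrium shifts
by `S` times the realised in-bubble concentration. For CO2 (`S = 0.83`) even
a fraction of a percent of in-bubble CO2 moves the steady state appreciably.
The scenario wrappers therefore evaluate the predictors at the run's own
transfer-weighted mean bubble gas concentration; with that substitution the
well-mixed simulation and the predictors agree to well under 1% (this is
asserted in the acceptance tests).

## Fermentation kinetics

The fermentation model is the four-component gluconic acid system
(*Aspergillus niger* on glucose): `R_X = mu X`, `R_P = (alpha mu + beta) X`,
`R_S = -(gamma mu + lambda) X`, `R_O2 = -(delta mu + phi) X`, with a Contois
growth law in which both half-saturation terms scale with biomass:

`mu = mu_max [S / (Ks' X + S)] [O2 / (Ko' X + O2)]`

Kinetics are computed in g/L and hours and share dissolved oxygen with the
transfer model through an explicit mol/g conversion (32 g/mol). The
coefficients are experimentally fitted quantities and **must be supplied for
any quantitative study**; `illustrative_contois_params()` provides a
clearly-labelled plausible set (growth timescale of hours, oxygen demand
below the transfer capacity of a lab vessel) so examples and tests have a
definite configuration. With a prescribed `kla`, the transfer term
`kla (sat - O2)` is evaluated *inside* each RK4 stage, so the simulator
integrates exactly the ODE system a reference solver sees; the test suite
checks agreement with an independent adaptive integrator (`deSolve::ode`,
lsoda at 1e-10 relative tolerance) to 1e-4 relative over 400 s and 1e-3 over
5 simulated hours.

Two practical observables come out of the fermentation runs. The product
growth rate `dP/dt` is reported as the slope of a linear fit over the first
2 h (configurable), because the product trajectory is nearly linear at these
conditions. The dissolved-oxygen history splits into a fast settle at the
transfer timescale `1/kla` followed by a slow decline at the growth
timescale `1/mu`; `dissolved_o2_timescales()` fits both and reports their
ratio (above 100 whenever `1/kla << 1/mu_max`, as in the default setup).

Broth viscosity can be coupled to biomass as
`nu = nu_ref (1 + C_X)^2.26` (`biomass_viscosity()`). The functional form of
this correlation is stated ambiguously in parts of the literature; the
implemented reading is the one that is dimensionally consistent and reduces
to water at zero biomass, and both the exponent and the form are overridable.

## The synthetic flow field: what it does and does not emulate

`make_stirred_tank_field()` builds an axisymmetric, divergence-free velocity
field: a smooth swirl profile peaking at the impeller tip radius (scaled so
the speed there equals the tip speed `pi D N`, 0.958 m/s for the default
0.061 m impeller at 300 RPM) plus a poloidal recirculation derived from a
Stokes streamfunction, giving a radial jet at the impeller plane and
recirculation loops above and below, with no flow through any boundary and
zero velocity at the side wall. The dissipation field is a Gaussian bump at
the impeller tip over a uniform background, normalised by quadrature so its
volume average equals a user-supplied mean — typically from the impeller
power draw, `eps = Np N^3 D^5 / V` (`mean_epsilon_from_power()`, `Np = 5`
for a Rushton turbine).

What this reproduces: the right velocity scale, a dissipation field peaked
at the impeller (hence `kL` and local `kla` maximal there), bubble residence
times of the right order, and a quasi-steady bubble population (a few
percent gas hold-up and a volumetric transfer coefficient near 0.014 1/s at
the default operating point). What it cannot reproduce:
turbulent fluctuations, trailing-vortex structure, baffle effects, and any
feedback of the gas on the liquid flow (the Newton's-third-law coupling is
exposed as a reporting hook, `fluid_reaction_force()`, with no fluid solver
to receive it). Consequently the *absolute* `kla` of a bubble-resolved run
is only order-of-magnitude faithful; results that depend on the flow detail
(mean bubble size distributions, bubble counts under breakup) are accepted
as inputs, not predicted. Tests passing on this synthetic flow validate the
transfer/kinetics/accounting machinery, not a CFD solution.

The default poloidal amplitude is 15% of the tip speed. This keeps the
downwelling speed in the outer recirculation below the ~0.21 m/s terminal
rise velocity of a 2 mm bubble — in a small vessel at these speeds bubbles
escape rather than recirculate indefinitely, consistent with hold-up of a
few percent; stronger recirculation traps parcels and makes the hold-up run
away unphysically.

## Numerical choices

* **Shared explicit timestep.** All physics advance on one `dt` (default
  5 ms). Transfer uses start-of-step concentrations (explicit coupling); the
  engine warns if `kla dt` exceeds 0.05, i.e. if a step moves concentrations
  by more than 5% of the driving difference. `timestep_from_courant()`
  implements the Courant rule `dt = Co dx / V_ref` (with `Co < 1` required,
  0.1 the conventional choice) for grid-based runs.
* **Parcels.** One simulated parcel represents `parcel_weight` physical
  bubbles (default 400). All molar accounting multiplies by the weight, so
  ledgers and transfer are unbiased; only the stochastic granularity
  changes. At 8 SLPM of 2 mm bubbles (31,831 bubbles/s physically) the
  default weight keeps the standing population near 10^2 parcels.
* **Injection randomness.** Ring positions are uniform in angle from R's
  seeded generator; parcel counts use a deterministic fractional carry.
  A run is reproducible byte-for-byte from its configuration and seed.
* **Bubble integrator.** Velocity Verlet, order 2; sub-steps when
  `dt` exceeds the drag relaxation time `m_eff / b` (secant-linearised
  drag). The fluid material acceleration is frozen over one global step —
  it varies on the flow timescale, far slower than drag relaxation.
  Parcels overshooting the wall or floor are slid back; the free surface is
  handled by removal, with the surface raised by the instantaneous hold-up
  volume (flat-plane bookkeeping, not a deformable interface).
* **Spatial grid.** `adr_step()` is first-order upwind advection plus
  central diffusion in conservative flux form on a Cartesian lattice
  (default 32^3 over the tank bounding box) with a staircase cylinder mask
  and no-flux walls; total moles are conserved to rounding in closed
  domains. An explicit stability check (advective + diffusive numbers
  summing below 1) rejects unstable steps naming the binding constraint.
  Negative concentrations produced by sinks are clipped with the clipped
  moles logged (`grid$deficit`). First-order upwind is diffusive; the grid
  exists to resolve concentration *patterns* (where transfer happens, how
  gradients correlate with local `kla`), not sharp fronts.
* **Degenerate inputs.** Contois factors resolve 0/0 to zero (exhausted
  substrate with no biomass); transfer clipping floors bubble content and
  dissolved stock at zero with the deficit logged rather than silently
  creating mass; the kLa fit refuses constant series and series already at
  saturation.

## Problem sizes used by the tests

The test suite runs the bubble-resolved scenarios for 600 simulated seconds
(120,000 steps at 5 ms) with parcel weight 400 — more than eight transfer
time constants (1/kla ~ 74 s at the default operating point), so plateau
means are converged to well under a percent. The fermentation
comparisons integrate 400 s at 0.1 s steps and 5 h at 0.5 s steps. The
grid/CSTR consistency experiment uses the 32^3 lattice with a turbulent
effective diffusivity of 2e-3 m^2/s and a transfer source localised at the
impeller totalling `kla` = 0.002 1/s, which puts the blend-to-transfer
timescale ratio near 0.008 — comfortably in the fast-mixing regime where the
volume-mean trajectory must collapse onto the well-mixed model. The
conservation sweep draws 100 random operating points (2-16 SLPM, 1-3 mm
bubbles, both reaction modes) and requires every ledger identity to close to
1e-8 relative.

## Known limitations

* No resolved hydrodynamics: no turbulence, no impeller/baffle geometry in
  the flow, one-way coupled bubbles, flat free surface.
* Bubble break-up and coalescence are off by default; the provided
  critical-Weber split and overlap merge are deliberately minimal plug-ins
  for qualitative exploration, not population-balance models.
* No hydrostatic-pressure correction to the in-bubble gas concentration
  (fixed molar volume of 22.4 L/mol), no real-gas behaviour, no temperature
  dependence of solubility, no pH/dissociation chemistry of the product.
* The Contois CO2 pathway is not modelled (the fermentation system has no
  CO2 source term); CO2 appears only in the constant-rate reaction pair.
* The well-mixed engine treats the liquid as a single compartment; spatial
  structure is available only through the scalar grid with prescribed
  sources.

## A minimal session

```{r example, eval = FALSE}
o2 <- species_spec("O2", solubility = 0.032, molar_mass = 32)
cfg <- run_config(
  species = list(o2),
  sparge = list(gas = gas_mixture(c(O2 = 1)), flow_slpm = 8),
  numerics = simulation_config(duration = 600, dt = 0.005, rng_seed = 1,
                               output_interval = 2))
res <- simulate_saturation(cfg)
res$steady_state   # ~0.00143 mol/L, the saturation limit S * c_b
res$kla_fit        # gassing-in fit of kla (1/s)
res$kla_direct     # population sum(kL A)/V_l (1/s)
```
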