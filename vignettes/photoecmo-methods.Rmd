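---
title: "Modelling a phototherapy membrane oxygenator: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a phototherapy membrane oxygenator: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoecmo)
```

## The device and the physics being coupled

A photo-ECMO device treats carbon monoxide poisoning by shining visible
light into extracorporeal blood: red photons (620 nm) photodissociate CO
from carboxyhemoglobin while hollow-fiber mats re-oxygenate the blood. The
modelled unit is a thin blood chamber — 20 cm x 20 cm in plan, 1 cm thick —
encased in 1.1 cm clear plexiglass, fed through a bottom inlet tube near one
corner and drained through a top outlet tube near the opposite corner, and
irradiated by 20 LEDs above and 20 below. The design variable is the corner
fillet radius (0, 5 or 10 cm): rounding the corners removes the stagnant
pockets of the square chamber where thrombosis risk and local heating
concentrate, at the cost of treated (priming) volume.

Four coupled stages are simulated, each behind its own function surface:

1. **Light** (`run_photon_transport`, `revolve_kernel`,
   `assemble_led_array`): an MCML-style photon random walk into the blood
   slab produces a cylindrical deposition kernel, revolved and superposed
   over the LED array into a volumetric heat source `mu_a * phi` (W/m^3).
2. **Flow** (`solve_flow`): steady incompressible momentum balance with the
   Carreau shear-thinning viscosity,
   `mu(gdot) = mu_inf + (mu0 - mu_inf) [1 + (lambda gdot)^2]^((n-1)/2)`,
   with whole-blood constants `mu0 = 0.056` Pa s, `mu_inf = 0.0035` Pa s,
   `lambda = 3.313` s, `n = 0.3568`, density 1057 kg/m^3.
3. **Particles** (`trace_particles`): 100 Lagrangian particles released
   across the inlet at t = 0 with the local fluid velocity; cumulative
   outlet arrivals are recorded every minute for 15 minutes.
4. **Heat** (`solve_heat`): transient/steady convection-diffusion
   `rho cp dT/dt + rho cp u.grad T - div(k grad T) = mu_a phi` in blood
   (cp = 3600 J/(kg K), k = 0.55 W/(m K)), conduction only in plexiglass
   (1190 kg/m^3, 1470 J/(kg K), 0.18 W/(m K)), Robin exterior boundaries
   with natural-convection film coefficients, 20 degC ambient and inflow.

## Geometry and volume accounting

The filleted footprint has closed-form area `L W - (4 - pi) r^2`. Priming
volume subtracts the solid volume of the gas-exchange mats: 20 stacked
layers of 380 um OD polypropylene fibers (280 um lumen + 2 x 50 um wall) at
20 fibers per cm, each layer's fiber length taken as linear density times
footprint area (exact chord summation is available and agrees to < 0.1%):

```{r volumes}
fib <- fiber_mat_spec()
sapply(1:3, function(g) priming_volume(device_preset(g), fib))
```

Ports sit `port_inset + r * port_scaling_factor` from the two adjacent
edges. The scaling factor is not derivable from the device drawings, so it
is a configuration knob; the default 0.3 is the smallest round value for
which the port disc clears the 10 cm corner arc with margin while staying
near the rim, matching the intended corner placement. Values near 1 would
push both ports of the circular (r = 10) variant into the centre of the
footprint, which contradicts the device's port layout and collapses the
transit path, so they are rejected by the validator when the disc leaves
the footprint.

The tube bore defaults to 1.27 cm. With a 0.635 cm bore the mean tube
velocity at 1 L/min would be ~530 mm/s; the device's reported operating
velocities (~132 mm/s at 1 L/min) are consistent only with the 1.27 cm
bore, so that is the default and the smaller reading remains available in
the spec constructor.

## Light transport

Photons launch normally onto the blood surface with radii sampled from a
Gaussian (default) or flat beam of radius 0.33 cm. Steps are exponential
with rate `mu_a + mu_s`; at each interaction a fraction `mu_a/(mu_a+mu_s)`
of the weight is scored into a 1.0 x 1.5 cm (r, z) grid; directions deflect
by Henyey-Greenstein sampling; Russian roulette (threshold 1e-4, survival
0.1) terminates low-weight photons with an explicitly tracked imbalance so
that absorbed + transmitted + reflected + in-flight + roulette-net = 1 to
machine precision on every run. Boundaries are index-matched (no Fresnel).

The per-LED optical power is 0.036 W (the stated per-LED input energy of
0.036 J interpreted as continuous power during irradiation — the steady
heating model needs a power; 0.035 is selectable). The plexiglass is
optically passive: a scalar 92% transmission factor scales every source.

The reference optical configuration is **absorption-only** (`mu_s = 0`,
`mu_a = 1.56` 1/cm, the fully CO-poisoned pool at 620 nm): its deposition
has the Beer-Lambert closed form with 1/e depth 0.64 cm, consistent with
the ~0.5 cm working penetration the chamber thickness was designed around,
and it makes the acceptance checks exactly verifiable. Literature-style
whole-blood scattering (`blood_optics_620()`: mu_s = 650 1/cm, g = 0.982,
and its similarity-reduced equivalent) is provided for sensitivity studies
but is deliberately not the silent default: those constants are not part of
the device's stated parameter set, and presenting them as ground truth
would overstate what is known.

The LED layout is under-determined: 20 sources per face "5 cm apart" on a
20 cm face force a 4 x 5 grid whose 5-position axis spans the face
edge-to-edge (rows at y = 0, 5, 10, 15, 20 cm). The layout is therefore an
explicit data frame the user can replace. Sources whose centre leaves the
filleted footprint are excluded with a warning, and lateral clipping is
tracked in a per-LED power ledger; consequently the filleted geometries
carry fewer effective sources (40/32/24 for fillet radii 0/5/10), which is
physically sensible — fewer LEDs fit over a smaller window — but is a
modelling choice, not a measured property of the device.

## Flow solver

The chamber is 20x wider than thick, so the discretization exploits the
thin-gap structure: in-plane velocities are staggered (MAC) and resolved on
every z-layer, the pressure is a single unknown per grid column (the
lubrication limit), and the through-thickness velocity is reconstructed
cell-by-cell from continuity, making the discrete divergence zero by
construction. Each Picard iteration (lagged Carreau viscosity, upwinded
lagged inertia, relaxation 0.7) solves the saddle-point system by a
pressure Schur complement: the two momentum blocks are sparse-LU
factorized and the reduced pressure system is solved by BiCGSTAB
preconditioned with the lubrication operator `div (h^3/(12 mu)) grad`.
Tubes are represented as flux patches on the bottom/top faces; their own
fully developed pressure drop (Carreau viscosity at the nominal wall shear
`8V/d`) is added analytically.

Verification: the Newtonian plane-channel fixture reproduces the parabolic
profile (max/mean = 1.5 within 0.5% at 20 cells across the gap) and the
`12 mu Q/(w h^3)` pressure gradient; the solved field is invariant under
the point reflection that swaps the ports (Stokes symmetry); pressure drop
rises strictly with flow rate.

What this discretization cannot represent: the three-dimensional impinging
jet at the ports. At 0.25 L/min (tube velocity 33 mm/s) entrance losses are
negligible and the solved pressure drop is quantitative; at 3 L/min
(400 mm/s, tube Reynolds ~1300) the unresolved impingement and turning
losses dominate the real pressure drop, so at high rates only orderings and
trends are claimed, not pascal values.

**Stagnation fraction.** The clinically meaningful quantity is the share of
blood volume moving slower than 1 mm/s. With six uniform layers across the
gap, the cells adjacent to the top/bottom walls lie deep in the parabolic
boundary layer everywhere in the chamber, so a naive cell-wise count is
dominated by this discretization artifact rather than by the lateral dead
zones the threshold is meant to flag. The reported `stagnation_fraction`
therefore classifies a *column* as stagnant when its depth-averaged speed
is below threshold (the cell-wise count is reported alongside). On a
boundary-layer-resolving grid the two definitions converge.

## Particle residence

Particles are neutrally buoyant 8 um tracers by default: their Stokes drag
relaxation time (~1e-6 s) is many orders below the flow time scale, so
trajectories follow streamlines (adaptive RK2, CFL 0.3, dt <= 0.25 s).
The full mass + Stokes-drag equation is available (`drag = "stokes"`) with
an exact exponential velocity update per step, and matches the tracer in
the vanishing-mass limit. Release positions are uniform over the inlet
disc (seeded), or a deterministic sunflower grid. Walls reflect: a particle
stepping through the no-slip plane would otherwise land exactly on it,
where the interpolated velocity vanishes and the particle would be
spuriously captured forever on a coarse grid. Arrival is the first crossing
of the top face within 1.25 tube radii of the outlet centre; counts are
stored every minute.

## Thermal solver

Conservative finite volumes on the conforming grid that includes the
plexiglass shell: harmonic-mean conductivities across material interfaces,
first-order upwind advection using the flow solver's face velocities,
inflow enthalpy at 20 degC at the inlet patch and upwind outflow at the
outlet. Exterior faces use a series resistance of the half-cell conduction
and a film coefficient from Churchill-Chu (vertical sides) or McAdams
(horizontal top 0.54 Ra^1/4, bottom 0.27 Ra^1/4) correlations evaluated at
the computed surface excess temperature by a 2-step fixed point; a constant
`h` override exists for fixtures. The steady state is one sparse solve;
transients use implicit Euler with dt growing geometrically from 0.06 s
(factorizations reused at each dt level). Thermal properties are
temperature-independent and radiation is neglected, consistent with the
sub-4-degC operating regime.

Verification: the uniform-source slab with Robin boundaries matches
`q L^2/(8 k) + q L/(2 h)` to discretization error (< 1e-10 relative on the
fixture grid), a zero-source run stays at 20 degC, and on every coupled run
the absorbed optical power equals advected outflow plus independently
recomputed exterior loss to well under 2%.

An energy-conservation bound worth keeping in mind when reading coupled
results: the steady outlet temperature rise can never exceed
`P / (rho cp Q)`, which for the ~0.8-1.0 W actually absorbed is ~0.06 K at
0.25 L/min and ~0.015 K at 1 L/min. Large outlet temperature rises at high
flow rates are thus physically impossible under this source; only local
maxima in stagnant regions can reach O(1 K).

## Study conditions and problem sizes

The default sweep (`pe_config()`) runs all 3 geometries x 3 rates at 5 mm
in-plane cells with 6 blood layers (flow: ~20k unknowns; heat: ~25k cells
including the shell) and 1e5 photons — sizes chosen so a full sweep
completes on a single desktop core in minutes while the solved flow metrics
at 0.25 L/min change by well under the acceptance tolerances on refinement.
The grid-sensitivity property tests refine a half-scale device and check
first-order convergence of the rasterized volume and stability of the
chamber-average velocity.

Three accuracy-versus-cost settings are fixed inside the pipeline: the flow
Picard tolerance is 1e-3 at the quantitative 0.25 L/min operating point and
2e-3 at 1 and 3 L/min (where only orderings and ceilings are claimed); the
particle time step is capped at 0.5 s (the CFL condition still limits it
near the ports, and slow particles move well under a cell per step); and
the exterior film coefficient uses a single fixed-point pass (exterior loss
is about 1% of the power budget, so its ~Ra^(1/4) sensitivity to the
surface excess enters far below the reported precision).

## Known limitations

- Point maxima of the temperature field are cell averages on 5 mm cells; a
  0.33 cm beam spot is under-resolved in-plane, so hot-spot maxima are
  biased low relative to a boundary-layer-resolving solution. The steady
  hot spots do co-locate with the stagnation zones, and the < 4 degC
  ceiling holds with a wide margin.
- The hollow-fiber mats are not resolved by the flow or heat solvers (they
  enter only the priming-volume accounting); fiber-scale mixing and
  porous-media drag are absent.
- No CO photodissociation chemistry or carboxyhemoglobin half-life
  modelling: the package models light, flow, residence and heat, which
  bound the photochemical performance but do not predict it.
- High-rate (3 L/min) pressure drops exclude jet impingement losses (see
  above); pulsatile flow, fluid-structure interaction and turbulence are
  out of scope (the chamber Reynolds number stays laminar).
- Both LED faces share one in-plane layout; a lateral offset between faces
  is not modelled.
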