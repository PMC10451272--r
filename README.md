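# photoecmo

Coupled light–flow–heat–particle simulation of a **phototherapy
extracorporeal membrane oxygenator (photo-ECMO)**: a thin blood chamber,
encased in clear plexiglass and irradiated by forty external red LEDs, that
photodissociates carbon monoxide from hemoglobin while blood is pumped
through at clinical ECMO rates. The package exists for device designers who
want to compare chamber shapes — a plain 20 × 20 × 1 cm square against
variants with 5 cm and 10 cm corner fillets — on the four quantities that
decide clinical feasibility: stagnant-flow volume (thrombosis and hot-spot
proxy), priming volume, blood residence time, and thermal load.

## The models at the core

* **Photon transport.** MCML-style Monte Carlo into the blood pool:
  exponential steps with rate μₐ + μₛ, weight fraction μₐ/(μₐ+μₛ) deposited
  per interaction on an (r, z) grid, Henyey–Greenstein deflection, Russian
  roulette with an exactly closed weight ledger. The fully CO-poisoned pool
  uses μₐ(HbCO) = 1.56 cm⁻¹ at 620 nm; each of the 40 LEDs delivers
  0.036 W through 92%-transmitting plexiglass (beam radius 0.33 cm). The
  2D kernel is revolved 360° into a per-LED 3D source and superposed over
  the array.
* **Hemodynamics.** Steady incompressible flow with the Carreau
  shear-thinning law μ(γ̇) = μ∞ + (μ₀ − μ∞)[1 + (λγ̇)²]^((n−1)/2)
  (μ₀ = 0.056 Pa s, μ∞ = 0.0035 Pa s, λ = 3.313 s, n = 0.3568,
  ρ = 1057 kg/m³), solved by a finite-volume thin-gap scheme: staggered
  in-plane velocities per z-layer, one pressure per column, exact discrete
  continuity, Picard iteration with a Schur-complement sparse solve.
* **Residence times.** 100 Lagrangian particles released across the inlet,
  traced through the steady field (tracer limit of Newton's law with Stokes
  drag), cumulative outlet arrivals per minute for 15 min.
* **Thermal load.** Transient/steady convection–diffusion
  ρc_p ∂T/∂t + ρc_p u·∇T − ∇·(κ∇T) = μₐφ in blood, conjugate conduction in
  the plexiglass, natural-convection (Churchill–Chu / McAdams) exterior
  cooling, 20 °C ambient and inflow.

Analytic fixtures (plane Poiseuille, Beer–Lambert slab, Robin-heated slab)
verify each solver against closed forms; see the methods vignette
(`vignettes/photoecmo-methods.Rmd`) for every design choice and its
rationale.

## Worked example

Volume accounting and one coupled operating point of the square chamber:

```r
library(photoecmo)

fib <- fiber_mat_spec()                    # 380 um fibers, 20/cm, 20 layers
sapply(1:3, function(g) priming_volume(device_preset(g), fib))
#> [1] 218.5416 206.8168 171.6422           # cm^3 for fillet 0 / 5 / 10 cm

spec <- device_preset(1)
grid <- build_grid(spec, resolution = 2, nz_blood = 6, include_shell = FALSE)
flow <- solve_flow(grid, blood_rheology(), flow_bc(0.25))
flow_metrics(flow)[, c("avg_chamber_mm_s", "avg_tube_mm_s",
                       "dp_total_Pa", "stagnation_fraction")]
#>   avg_chamber_mm_s avg_tube_mm_s dp_total_Pa stagnation_fraction
#> 1         2.895362      32.89209    6.249619              0.1125
```

So at 0.25 L/min blood crosses the square chamber at ~2.9 mm/s on average,
enters through the tubes at ~33 mm/s, costs ~6.2 Pa of pressure, and 11%
of the blood volume moves slower than 1 mm/s — the stagnant corners the
fillets are designed to remove. Tracing particles shows how long blood
actually stays inside:

```r
rt <- trace_particles(flow, n = 100, seed = 11)
rt$count[c(1, 2, 10)]
#> [1] 47 78 95                              # cumulative arrivals at 1/2/10 min
```

The full 3-geometry × 3-rate study, with the LED heat source and thermal
solves, runs through the pipeline:

```r
bundle <- run_pipeline(pe_config(seed = 1))
compare_geometries(bundle)                  # stagnation / volume / dT ranking
```

`compare_geometries()` codifies the design argument: among shapes that
reduce stagnation relative to the square and stay below a 4 °C rise, pick
the one with the largest treated volume — the 5 cm fillet.

## Command line

A thin wrapper over the same functions lives at `inst/cli/photoecmo.R`
(verbs: `geometry`, `light`, `flow`, `trace`, `heat`, `fixtures`, `report`,
`compare`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/photoecmo.R", package="photoecmo"))')" \
    flow --config inst/extdata/geometry2.yaml --rate 0.25
```
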