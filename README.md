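# cyanomech

Structural mechanics of filamentous cyanobacteria — and of slender microbial
filaments generally — measured from microfluidic flow-cell deflection
experiments.

Filamentous cyanobacteria (Oscillatoriales such as *Kamptonema*, *Lyngbya*
and *Oscillatoria*) are chains of cells a few micrometres across and up to
millimetres long. Mechanically they act as slender elastic rods, and the
single most important number for modelling their gliding motility, bundling
and biofilm self-organization is the bending stiffness (flexural rigidity)
β, of order 10⁻¹⁷ N m². `cyanomech` implements the full measurement
pipeline:

* **Channel hydrodynamics** — the rectangular-duct series solution for
  laminar Poiseuille flow (no-slip, mean speed U₀ set by the pump) and the
  low-Reynolds cylinder drag law ξ = 4πμ / ln(7.4/Re), Re = 2ρru_n/μ.
* **Beam mechanics** — linearized cantilever integration of
  β δ''''(s) = w(s) with clamped/free boundary conditions, plus the
  thin-walled-cylinder relations β = πEr³Δr, σ_s = κEr and U = ½βκ̃².
* **Stiffness inference** — the inverse procedure: the observed deflection
  profile of an anchored filament is decomposed into a bending mode and a
  small solid-body rotation α about the anchor, minimizing
  Σ (c(s)/β − |x(s) − R(α)x₀(s)|)², with a closed-form β at fixed α and a
  bounded search over α. Per-point β(s) diagnostics, inverse-variance
  strand aggregation and species summaries included.
* **Shape statistics** — skeleton tracing from binary images, tangent and
  curvature profiles, Pratt circle fits, tangent-correlation persistence
  length via ⟨cos φ⟩ = exp(−Δs/2P), and the energy scales β/P² and
  β/k_BT.
* **Synthetic data** — generators for circular-arc ensembles, planar
  worm-like chains, rasterized filament images and complete flow-cell
  experiments with known ground truth, so every estimator is validated by
  parameter recovery.

## Worked example

Generate a synthetic flow-cell experiment with known ground truth
(β = 5×10⁻¹⁷ N m², rotation 0.3°, 0.5 px pixel noise) and invert it:

```r
library(cyanomech)
env <- flow_environment(channel_geometry(width = 300e-6, height = 134e-6),
                        mean_speed = 1e-3)
syn <- gen_deflection_experiment(5e-17, rotation = 0.3 * pi / 180, env,
                                 noise = 0.5, seed = 103)
fit <- fit_filament_stiffness(syn$experiment)
summary(fit)
#> Flow-cell bending stiffness fit
#>   filament: L = 250 um, r = 2.2 um, height z = 0 um
#>   flow: U0 = 1 mm/s, channel 300 x 134 um, Re_c = 0.185
#>   beta  = 4.952e-17 N m^2
#>   alpha = 0.3312 deg
#>   per-point beta: mean 4.945e-17, sd 3.7e-18 N m^2 over 433 samples
#>   RMS residual: 0.346 um (tip deflection 32.4 um)
```

The fitted stiffness is within 1% of the ground truth and the recovered
rotation within a few hundredths of a degree; the per-point profile spread
(sd/mean ≈ 7%) reflects the imposed pixel noise. `plot(fit)` shows the
rest/deflected configurations and the fitted deflection profile;
`simulate(fit)` draws parametric replicates.

Persistence length of a disordered (inactive-filament-like) ensemble:

```r
chains <- gen_wlc_filaments(150, persistence = 7e-3, seed = 1)
fit_persistence_length(angular_correlation(chains))
#> Persistence length: P = 7.608 mm (17 bins, SSE 2.5e-06)
```

Derived cell-wall mechanics for the bundled species-level measurements
(wall thickness in m, maximal wall stress in Pa, bending energy density in
J/m, with delta-method standard errors):

```r
derive_summary(species_table())[, c("species", "dr", "sigma_s", "U")]
#>          species           dr sigma_s            U
#> 1     K. animale 3.587264e-08 41360.0 5.301600e-12
#> 2 L. lagerheimii 8.968160e-08 19888.0 6.129120e-12
#> 3       O. lutea 3.437101e-08 29320.2 3.748797e-12
```

That is: walls a few tens of nanometres thick carrying peak bending
stresses of tens of kPa, and a few pJ/m of stored bending energy in the
curved gliding shape.

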