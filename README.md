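# reefshield

Coral reefs act as natural breakwaters: waves break on the shallow crest
and lose further energy to the drag of the rough coral canopy, so the
run-up reaching the shoreline is a fraction of what an unprotected coast
would receive. When disturbances (predator outbreaks, cyclones,
bleaching) strip living coral, the reef flattens, its hydraulic roughness
collapses, and extreme run-up events become more frequent — even without
any change in offshore wave climate or sea level.

`reefshield` is an R implementation of that causal chain as a tested,
reusable pipeline, aimed at coastal scientists and ecologists who want to
explore reef-state scenarios end to end:

1. **Reef construction and structural complexity.** Synthetic coral
   assemblages are built on a substrate strip from per-taxon cover and
   colony-size survey tables; complexity is the rumple index
   `SC = (3D surface area) / (planar area)` of the composite surface.
2. **Hydraulic roughness.** The empirical power law
   `k_n = 0.01 × SC^2.98` (m) converts complexity into a Nikuradse
   roughness height; section coefficients and a grain-size value
   (`k_n = 2.5 d50`) extend it into a continuous cross-shore profile.
   An independent spectral-attenuation estimator recovers `k_n` from
   paired bottom-pressure records through the energy balance
   `dF/dx = −(2/3π) ρ f_w u_b³`.
3. **Wave propagation.** A one-dimensional Boussinesq solver
   (dispersion coefficient B = 1/15, surface-roller breaking, swash
   eddy viscosity with mixing length 3.5 h, bed friction
   `τ_b = ½ ρ f_w U|U|` with
   `f_w = exp[5.213 (k_n/a₀)^0.194 − 5.977]`, thin-film dry-bed
   shoreline) propagates irregular JONSWAP seas from 20 m depth to the
   beach and returns the 2% exceedance run-up R₂%.
4. **Climate ensemble.** Weekly offshore (Hs, Tp) pairs give empirical
   Hs percentiles 0.1–100; Tp is attached through a maximum-likelihood
   Gaussian copula; one simulation runs per reef state × condition.
5. **Extremes and synthesis.** Weighted generalized Pareto fits give
   return-level curves per state and the frequency amplification of
   extreme run-up under degradation; a Bayesian interaction model
   `RU ~ N((α+σ_ζ)Hs + (β+σ_ζ)SC + (γ+σ_ζ)SC·Hs, σ)` with N(0,1) and
   Γ(2, 0.1) priors summarises the ensemble (4 chains × 5000 draws,
   1000 warm-up, 16,000 retained).

All inputs can be generated synthetically (`generate_survey_table()`,
`generate_bathymetry()`, `generate_wave_climate()`,
`generate_pressure_records()`), so the whole pipeline runs and is tested
without any external data. See the methods vignette
(`vignettes/reefshield-methods.Rmd`) for the models, closures, defaults
and known limitations.

## Worked example

Compare the run-up on a fringing-reef coast under a healthy
(structurally complex) and a degraded reef state:

```r
library(reefshield)

bathy <- generate_bathymetry()       # 20 m depth -> crest -> flat -> beach
kn_healthy  <- build_kn_profile(3.86, bathy)   # k_n = 0.560 m on the reef
kn_degraded <- build_kn_profile(1.58, bathy)   # k_n = 0.039 m

sim_h <- run_simulation(bathy, kn_healthy,  hs = 2, tp = 12,
                        duration = 1800, seed = 42)
sim_d <- run_simulation(bathy, kn_degraded, hs = 2, tp = 12,
                        duration = 1800, seed = 42)
sim_h
#> Boussinesq reef simulation
#>   offshore Hs = 2.00 m, Tp = 12.0 s, duration = 1800 s
#>   R_2% = 1.307 m (39 run-up events, low confidence)
#>   dissipated energy fraction toe -> inner flat: 1.00
sim_d$r2
#> [1] 1.487
energy_absorption(sim_d)
#> [1] 1
```

With a 0.5 m crest both states absorb nearly all sea-swell energy
before the inner flat, yet the degraded reef still sends about 14% more
run-up to the beach in this condition (1.49 m vs 1.31 m): the difference
is carried by the swash and infragravity motion that the healthy reef's
drag suppresses. The contrast is largest for small waves that cross the
crest unbroken and for energetic seas (structural complexity matters
most during extreme events); a whole wave climate is summarised by
`run_ensemble()`, `fit_gpd()` and `frequency_amplification()`. The full orchestration, from synthetic
surveys to the Bayesian posterior, is one call:

```r
res <- run_pipeline(seed = 1, profile = "desk", out_dir = "run1")
res$sc_summary      # per-year structural complexity, median and 5-95%
res$amplification   # return periods and amplification factors
```

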