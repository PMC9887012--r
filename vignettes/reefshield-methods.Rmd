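---
title: "From coral structural complexity to coastal wave run-up: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From coral structural complexity to coastal wave run-up: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(reefshield)
```

`reefshield` quantifies how the three-dimensional structural complexity of
a fringing coral reef controls wave-driven run-up on the coastline it
shelters. The pipeline has six scientific stages, each usable on its own:

1. **Synthetic reef construction** — coral colonies are placed on a
   substrate strip until survey cover targets are met, and the rumple
   index (3D surface area over planar area) of the composite surface
   measures structural complexity, SC.
2. **Hydraulic roughness** — SC is converted to a Nikuradse roughness
   height through the empirical power law `k_n = 0.01 SC^2.98` (m), and a
   continuous roughness profile is assembled along the cross-shore
   transect; an independent spectral-attenuation estimator recovers `k_n`
   from paired bottom-pressure records.
3. **Wave propagation** — a one-dimensional Boussinesq solver with
   surface-roller breaking, swash eddy viscosity, quadratic bed friction
   and a thin-film shoreline propagates irregular waves from 20 m depth
   across the reef and extracts the 2% exceedance run-up, R₂%.
4. **Climate ensemble** — weekly offshore (Hs, Tp) pairs feed empirical
   Hs percentiles (0.1–100 by 0.1) whose peak periods are linked through
   a fitted Gaussian copula; one simulation per reef state and condition.
5. **Extremes** — weighted generalized Pareto fits of R₂% per reef state
   give return-level curves and the change in frequency of extreme
   run-up between healthy and degraded states.
6. **Bayesian synthesis** — a linear interaction model of run-up on
   offshore Hs and SC with fixed priors summarises the ensemble.

## Synthetic data: what it emulates, and what it does not

All inputs can be generated synthetically, so every stage is testable
without field data. The generators emulate the statistical structure of a
high-energy Pacific fringing-reef site:

* `generate_survey_table()` follows a ten-year disturbance–recovery cycle
  of living coral cover — 50% before disturbance, collapse to 3%, and
  recovery to 45% dominated by *Pocillopora* — with per-taxon lognormal
  colony size distributions.
* `generate_bathymetry()` builds a piecewise transect at 1 m resolution:
  a fore reef rising from 20 m depth to a 0.5 m crest over 160 m, a reef
  flat, a 150 m coral back reef, a sandy lagoon section (2.5 m deep, the
  sandy section lies within the reef-flat/lagoon zone) and a subaerial
  beach of slope 0.1. The lagoon is deeper than the flat, as on real
  fringing reefs, so reformed waves re-shoal onto the beach face.
* `generate_wave_climate()` draws weekly Hs from a Weibull marginal with
  mode near 1.5 m (52 records per year) and links Tp through a Gaussian
  copula (default ρ = 0.5); both the marginal and the dependence strength
  of the real hindcast are unknown, so they are configuration, not
  assertions.
* `generate_pressure_records()` is the closed-loop oracle for the
  roughness inversion: bottom-pressure bursts at paired sensors whose
  spectral energy flux decays exactly per the friction-dissipation law
  that `estimate_kn_spectral()` inverts. Additive Gaussian noise at an
  amplitude SNR of 100 reflects the mm-scale resolution of modern
  pressure transducers. Component frequencies snap to the burst's Fourier
  grid so the discrete spectra are leakage-free.

The bare substrate carries a deterministic microtopography (default
amplitude 0.055 m, three octaves around a 0.5 m wavelength): dead
carbonate framework and rubble retain decimetre-scale relief even when
living cover is lost, which is why a fully disturbed reef keeps a
structural complexity well above 1 (the synthetic disturbed state lands
near SC ≈ 1.6). Colonies sit on that relief surface.

The coral shapes are parametric proxies — a tabular plate (*Acropora*), a
corrugated dome (*Pocillopora*), a smooth hemispheroid (*Porites*) — not
photogrammetric meshes. They reproduce the qualitative per-taxon rumple
ordering (*Pocillopora* > *Acropora* > *Porites*) and the scaling of
assemblage complexity with cover and colony size, but **absolute** SC
values depend on this choice: the branching proxy's sub-centimetre
texture (mesh rumple near 9) is partly lost to the raster resolution, so
synthetic healthy assemblages saturate near SC ≈ 2.5–2.8 rather than the
≈ 3.9 that photogrammetric meshes of branching corals reach. Passing
tests therefore demonstrate the pipeline's internal consistency and
qualitative behaviour, not agreement with any specific reef's measured
complexity.

## Structural complexity

`populate_cross_section()` adds colonies one at a time — random mesh from
the shape bank, size resampled from the survey distribution, uniform
position, uniform rotation in [−π/2, π/2] — until each taxon's summed
planar footprint first reaches its cover target (threshold crossing).
Overlap is allowed; summed-footprint accounting is the default and a
union-of-footprints mode is available where heavy overlap would otherwise
overcount. The composite surface is a height field (max of substrate and
colony surfaces, default cell 1 cm at study scale) whose rumple index
divides the triangulated 3D area by the planar area. Rasterized height
fields cannot represent overhangs and underestimate exactly vertical
faces; closed-form checks on curved surfaces (hemisphere = 2) therefore
use the mesh route, while planes are exact on both routes.

At study scale the ensemble is 100 replicates for each of 10 survey years
(1000 SC profiles). Tests and the acceptance analyses use a shorter strip
(10–20 m) and a coarser cell (2–5 cm), stated here as the package's
desk-scale choice; medians are insensitive to the strip length because
placement is spatially homogeneous.

## Roughness profiles

The fore reef takes `sc_to_kn(SC)`; the crest and the coral back reef
scale it by section coefficients α (ratios to the fore-reef value,
default 1 — the field values are site-specific and unpublished, so they
are configuration); the sandy section takes the grain-size roughness
`k_n = 2.5 d₅₀` (Nielsen-type convention) with d₅₀ = 63 µm. One profile
per SC replicate, and each state's pointwise-median profile represents it
in the ensemble.

The spectral estimator integrates one-sided periodogram energy flux
(linear-theory group velocities absorb shoaling) over the 0.04–0.4 Hz
sea–swell band, excludes noise-dominated bins below 10⁻⁴ of the peak,
attributes the flux loss between sensors to friction through
`ε = (2/3π) ρ f_w u_b³`, and inverts the Jonsson friction-factor relation
for `k_n` (lower bound 10⁻⁴ m; bursts with non-positive inferred
dissipation are flagged and excluded). Closed-loop recovery against the
forward generator is within a few percent over `k_n` ∈ [0.05, 0.6] m.

## The wave solver

The solver integrates depth-averaged continuity plus a higher-order
momentum equation of the improved-dispersion Boussinesq family: Peregrine
dispersive terms with the additional `B = 1/15` terms, giving the phase
speed `c² = g d (1 + B(kd)²) / (1 + (B + 1/3)(kd)²)`. (The printed source
equation of this model family circulates with typographically garbled
dispersive terms; the standard form above is implemented.) Terms with
mixed space–time derivatives are grouped into an auxiliary variable
advanced in time by a third-order Adams–Bashforth predictor and
fourth-order Adams–Moulton corrector; velocity is recovered each stage by
a tridiagonal solve. Two startup steps use the explicit midpoint rule.

Key closures, with defaults and the reasoning behind them:

* **Breaking.** A Schäffer-type geometric roller: breaking initiates
  where the shoreward front slope exceeds tan 20° and persists above
  tan 10°; roller thickness is the water above the 10° line from the
  local crest, capped at 0.8 h; celerity 1.3 √(gh). A depth-limited
  trigger (crest elevation above 0.55 × still depth) catches long waves
  whose fronts never steepen to the slope criterion at 1 m resolution.
  The roller's energy dissipation is closed numerically by an
  eddy-viscosity term ν = 2.5 c δ at flagged nodes.
* **Swash.** Depths below R/4 (R from the Stockdon estimate on the beach
  slope) form the swash zone, where the roller is replaced by
  eddy-viscosity diffusion with mixing length 3.5 h, active only on
  converging flow (steepening fronts) so uprush and backwash are not
  artificially damped.
* **Friction.** `τ_b = ½ ρ f_w U|U|` with
  `f_w = exp[5.213 (k_n/a₀)^0.194 − 5.977]`, capped at its `k_n/a₀ = 1`
  value. The orbital amplitude a₀ is computed per node from linear theory
  at the peak period and the local running Hs, refreshed every 100 steps.
  Two refinements matter in the surf zone: the friction velocity is
  capped at 1.5 × the linear orbital-velocity scale (the depth-averaged
  spike of a breaking bore is carried by the roller above the boundary
  layer), and the wave-mean part of the quadratic stress is removed
  (tapered off shallower than ~0.2 m total depth). Without the second
  refinement the skewness of bores pumps a spurious roughness-dependent
  onshore mean stress whose setup can exceed the physical
  radiation-stress setup; wave-momentum theory puts the true mean stress
  of friction-dissipated waves near ε/c, an order of magnitude smaller.
* **Shoreline.** "Dry-bed" run-up via a thin film (0.5 mm) on dry nodes,
  a 1 mm wet/dry threshold, a dam-break bound |U| ≤ 2√(gh), and the
  waterline defined by depths above 5 mm. Run-up statistics use the
  quasi-stationary part of the record (after 35% of the run) and event
  maxima referenced to a running setup level, so slow lagoon filling
  does not masquerade as swash.
* **Numerics.** dx = 1 m default, dt = 0.2 dx/√(g d_max); dispersive
  terms are smoothly tapered off below a cutoff still depth (0.3 m,
  raised to Hs/2 for energetic runs — bores with amplitude comparable to
  depth are outside Boussinesq validity); a conservative
  curvature-sensing three-point filter supplies shock dissipation only
  where the surface curvature is significant relative to the local depth
  (it leaves linear dispersion tests bit-accurate and conserves volume
  exactly); momentum advection is upwinded at breaking nodes and in the
  thin swash tongue.
* **Generation/absorption.** Internal mass-source wavemaker (Gaussian
  spatial distribution, component amplitudes from a JONSWAP spectrum with
  γ = 3.3, source strength 2 c a corrected for the source width) and a
  sponge layer of about one peak wavelength at the offshore boundary.
  A monochromatic mode supports deterministic sensitivity studies.

Simulated durations: 1200 s default per ensemble run (≈100 peak periods;
the run-up statistics flag records with fewer than 50 events as
low-confidence), 2400 s for two-state comparisons in the package's own
analyses. Each 1-hour-equivalent run on the ~620-node default transect
takes a few seconds.

**Known limitations.** The model is one-dimensional, with three
consequences worth keeping in mind. First, the lagoon cannot drain
alongshore: for offshore Hs beyond ≈ 4.5 m, wave pumping over the nearly
drying crest ponds the lagoon and run-up levels lose quantitative
meaning (they remain finite and stable, and affect both reef states
through the same matched conditions); ensemble analyses should stop at
about the 99th wave-height percentile. Second, the enclosed lagoon
supports an essentially undamped seiche (real lagoons radiate that
energy alongshore and through passes), which can dominate desk-scale
run-up records; controlled two-state comparisons therefore use the
generator's flat-to-beach transect variant without the deep lagoon.
Third, even with the friction refinements above, the depth-averaged
closure only approximates the vertically sheared surf-zone mean flow:
in two-state comparisons the degraded (smooth) reef produces clearly
higher run-up at low offshore Hs (where waves cross the crest without
fully breaking and roughness dissipation dominates) and at high Hs
(where the healthy reef's drag on energetic bores matters most — the
protective effect grows with wave height), but at moderate Hs
(≈ 1.3–1.8 m here), with both states fully depth-limited at the crest,
the residual setup response to roughness offsets the swash reduction
and the two states' run-up is statistically indistinguishable or
slightly reversed. Reflection from the steep fore reef also stands
partially in the domain, so nearshore Hs diagnostics include reflected
energy.

## Climate ensemble

`fit_hs_tp_copula()` fits the one-parameter Gaussian copula by maximum
likelihood on rank-transformed pseudo-observations (the closed form
Kendall τ = (2/π) asin ρ is reported alongside the empirical τ);
`build_conditions()` takes empirical Hs quantiles at percentiles
0.1–100 and links Tp as the conditional median (conditional mean
available). The Gaussian family is the default because the dependence
family of the source climate is unspecified; it is configuration.
`run_ensemble()` derives each condition's seed from the global seed and
the condition index only, so all states see the same incident wave
realisation — state contrasts are paired, which sharply reduces the
variance of between-state comparisons — and failed runs are logged,
marked and skipped.

## Extremes

R₂% samples (one per condition, equal percentile-band weights, 52
independent weekly events per year) feed a weighted maximum-likelihood
GPD fit above the weighted 90th percentile by default; the annual
exceedance rate is λ_u = 52 × P(R > u). Return levels use the standard
closed form, inverse lookups are closed-form (no interpolation), and the
frequency amplification between states is T divided by the return period
of the healthy state's T-year level on the degraded curve, flagged as a
lower bound when that level sits below the degraded threshold. The
threshold rule and annualization are package decisions, configurable,
because the corresponding field-study choices are unpublished.

## Bayesian run-up model

The model is exactly the stated structure: `RU ~ N(μ, σ)` with
`μ = (α + σ_ζ) Hs + (β + σ_ζ) SC + (γ + σ_ζ) SC·Hs`, priors
N(0, 1) on α, β, γ and Gamma(shape 2, rate 0.1) on σ and σ_ζ; four
chains × 5000 draws with 1000-step warm-up retain 16,000 draws, gated at
R̂ < 1.05. The shared dispersion term σ_ζ enters all three slopes
additively, which leaves (α, β, γ, σ_ζ) identified only through the
sums α+σ_ζ, β+σ_ζ, γ+σ_ζ; the sampler therefore works in those
identified sums (an exact change of variables with unit Jacobian) and
reports both raw and effective coefficients. Because of the ridge, a
coverage study of the raw coefficients is only calibrated when all five
parameters are drawn from their priors per replicate dataset
(simulation-based-calibration design); that is how the package's
recovery study is run. Predictors are scaled by their standard
deviations (no centring, preserving the no-intercept structure) so the
unit-scale priors are appropriate; Gibbs/slice sampling via JAGS is the
implementation choice of sampler. Predictions cover offshore Hs 1–6 m by
1 m against the SC gradient, and the residual run-up subtracts each Hs
level's minimum so the least exposed state sits at zero.

## Orchestration

`run_pipeline()` executes the stages in order with a single global seed
fanned out through a counter-based mixing scheme (stage order cannot
perturb per-run streams), JSON-lines stage logs, CSV/JSON outputs and a
manifest carrying the configuration hash. The `desk` profile (10
replicates per year, two states, 30 percentile conditions, 400 s runs)
is for interactive work and testing; `full` is study scale. All stage
functions also run independently on files produced by the previous
stage.
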