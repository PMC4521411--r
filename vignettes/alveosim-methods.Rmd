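---
title: "Modelling nanoparticle fate in the alveolar lining fluid with alveosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nanoparticle fate in the alveolar lining fluid with alveosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alveosim)
```

## The model

Inhaled engineered nanoparticles that reach the alveolar region land on
the pulmonary surfactant layer and are pulled through a ~0.2 µm film of
alveolar lining fluid toward the epithelial cell surface. On the way they
are transformed: surfactant lipid vesicles adsorb and rupture into
supported bilayers on the particle surface, surfactant proteins
(SP-A/B/C/D) build a corona, the silver core oxidises and dissolves, and
particles collide and agglomerate. The state in which a particle finally
arrives at the cells — its size, agglomeration number, lipid coverage and
protein load — is what downstream cellular dosimetry sees.

`alveosim` simulates this with a constant-number direct-simulation Monte
Carlo (DSMC) scheme. A control volume (CV) of lining fluid holds `N`
tracked particles (default 100). Each sweep of the loop fires the process
modules — agglomeration, vertical transport, lipid-vesicle adsorption,
protein adsorption, dissolution — advances time, re-establishes the CV so
the tracked number stays `N` while the represented concentration falls,
and records the state. A run stops when the suspended concentration drops
to 1% of its initial value (`stop_fraction`) or at `max_time`.

Two in vitro calibration scenarios reproduce published incubation
experiments (a seven-day citrate-silver/DPPC study at pH 3–7, and a
one-hour stirred silica/DOPC vesicle study); the in vivo scenario
represents a single-breath human exposure at 0.14 mg/m³, with the
deposited number dose per unit alveolar area converted into the CV.

## Process models

**Lipid vesicle adsorption.** Alveolar vesicles are a two-class mixture:
small unilamellar vesicles (20–50 nm) and large ones (50–500 nm), each a
normal distribution whose 5th/95th percentiles sit at those limits; the
class is drawn with the lavage light/heavy fraction weights 43:48
renormalised over the two classes (the 9% ultra-heavy aggregate fraction
is treated as non-adsorbing). A candidate vesicle adsorbs on a particle
with probability `Pad = exp(-α d_ves² / (f_SA² d_ENM²))`, accepted when a
uniform draw falls below `Pad/(Pad + P_diff)` with the constant
diffusion-encounter probability `P_diff = 0.001`. An adsorbed vesicle
ruptures immediately and spreads a 4-nm bilayer patch equal to its outer
surface area; coverage is capped at a full monolayer and excess patch
area is discarded (returned to the pool where the pool is finite). In the
in vitro scenarios the lipid pool is depleted by adsorption; in vivo the
alveolar cells hold the lipid and protein concentrations constant.

The physical time per adsorption attempt is not fixed by the published
scheme. We attach to each attempt the time a vesicle needs to diffuse
across the mean inter-vesicle spacing, `τ_ves = l²/(6 D_ves)` with
`l = C_ves^{-1/3}` and the literature encounter diffusivity
`D_ves = 8.7e-10 m²/s`. This timescale is independent of particle size,
consistent with holding `P_diff` constant regardless of size. At the
alveolar lipid concentration (328 µg/mL) it gives `τ_ves ≈ 4.6e-5 s`, so
a 20-nm particle is fully coated in a few tens of microseconds — fast
relative to its millisecond transit of the lining layer.

**Protein corona.** Each surfactant protein species adsorbs under the
slower of two regimes: adsorption-limited, with per-particle attempt rate
`2R² C_o k_a'` (headgroup radius `R`, number concentration `C_o`, net
rate `k_a' = k_a/k_d`), or diffusion-limited, with the decaying flux
`2R² C_o √(D/(πt))`. Coverage dependence follows the power laws
`k_a = k_a0 (1 + β_a θ^{n_a})` and `k_d = k_d0 (1 + β_d θ^{n_d})`;
desorption is folded into the net rate rather than simulated as discrete
removals. Adsorbed molecules occupy their headgroup footprint and the
total footprint cannot exceed the particle surface area — which is why
SP-D (92-nm headgroup) never fits on a 20-nm particle.

The species baselines are not recoverable from the published record, so
they are model choices (all config-overridable): the surface-active
SP-B/SP-C, closely associated with surfactant lipids, are given large
`k_a0` so their adsorption runs at the physical diffusion limit, with
strong lipid enhancement (`β_a = 4`); the collectins SP-A/SP-D adsorb
reaction-limited with small `k_a0 = 5e-10 m/s` and weak enhancement
(`β_a = 0.25`). With the printed concentrations and headgroup sizes an
undifferentiated choice would invert the observed corona composition,
because SP-A and SP-D have ~100-fold larger `2R²C_o`; the
surface-active/collectin split restores the observed SP-B/SP-C
dominance.

**Transport.** In vitro, particles settle by Stokes' law (disabled for
the stirred scenario); in vivo, gravitational settling is replaced by
surface-tension-driven immersion. Equating the capillary force
`F_s = 2πRγ sin(φ) sin(θ_c + φ)` to Stokes drag gives the
size-independent speed `v = (γ/3μ) sin(φ) sin(θ_c + φ)` —
the particle radius cancels, so every particle spec immerses at the same
velocity. Evaluated at the published interface angles (θ_c = 20°,
φ = 160°) the sine product vanishes, which contradicts the finite
published transport rate; we therefore drive in vivo motion with a
calibrated immersion-speed constant `v_immersion = 7.481e-5 m/s` (the
published rate) and keep `surface_tension_velocity()` as the documented
force balance. A Brownian kick with Stokes–Einstein diffusivity is added
each sweep; depth reflects at the air–liquid interface and absorbs at the
cell surface, where the particle joins the deposited inventory with its
full adsorbed state.

**Agglomeration.** Pairs coagulate with the modified Smoluchowski kernel
`β_ij = (2kT/3μ)(d_i+d_j)²/(d_i d_j) / W_ij`. The stability ratio `W`
comes from the pair energy `V(h)`: Hamaker sphere–sphere van der Waals
attraction (default `A_H = 3.7e-20 J`), linearised double-layer repulsion
with the coverage-weighted zeta potential `ζ = ζ_L θ + ζ_0 (1-θ)` and the
Debye length of the medium, plus the polymer-brush steric energy
`E_st = η_S kT (n_m L/s)[(2L/d)^{2.25} - (d/2L)^{0.75}]` for separations
inside twice the chain length. The steric factor η_S multiplies the
energy (its exact placement is not printed; this is the simplest
reading), and the mean chain spacing is taken as the geometric
`s = 1/√n_m` for a surface density `n_m` per unit area.

Numerically, `W` is the Fuchs integral of `exp(V/kT)` from the outermost
barrier crest outward. Because the brush term diverges at contact, a
coated pair's capture state is its deepest attractive minimum (usually
the secondary minimum at brush contact); a shallow minimum does not hold
a pair against thermal motion, so the barrier factor is divided by the
capture efficiency `ε = 1 - exp(-|V_min|/kT)`. This makes stability
continuous in the inputs: bare DLVO pairs recover the classical
behaviour, strongly brush-stabilised pairs get `W → 1e30` (no
coagulation), and weakly stabilised PVP pairs coagulate slowly rather
than switching off — matching the observation that PVP-coated particles
agglomerate only slightly more slowly than citrate-coated ones. Within
the engine the pairwise rates drive an exact event-driven (Gillespie)
loop inside each sweep, with the represented concentration updated after
every merge so coagulation self-limits; this realises the same process as
majorant rejection sampling (`dsmc_agglomeration_attempt()`) without
wasting rejected draws. Stability ratios are memoised on rounded
(size, coverage) pairs.

Merged particles are volume-equivalent spheres (fractal dimension 3);
coverage mixes area-weighted, protein counts and lipid mass add.

**Dissolution.** The published model defers the oxidative rate law to
earlier work, so we adopt a surface-limited first-order law:
`dm/dt = -k_0 e^{-E_a/RT} [O_2] · 10^{λ(7-pH)} g(I) c_coat f_SA π d²`,
with linear O₂ dependence, exponential pH acceleration (λ = 0.25 per pH
unit), `g(I) = 1`, a per-coating multiplier (citrate 1, PVP 1e-3 — the
published in vivo dissolution gap between the coatings spans 2–3 orders
of magnitude and cannot arise from coverage alone), and complete blocking
by a full lipid layer (`f_SA = 0`). `k_0` is calibrated once so a bare
20-nm citrate particle at pH 7 loses ~5% of its mass over seven days,
inside the observed in vitro range. Silver mass is conserved exactly:
dissolved mass moves to the medium pool, and particles below 1 nm are
removed with their remainder credited to the pool.

## Constant-number bookkeeping with statistical weights

Classic constant-number schemes restore `N` after a removal by
duplicating a random survivor, which conserves mass only in expectation.
Here every tracked particle carries a statistical weight (physical
particles represented per tracked particle). A removal (deposition or
complete dissolution) is compensated by *splitting* a random survivor's
weight in half across two identical rows; a merge of unequal-weight
partners first splits the heavier partner so the merging pair has equal
weight. Total weight — the represented concentration — falls exactly by
what was removed, and particulate + dissolved + deposited silver is
conserved to floating-point precision (the test suite demands 1e-9
relative). The control volume is re-established each sweep as
`V = n_tracked / (n_0 · Σw/N_0)`.

## Time stepping

The sweep time step follows the slowest-process rule: `Δt` is the largest
finite process timescale (a `fastest` policy is available for
comparison), and faster processes fire `Δt/τ` events within the sweep, so
nothing is starved. Three numerical bounds protect the discretisation:
`Δt` never exceeds 1/20 of the fastest transport crossing time (so the
deposition front is resolved; the transport-oracle test uses 1/400), a
per-sweep event budget (default 2e4 attempts) bounds memory and CPU when
timescales are very disparate, and `Δt` never overshoots `max_time`.
Processes that cannot act (saturated coverage, exhausted lipid pool, no
finite rate) report an infinite timescale and drop out of the policy.
Within-sweep vesicle event times are drawn uniformly (the correct
conditional distribution for a Poisson process), which matters because a
20-nm particle's entire coating window can sit inside one sweep.

## Kinetic-rate estimators

`estimate_kinetic_rates()` reduces a run to the summary rates:
diameter-growth slope (agglomeration), thickness over mean deposited
transit time (transport; censored particles excluded), dissolved fraction
per unit time, and protein fluxes in nmol per nm² per second of
residence, split into surface-active (SP-B+SP-C) and collectin
(SP-A+SP-D) classes.

The phospholipid adsorption rate is coverage-based: adsorbed mass per
unit surface area divided by the *active coating window* (entry to the
particle's last adsorption event), matching accounting in terms of
fractional coverage by a uniform 4-nm bilayer. A full-residence variant
is also reported (`pl_adsorption_rate_fullrun`). The distinction matters:
coating completes within tens of microseconds while transit takes
milliseconds, and a full-residence denominator is bounded above by
(bilayer areal mass)/(transit time) ≈ 1.7e-9 ng/nm²/s for any trajectory
at the default immersion speed — an order of magnitude below the
published rates, which the coating-window estimator reproduces. One
consequence is worth stating openly: with coverage capped at one bilayer,
the areal mass rate is proportional to the coverage rate, so "smaller
particles coat faster" (which this model reproduces, and which the source
figures show) and "the 110-nm citrate rate exceeds the 20-nm one" (which
the published table prints) cannot both hold; this package reproduces the
published values to well within an order of magnitude but with the
opposite size ordering.

## Sensitivity analysis

`local_sensitivity()` perturbs one parameter at a time by 1% and reports
`S_i = (V_i^* - V)/(V·Δp_i)`, averaged over 10 paired-seed iterations
(perturbed and base runs share seeds to suppress Monte Carlo noise) and
normalised per output by the largest-magnitude index. The default
parameter list has the standard 17 entries in three groups
(alveolar-interface, phospholipid-adsorption, particle properties); the
simulator hook accepts any function from a config to named outputs, which
the test suite uses to verify `S_i = 1` exactly on a linear model.

## What the synthetic scenarios do and do not show

The scenario generator reproduces the *conditions* of the source studies
— concentrations, ionic strengths, pH values, temperatures, particle
specs — not their measured outcomes. Passing tests therefore show that
the mechanisms interact as specified under those conditions, not that the
model predicts any particular laboratory measurement; the figure-level in
vitro comparisons (digitised curves) are outside this package's scope.
Known limitations: lipid-coated citrate particles at low ionic strength
come out less stable than the DPPC-supplemented seven-day study suggests
(the brush model underestimates electrosteric stabilisation of
lipid-coated surfaces at 0.1 mM); protein corona composition rests on
chosen kinetic baselines; vesicle size distributions for the commercial
in vitro formulations default to 100 ± 20 nm (extruded-formulation
convention) and the seven-day study's DPPC supplementation concentration
is not printed (default 0.1 mg/mL); conformational change of adsorbed
proteins, sulfidation, fragmentation and lateral transport are not
modelled.

## Problem sizes

The shipped defaults follow the study design: `N = 100` tracked
particles, 10 replicates per particle spec, stop at 1% concentration. A
full in vivo replicate takes on the order of a second; the seven-day and
one-hour in vitro scenarios run in well under ten minutes each. Test
configurations use 20–150 particles and shortened horizons where a
property does not require the full design.

## A worked in vivo run

```{r example, eval = FALSE}
cfg <- sim_config("invivo_human", "C20", seed = 1)
run <- run_simulation(cfg)
run
estimate_kinetic_rates(run)
autoplot(run, "coverage")

# replicate-averaged rates (the study design: 10 runs per spec)
rates <- average_over_runs(cfg)
rates$summary
```
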