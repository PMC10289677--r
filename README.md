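# crowdcell

Crowding-adjusted reaction kinetics and the optimal dry-mass occupancy of a
bacterial cytosol.

`crowdcell` is for quantitative cell biologists and biophysical modellers who
want to ask: given that macromolecular crowding simultaneously *boosts*
binding equilibria (excluded volume favours the compact enzyme–substrate
complex) and *throttles* them (diffusion slows with density, and more so for
large molecules), what cytosolic volume occupancy ρ maximises flux — or, for
a self-replicating cell, growth rate?

## The model

Reactions follow irreversible Michaelis–Menten kinetics
`v = kcat [S][E] / (KM* + [S])` with a crowding-adjusted Michaelis parameter

```
KM* = KM0 · (Γ + θ e^{-gρ}) / ((1+θ) · Γ · e^{-gρ})
```

where `e^{-gρ}` is the size-dependent diffusion slowdown of the substrate
(`g(r)` from the empirical cytosolic scaling law with hydrodynamic radius
`r_h = 1.3(r + 0.14 nm)`), `Γ = γ_E γ_S / γ_ES` is the Gibbs
free-energy perturbation with hard-sphere activity coefficients from scaled
particle theory (verified in the test suite against Widom-insertion Monte
Carlo), and `θ` weights the diffusion (θ→0) versus transition-state (θ→∞)
limits. Because a reaction's own species are crowders, `KM*` and the bound
complex are solved self-consistently.

On this foundation the package builds:

* **pathway model** — an N-step linear (metabolic: r_s = 0.34 nm,
  r_E = 2.4 nm) or N-parallel (ribosomal: r_s = 2.4 nm, r_E = 13 nm)
  system; grid scans locate the occupancy maximising flux per unit dry mass.
* **whole-cell model** — a five-variable growth-balance model (transporter →
  N-step metabolism → ribosome) whose balanced growth rate
  `μ = v_R / (l_M[M] + l_R[R] + l_T[T])` is maximised at fixed occupancy by
  exact constraint elimination plus seeded multi-start search.
* **density conversion** — `ρ = ρ_DM / D(r)` with
  `D(r) = 1.35/(1+r) + 1.81 r/(1+r)` g/mL linking measured dry-mass density
  and RNA/protein ratio to occupancy.

## Worked example

```r
library(crowdcell)

## Where should a ribosome-dominated cytosol sit? Scan the 20-reaction
## parallel system on the reference grids (a second or two, vectorised C++).
rib <- scan_optimal_occupancy(pathway_params("ribosomal"), scan_grid())
rib$rho_opt
#> [1] 0.122

## The same scan for the metabolic (small-molecule) system peaks much higher:
met <- scan_optimal_occupancy(pathway_params("metabolic"), scan_grid())
met$rho_opt
#> [1] 0.297

## A self-replicating cell at fixed occupancy 0.22 (N = 150 enzymes,
## 1 uM external nutrient), growth maximised with 20 seeded restarts:
sol <- solve_at_occupancy(wholecell_params(N = 150, s_ext = 1), 0.22,
                          n_restarts = 20, seed = 1)
sol
#> Balanced-growth optimum at rho = 0.22: mu = 0.91086 1/h
round(derived_observables(sol), 3)
#>   volfrac_metab volfrac_ribo sat_M sat_R km_star_M km_star_R alloc_T alloc_M alloc_R
#> 1         0.503        0.497 0.966 0.799   158.458    533.97   0.028   0.865   0.107

## Convert a measured dry-mass density to occupancy:
occupancy_from_density(0.31, r = 0.086)
#> [1] 0.2235963
```

The pathway numbers say: a system built from ribosome-sized molecules works
best in a markedly more dilute cytosol (ρ ≈ 0.12) than one built from
metabolites and ordinary enzymes (ρ ≈ 0.30) — the size-dependence of
crowding costs is the mechanism behind growth-rate-dependent cytosolic
density. The whole-cell observables show the balanced allocation behind a
growth rate of 0.91/h: 86% of ribosome output goes into metabolic enzymes,
and the ribosome runs at ~80% saturation with its KM* inflated ~4.5-fold by
crowding.

A thin command-line wrapper over the same functions is installed at
`inst/cli/crowdcell.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","crowdcell.R",package="crowdcell"))') pathway-scan --preset ribosomal-pathway --out scan.csv`),
with subcommands `pathway-scan`, `wholecell-scan`, `wholecell-heatmap`,
`vazquez-scan`, and `convert-density`; outputs are CSV/JSON with a
provenance header (config hash, seed, package version).

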