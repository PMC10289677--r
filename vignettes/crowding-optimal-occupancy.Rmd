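---
title: "Crowding-adjusted kinetics and the optimal occupancy of a bacterial cytosol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding-adjusted kinetics and the optimal occupancy of a bacterial cytosol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcell)
```

## The scientific question

A bacterial cytosol is a dense suspension: roughly a fifth to a third of its
volume is occupied by dry mass. Higher density packs more catalysts and
substrates per volume — which should raise biochemical fluxes — but crowding
also slows diffusion and perturbs the Gibbs free energies of binding
equilibria. `crowdcell` implements a coarse-grained modelling framework in
which these opposing effects produce an interior optimum of the cytosolic
volume occupancy $\rho$ (the fraction of cytosolic volume occupied by dry
mass), and in which the location of that optimum depends on the size
distribution of the molecules doing the work: large ribosomes and tRNAs
favour a dilute cytosol, small metabolites and enzymes a dense one.

## Crowding-adjusted Michaelis–Menten kinetics

Every catalytic reaction is modelled as two consecutive sub-steps: (1) the
substrate and the catalyst diffuse until they meet, and (2) they bind and
unbind reversibly until the conversion proceeds. Both sub-steps respond to
crowding, and their combination yields an effective, crowding-adjusted
Michaelis parameter in the irreversible rate law
$v = k_\mathrm{cat}[S][E]/(K_M^* + [S])$:

$$K_M^* \;=\; K_M^0\,
  \frac{\Gamma + \theta\, e^{-g\rho}}{(1+\theta)\,\Gamma\, e^{-g\rho}} .$$

* $e^{-g\rho}$ is the diffusion slowdown of the substrate. The exponent
  $g(r_S)$ comes from an empirical scaling law for diffusion in the
  *E. coli* cytosol, normalised by the reference occupancy at which the law
  was calibrated ($\rho_\mathrm{ref} = 0.22$), and uses the hydrodynamic
  radius $r_h = 1.3\,(r + 0.14\,\mathrm{nm})$. Larger substrates are slowed
  more: $g(0.34\,\mathrm{nm}) \approx 5.06$ for a metabolite,
  $g(2.4\,\mathrm{nm}) \approx 12.2$ for a tRNA-sized molecule.
* $\Gamma = \gamma_E \gamma_S / \gamma_{ES}$ is the excluded-volume shift of
  the binding equilibrium. Activity coefficients $\gamma_i$ come from scaled
  particle theory (SPT) for hard-sphere mixtures, a closed form in the
  density moments $\langle\langle 1\rangle\rangle$,
  $\langle\langle r\rangle\rangle$, $\langle\langle S\rangle\rangle$,
  $\langle\langle V\rangle\rangle$ of the crowders. Because the
  catalyst–substrate complex is modelled as a sphere of the combined volume,
  it exposes less surface than its separated parts, so $\Gamma > 1$:
  crowding *favours* complex formation.
* $\theta$ weights the two sub-steps: $\theta = 0$ is the pure diffusion
  limit ($K_M^* = K_M^0 e^{g\rho}$), $\theta \to \infty$ the pure
  transition-state limit ($K_M^* = K_M^0/\Gamma$). The default
  $\theta = 2.3$ is the published estimate for a kinase phosphorylation
  reaction; a variant with $\theta = 4.6$ for metabolic reactions (small,
  fast-diffusing substrates) is provided.

Two points about this formula deserve comment, because the sources render it
ambiguously. First, the grouping adopted here is the unique parenthesisation
under which *all* stated limits hold simultaneously (the identity
$K_M^* = K_M^0$ at $\rho = 0,\ \Gamma = 1$; the two pure limits above; a
diffusion-only variant that increases with $\rho$; a transition-only variant
that decreases to the plateau $K_M^0/(1+\theta)$). Second, the higher-order
terms of the SPT expression were not transcribed but re-derived from the SPT
insertion work $W(R) = K_0 + K_1 R + K_2 R^2 + \tfrac{4\pi}{3}\beta P R^3$
with the scaled-particle mixture pressure; the resulting third-order term
$V_i \langle\langle r\rangle\rangle_2 \langle\langle S\rangle\rangle^2 /
\left(3(1-\langle\langle V\rangle\rangle)^3\right)$ is identically equal to
the pressure contribution because
$\langle\langle S\rangle\rangle = 4\pi \langle\langle r\rangle\rangle_2$.
The implementation is verified against an independent Widom particle
insertion Monte Carlo oracle in the test suite (agreement within the Monte
Carlo standard errors at occupancies 0.05–0.2).

Since a reaction's own substrate, catalyst and complex are crowders in their
own right, $K_M^*$ and the complex concentration are mutually dependent.
`solve_binding_equilibrium()` iterates the two relations — $K_M^*$ from the
current free/bound composition, then the complex reset to the exact solution
of $[ES] = [E_\mathrm{tot}][S_\mathrm{free}]/([S_\mathrm{free}] + K_M^*)$ —
until every $K_M^*$ changes by less than $10^{-5}$ relative (0.001%). Using
the closed-form complex update (instead of one substitution step) leaves the
fixed point unchanged, keeps mass conservation exact at every iteration, and
makes the binding contract hold exactly at convergence; the complex update is
damped by 0.5 if the $K_M^*$ iteration oscillates, and 500 iterations is the
cutoff (an error, not a warning).

What the crowding model deliberately ignores: effects of crowding on
$k_\mathrm{cat}$ (reactions are irreversible and protein folding and active
sites are assumed undisturbed), reversible kinetics, and virial-expansion
treatments of the interactions (superseded by the SPT closed form). The
surface-distance parameter $\xi = 0.51$ nm is treated as a constant even
though it weakly depends on $\rho$; the model is intended for occupancies
near the native range, and $e^{-g\rho}$ is known to break down as
$\rho \to 1$.

## The pathway model

`pathway_params()` builds an $N$-step pathway of identical reactions
($k_\mathrm{cat} = 1\,\mathrm{s}^{-1}$ as a pure scale, $K_M^0 = 130$ µM,
$\theta = 2.3$, $N = 20$): a linear chain for the *metabolic* preset
(substrates $r = 0.34$ nm, enzymes $r = 2.4$ nm) or $N$ parallel reactions
for the *ribosomal* preset (tRNA-like substrates $r = 2.4$ nm, ribosomes
$r = 13$ nm; the parallel specific flux is $N$ times the linear one). The
occupancy is $\rho = N_A \tfrac{4\pi}{3}([s] r_s^3 + [E] r_E^3)$, the
pathway flux per volume is $v = (k_\mathrm{cat}/N)\,[s][E]/(N K_M^* + [s])$
with the self-consistent $K_M^*$, and the growth proxy is the flux per unit
dry mass $\mu = v/\rho$. Dilution of intermediates is ignored in this module.

`scan_optimal_occupancy()` scans $\rho$ (0.01–0.80 in steps of 0.01, refined
to 0.001 steps in [0.100, 0.360]) and the substrate share of occupied volume
(geometric grid from 0.1% to 97.7%, factor 1.0023 per step — both grids as
in the reference protocol). A grid point $(\rho, f)$ maps to concentrations
by giving the substrates the fraction $f$ of the occupied volume; the share
is read as a fraction of *occupied* volume, not of total volume. For each
$\rho$ the objective is maximised over the share (the envelope); flux curves
use the same envelope convention (the flux maximised over composition per
$\rho$), with ties broken toward the smaller $\rho$ within $10^{-12}$
relative. Non-converged grid points are excluded from envelopes with a
warning.

```{r pathway, eval = FALSE}
sc <- scan_optimal_occupancy(pathway_params("ribosomal"), scan_grid())
sc$rho_opt     # 0.122: large molecules favour a dilute cytosol
```

With these defaults the metabolic optimum lands at $\rho \approx 0.30$ and
the ribosomal optimum at $\rho \approx 0.12$; the ribosomal *total* flux
peaks near $\rho \approx 0.21$. Halving the occupancy from its optimum costs
the ribosomal system about 21% of its specific flux but the metabolic system
only about 1.3% — the penalty grows with $N$ while the optimum location
barely moves. `vazquez_flux()` provides the older two-regime treatment
(saturated reactions sped up by $1/(1-\rho)$, diffusion-limited ones
additionally slowed by $e^{-5.8\rho}$) as an alternative backend for the
same scans.

## The whole-cell model

`wholecell_params()` assembles a five-variable self-replicating cell:
transporter $T$ (conventional kinetics,
$k_{\mathrm{cat}T} = 13.7\,\mathrm{s}^{-1}$, $K_{MT} = 1$ µM; membrane-bound,
so excluded from cytosolic crowding and from $\rho$), an $N$-step metabolic
pathway ($k_{\mathrm{cat}M} = 13.7\,\mathrm{s}^{-1}$, $K^0_{MM} = 130$ µM)
lumped into one reaction with scaling $k_{\mathrm{cat}M}/N$ and
$N K^*_{MM}$, and a ribosome
($k_{\mathrm{cat}R} = 22\,\mathrm{s}^{-1}$, $K^0_{MR} = 120$ µM) that
polymerises the precursor $p$ into the three protein types at costs
$l_T = l_M = 300$ and $l_R = 7459$ precursors. The growth rate is
$\mu = v_R / (l_M[M] + l_R[R] + l_T[T])$, reported in h$^{-1}$; balanced
growth requires $v_T - v_M - \mu[s] = 0$ and $v_M - v_R - \mu[p] = 0$. The
free tRNA pool is not modelled and the precursor reactions do not conserve
volume, following the source model's bookkeeping. Internally all
concentrations are number densities (molecules/nm³; 1 µM =
$6.022\times10^{-7}$ nm$^{-3}$), which absorbs the Avogadro factors of the
printed occupancy and growth-rate formulas; the interface speaks µM and
h$^{-1}$.

`solve_at_occupancy()` maximises $\mu$ subject to the two balances and
$\rho(\text{state}) = \rho_\mathrm{target}$ (an equality, matching the
"constrained at different occupancies" protocol). Rather than penalising the
constraints inside a generic SQP solver, the implementation eliminates them
exactly, which is the design choice that guarantees the $10^{-9}$
feasibility contract by construction:

* $[R]$ from the occupancy equality (linear, by volume additivity of the
  complexes);
* $[T]$ from the substrate balance — since $T$ neither crowds nor occupies
  cytosolic volume, this is a closed-form quadratic;
* $[p]$ from the precursor balance by bracketed root finding on a
  logarithmic grid (28 points) with Illinois refinement; when two balanced
  solutions exist, the higher-$\mu$ branch is kept;
* the remaining two degrees of freedom — the volume shares of $s$ and $M$ —
  are optimised by Nelder–Mead in softmax coordinates (every iterate is
  automatically inside the occupancy constraint), multi-started from the
  optimum of the crowding-unaware model, perturbations of it, and random
  log-uniform points on the share simplex (20 restarts by default, seeded
  and reproducible; occupancy scans additionally warm-start each grid point
  from its neighbour's optimum).

The coupled binding equilibria of the metabolic and ribosomal reactions
share one crowding background — free $s$, free $M$, the $Ms$ complex, free
$p$, free $R$, the $Rp$ complex — and both reactions see the total occupied
fraction of that mixture in their diffusion factors (by volume additivity it
equals the constrained $\rho$, so $e^{-g\rho}$ is constant within a solve).
Gradient-free local search was chosen over finite-difference SQP because the
nested fixed point makes objective evaluations mildly noisy at the $10^{-8}$
level; the hot kernels are implemented in C++ (Rcpp) and the R-level
functions are thin wrappers over the same code paths, cross-checked in the
tests.

Scans over $\rho$ (`optimal_occupancy()`) and over $(N, s_\mathrm{ext})$
(`heatmap_scan()`) reproduce the qualitative physiology: the optimum rises
with pathway length $N$ and falls with nutrient concentration
$s_\mathrm{ext}$; removing the crowding terms removes the interior optimum
entirely; the ribosomal $K_M^*$ at the optimum tracks the optimal occupancy
closely while the metabolic $K_M^*$ barely moves.

### Problem sizes and known limitations

The default scan protocol evaluates ~0.9 million pathway grid points
(seconds, vectorised in C++) and, for each whole-cell configuration, ~180
occupancy points with 20 restarts each (about a minute per configuration).
The acceptance script uses a 0.002 occupancy step in the refined window
[0.10, 0.36]; the package default keeps the 0.001 step.

The main known limitation concerns the *absolute* location of the
whole-cell optimum. The growth-rate curve $\mu(\rho)$ is extraordinarily
flat: in this implementation $\mu$ at $\rho = 0.25$ is within 0.4% of
$\mu$ at $\rho = 0.20$ for $N = 250$, $s_\mathrm{ext} = 0.1$ µM, and the
published sensitivity figures (a ~1% loss for halving $\rho$) show the same
flatness. On such a curve the argmax is decided by sub-percent systematic
terms. This implementation, built strictly from the printed equations and
constants, places the whole-cell optima at $\rho_\mathrm{opt} \approx$
0.168–0.200 across the reference conditions, below the published
0.204–0.250, while reproducing the pathway-model optima, all monotone
trends, the saturation levels, and the relative $\mu$ losses at half/double
occupancy to within a fraction of a percentage point. Alternative
conventions for the crowding background, the dilution terms, the diffusion
occupancy, concentration bounds, and complex-volume bookkeeping were each
implemented and scanned during development; none reconciles the absolute
optima without contradicting a printed equation or degrading the trends, so
the faithful reading is retained. Conclusions that depend on *where exactly*
the flat optimum sits should therefore be drawn with corresponding caution;
conclusions about trends, sensitivities and mechanism are robust to it.

The same flatness affects the pathway model's $\theta = 4.6$ metabolic
variant: doubling $\theta$ changes the attainable maximum by under 1% but
can move the argmax along the plateau by up to ~0.05.

## Density conversions

The link to experiment: occupancy is dry-mass density divided by the
specific density of dry mass, $\rho = \rho_\mathrm{DM}/D(r)$, where
$D(r) = 1.35/(1+r) + 1.81\,r/(1+r)$ g/mL interpolates between protein
(1.35 g/mL) and RNA according to the RNA/protein mass ratio $r$. The RNA
specific density 1.81 g/mL is derived from the 70S ribosome (1.637 g/mL,
61.87% RNA by mass) by mass-fraction-weighted linear mixing — the mixing
rule that reproduces the published value. $r$ itself comes from the growth
law $r = 0.087 + \mu/4.5\,\mathrm{h}^{-1}$ or from user-supplied $(\mu, r)$
measurements with linear interpolation (`rna_protein_ratio()`); measured
tables are deliberately not bundled. Note that published conversions of this
kind round $D$ to three figures before dividing, which can move the third
decimal of $\rho$ (0.31/1.39 = 0.223 vs the unrounded 0.224); this package
never rounds intermediates.

```{r density}
occupancy_from_density(0.31, r = 0.086)   # slow growth, minimal medium
occupancy_from_density(0.28, r = 0.33)    # fast growth, rich medium
```

## What the tests do and do not show

The test suite verifies the SPT activity coefficients against Widom
insertion Monte Carlo (an independent thermodynamic oracle), all limiting
identities of $K_M^*$, mass conservation and fixed-point contracts of the
binding solver, the crowding-free Michaelis–Menten limits, feasibility of
every reported whole-cell solution to $10^{-9}$ relative, seed robustness of
the multi-start optimiser, and the reproduction of the published pathway
optima and density conversions. All model molecules are hard spheres with
two sizes per sector and identical kinetics within a pathway; real cytosols
have broad size distributions, soft interactions, and heterogeneous
kinetics. Passing tests therefore validate the implementation of this
coarse-grained model, not the model's fidelity to any particular organism.
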