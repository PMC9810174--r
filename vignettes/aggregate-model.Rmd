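---
title: "Modelling spatial self-organisation of microbial aggregates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial self-organisation of microbial aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggresim)
```

## The model

`aggresim` simulates the maturation of a two-dimensional microbial
aggregate as an individual-based model coupled to a reaction–diffusion
field. Three populations, B1, B2 and B3, share identical kinetic
parameters ("theoretical equal fitness") and differ only in their signed
metabolic stoichiometries, which define the community's ecological
interaction structure:

* **neutralism** `[0,0,0]` — each population consumes its own substrate
  (A, B or C) and produces a common product D;
* **competition** `[-,-,-]` — all three consume substrate A;
* **commensalism** `[0,+,+]` — a metabolic chain A → B → C → D in which
  each population feeds on its predecessor's product;
* **commensalism + competition** — the chain plus shared consumption of
  oxygen, so whichever substrate is most limiting decides the realised
  interaction.

Each cell is a disc-shaped agent with a position, a mass and an activity
state. Its actual growth rate is multiplicative Monod kinetics over its
consumed substrates minus a maintenance coefficient,

$$\mu = \mu_{max}\prod_s \frac{\phi_s}{K_S + \phi_s}
        \prod_i \frac{K_I}{K_I + \phi_i} - b,$$

evaluated at the concentrations of the grid node containing the cell
centre. Mass integrates by forward Euler, radius follows from a fixed
cell density assuming spherical shape, and a cell at the division mass
splits into a daughter carrying a stochastic fraction
$\alpha \sim U(0.45, 0.55)$ of its mass, placed adjacent to the parent at
a random angle. Cells that shrink to the dormancy threshold become
inactive — they neither grow, decay, nor react — and reactivate when local
conditions would again support positive growth. Overlapping cells shove
one another apart (hard-sphere relaxation); cells beyond a configurable
maximum radius can be removed to represent shear detachment.

Soluble substrates obey a diffusion–reaction equation on a uniform grid
partitioned into the aggregate, a diffusive boundary layer, and bulk
liquid pinned at fixed concentrations (Dirichlet). Because diffusion
equilibrates orders of magnitude faster than growth, each biological step
first relaxes the fields to a pseudo-steady state: on every
diffusion-region node the discrete residual
$(\sum_{nb}\phi - 4\phi) + (h^2/D)\,R(\phi)$ must fall below 1% of the
local concentration, or below an absolute floor of $10^{-6}$ mol/L where
concentrations are tiny. The reaction term sums
$\mathrm{stoich} \cdot \mu^+ X / V$ over the cells of each node; decaying
cells neither consume nor release solutes (no lysis products are
modelled).

## Readout statistics

* **Relative abundance** of active cells, and the **fitness median** (the
  median actual growth rate over a population's active cells).
* **Colony sections**: angular bins about the aggregate centre are
  labelled by their radially outermost active cell; contiguous runs form
  sections with perimeter $P_c = 2\pi\langle r\rangle\,\theta/360$ and
  relative size $P_c / (2\pi R)$.
* The **biological Thiele modulus**
  $\phi_{Bio} = R\,q_S X / (D_S C_S)$ compares characteristic diffusion
  and Monod reaction times, and the **eco-interaction modulus**
  $\phi_{EI} = [(n_A q_A)/(D_A C_A)]\,/\,[(n_{O2} q_{O2})/(D_{O2} C_{O2})]$
  compares the limitation pressure of the commensal substrate A against
  the shared substrate O2: values above 1 predict a commensal, layered
  environment; below 1 a competitive, columned one.
* **Stratification indices**: the layering index is the rank correlation
  between chain order and median radial position of active cells (−1 =
  perfectly layered); the segregation index is one minus the mean
  normalised Shannon entropy of composition over angular bins in the
  outer shell (1 = pie-sector columns, 0 = well mixed).
* The **statistical suite** applies Welch's unequal-variance test to
  abundances across groups, the paired t-test to fitness between
  populations within the same simulations, and Pearson's correlation to
  abundance–fitness pairs.

## Parameters and units

Lengths are in micrometres, time in hours, cell mass in moles of biomass
and concentrations in mol/L; diffusivities are accepted in m²/h and
converted internally. The substrate diffusivity is 3.6×10⁻⁶ m²/h for the
organic substrates and 7.2×10⁻⁶ m²/h for oxygen. Oxygen bulk levels are
given in mg/L and converted with a molar mass of 32 g/mol; the mixed
preset's oxygen coefficient is the catabolic demand
$(1-Y_{XS})/Y_{XS}$ mol O₂ per mol biomass, from an electron balance
(only the substrate fraction not fixed into biomass is oxidised).

The source study does not publish its kinetic table, so the remaining
defaults are this package's own stand-ins, chosen once from a scale
analysis so that the qualitative regimes of the study appear at "desk
scale" (aggregates of 30–110 µm simulated for about six days on one CPU):

| parameter | default | rationale |
|---|---|---|
| $\mu_{max}$ | 0.1 h⁻¹ | day-scale maturation; ~10 generations over a run |
| $K_S$ (A–D) | 0.01 mM | keeps chain intermediates (µM scale) usable by successors |
| $K_S$ (O₂) | 0.5 mg/L | well below the 1–14 mg/L experimental window |
| $b$ | 0.01 h⁻¹ | 10% of $\mu_{max}$ |
| $Y_{XS}$ | 0.5 mol/mol | generic growth yield |
| $\rho$ | 9.55×10⁻¹⁵ mol/µm³ | ≈0.23 g dry weight/cm³ |
| $M_{max}$ | 1.35×10⁻¹³ mol | division diameter 3 µm |
| $M_{min}$ | 0.3 $M_{max}$ | dormancy within days of starvation, below any birth mass |
| boundary layer | 20 µm | finite external mass-transfer resistance |

The scale analysis: with volumetric biomass density $X_v \approx 13$
mol/L inside the aggregate, the centre-to-rim concentration deficit is
$\approx q_v R^2 / 4D$ with $q_v = (1/Y)\mu X_v$. At these defaults the
deficit reaches the 0.05–1 mM experimental window for radii of tens of
micrometres, so substrate limitation — the driver of all the spatial
patterns — develops within desk-scale runs. A lower $\mu_{max}$ or
density would push the limited regime beyond reachable aggregate sizes.

Desk-scale study conditions (the package defaults): a 91×91 grid at
h = 2.5 µm, a 20 µm premature-aggregate inoculum of 24 cells (one third
per population, masses uniform in $[M_{min}, M_{max})$), a 144 h horizon
with snapshots every 12 h, and early termination when the community is
steady (every population's active abundance, every bulk value and every
fitness median changing by less than 5% over a trailing 36 h window) or
when the aggregate reaches the grid limit.

## Numerical choices

* **Pseudo-steady solver.** The default strategy linearises each
  substrate's Monod uptake about the current field and solves the
  resulting sparse symmetric system directly (cached Cholesky
  factorisations), sweeping substrates in chain order until both the
  residual rule above and a Picard self-consistency criterion (maximum
  relative field change below 1%) hold; the self-consistency requirement
  lets trace-level chain products propagate even where the absolute
  residual floor is already met. A damped Jacobi relaxation with periodic
  reaction refreshes (every 10 inner iterations) is available as an
  alternative strategy and is tested against the same residual rule and
  against a dense direct solve.
* **Node ownership** is half-open, $[x_i, x_i + h)$: a cell on a node
  edge belongs to exactly one node.
* **Adaptive biological step**: $dt_{bac} = \min(1\,h,\,0.05/\max|\mu|)$,
  so no cell changes mass by more than 5% per step; divisions are checked
  every 3 h.
* **Shoving** runs after every growth step, not only after divisions. A
  packed disc (coverage above ~55%) is first expanded affinely about the
  biomass centroid by the area-growth factor; pairwise Gauss–Seidel
  sweeps (compiled code, uniform-grid hashing) then resolve the remaining
  local overlaps, with a 5% accepted overlap fraction and a deterministic
  golden-angle rule for exactly coincident centres. Without the affine
  step, pairwise relaxation propagates collective expansion only one
  cell layer per sweep and stalls at the iteration cap.
* **Determinism.** All randomness (inoculum, division fractions and
  angles) derives from the configuration seed; runs are bit-reproducible.

## What the synthetic runs do and do not show

The generator emulates the study conditions — random premature
aggregates, equal-fitness populations, fixed bulk concentrations — not
real organisms: there is no lysis, no EPS, no motility, no 3D geometry,
and the kinetic stand-ins above replace unpublished values. Passing
tests therefore demonstrate that the mechanisms (diffusion-limited
growth, shoving, detachment, the moduli) reproduce the study's
qualitative structure at reduced scale, not that any real community is
calibrated.

Two desk-scale limitations are worth stating plainly, because the test
suite reports them honestly as failures rather than hiding them:

* **Fitness medians compress.** In the source study's long steady states,
  starved interior cells have become inactive, so each population's
  fitness median reflects its growing band and orders as
  F(B1) > F(B2) > F(B3) under commensalism. With the net-rate reaction
  term used here, starved interiors self-regulate at $\mu \approx 0$ and
  remain active for longer than a desk-scale run, dragging the medians of
  interior-heavy populations toward zero. The abundance hierarchy and the
  layered geometry reproduce well; the commensalism abundance–fitness
  correlation and the fitness ordering do not, within this horizon. (A
  maintenance-driven gross-uptake variant retires interiors but erodes
  the chain ratios instead; the net-rate formulation was kept.)
* **Small capped communities drift.** With the 30 µm detachment cap the
  whole aggregate holds only a few hundred cells, and competitive
  exclusion by drift can fix one population, leaving the segregation
  index undefined for that replicate.

## A worked run

```{r example, eval = FALSE}
eco <- build_ecology_preset("commensalism", c(A = 1e-4))
cfg <- simulation_config(eco, seed = 1)
traj <- run_simulation(cfg)
snap <- get_snapshot(traj)
relative_abundance(snap)
stratification_indices(snap)
plot(traj, type = "abundance")
plot(snap)
```

The acceptance script (`scripts/acceptance.R`) reruns the four
simulation sets from scratch with seeded replicates and writes the
summary quantities as JSON; see the README for how to invoke it.
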