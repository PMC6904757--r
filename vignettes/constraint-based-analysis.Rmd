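---
title: "Constraint-based analysis with megaflux: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis with megaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megaflux)
```

# The model and its assumptions

A genome-scale metabolic model is a stoichiometric network: metabolites
indexed by i, reactions indexed by j, and a matrix S whose entry S_ij is
the signed coefficient of metabolite i in reaction j. Flux balance
analysis (FBA) rests on two assumptions:

* **Steady state.** Over the time scale of balanced growth, intracellular
  metabolite pools neither accumulate nor deplete: `S v = 0` for the flux
  vector v.
* **An evolutionary objective.** The cell allocates flux to maximise a
  linear objective `Z = c'v`, in practice the flux through a biomass
  pseudo-reaction that drains precursors in cell-dry-weight proportions,
  so `Z` approximates the specific growth rate in 1/h.

Fluxes are bounded, `lb <= v <= ub`, and the bounds carry all the
environmental and genetic information: a medium is a set of exchange-flux
lower bounds, a knockout is a pair of zero bounds. Exchange reactions
follow the standard sign convention — negative flux is uptake, positive is
secretion — so a medium entry `u` (a non-negative magnitude in mmol/gDW/h)
becomes a lower bound of `-u`. One refinement of the single-metabolite
rule for recognising exchanges: a reaction with nonzero objective weight
is never classified as an exchange, because in small didactic networks the
biomass drain touches a single precursor and must not be closed by
`apply_medium()`.

FBA cannot see kinetics, regulation or thermodynamic infeasibility
(loop-law violations); those are out of scope here, as is any
mixed-integer extension.

# Parameters that matter

| Parameter | Where | Default | Units | Why |
|---|---|---|---|---|
| `fraction` | `fva()`, `min_total_flux()`, `production_capacity()` | 0.9 for suboptimal analyses, 1 otherwise | — | a 10% tolerance on the optimum is the conventional "suboptimal" setting when confronting measured fluxes; 1 pins the optimum |
| `uptake_bound` | `screen_carbon_sources()` | 5 | mmol/gDW/h | the conventional single-source test bound; medium salts are effectively unbounded (1000) |
| `growth_threshold` | `screen_carbon_sources()` | 1e-6 | 1/h | LP round-off must not count as growth |
| default bounds | readers, generators | (-1000, 1000) reversible, (0, 1000) irreversible | mmol/gDW/h | the field's "effectively unbounded" convention |
| `carbon_basis` | `flux_sum_profile()` | 1 | mmol carbon/gDW/h | puts molecules of different size on an equal-carbon footing (glucose: 1/6, glycerol: 1/3, ...) |
| `tol` | `interval_contains()`, FVA flags | 1e-6 | flux units | matches the solver's reported-equality tolerance |

# The LP core

Every analysis reduces to linear programs over the flux polytope. The
package ships its own LP solver (`R/lp-solver.R`): a two-phase dense
tableau simplex using Bland's smallest-index rule for both the entering
and the leaving variable. Bland's rule guarantees finite termination, which
matters because FBA instances are extremely degenerate — knocked-out
reactions contribute fixed-at-zero variables, empty media close whole rows,
and alternate optima are the norm rather than the exception. Problems are
shifted to non-negative variables (`x = v - lb`), upper bounds become
inequality rows, and feasibility is established in phase 1 through
artificial variables.

Numerical choices:

* pivot tolerance 1e-9; phase-1 infeasibility is declared above 1e-7;
  reported equalities (steady state, objective floors) are checked at 1e-6;
* solutions are clipped back into the box bounds to absorb last-digit
  round-off;
* model validation requires finite bounds, so "unbounded" cannot occur for
  a validated model; the status is kept in the API for completeness.
* at most `50 (m + n) + 1000` pivots; in practice the fixtures solve in a
  handful.

The test suite cross-checks the solver against an independent brute-force
oracle (`brute_force_lp_oracle()`) that enumerates candidate vertices of
the polytope — every subset of `n - rank(S)` fluxes pinned to a bound, the
remaining square steady-state system solved exactly — on networks of up to
8 reactions. Agreement is at 1e-6 across 50+ seeded random networks per
run.

Alternate optima deserve one more note: `solve_fba()` returns whichever
optimal vertex the pivoting path reaches (deterministically, given the
model). Whenever a *distribution* matters downstream — flux-sum turnover in
particular — the package uses `min_total_flux()`, which minimises
`sum |v_j|` at the objective floor via the standard `v = p - q` split.
This is what suppresses futile cycles: a cycle adds `|v|` without changing
anything else, so the minimiser zeroes it.

# What the synthetic generators emulate

The package treats its synthetic data as first-class study material:

* `make_toy_core()` / `make_branched_toy()` are fixed four- and
  six-reaction networks whose optima are solved by hand in their
  documentation (growth 20 at uptake 10; divertible product `10 (1 - f)`
  at growth floor `f`). They exercise GPR gating (an isozyme `or`, a
  complex `and`), media, knockouts and the two-stage production protocol.
* `random_viable_network(n_m, n_r, seed)` plants a strictly positive flux
  vector first and balances every random stoichiometric column against it,
  so `S v = 0` holds by construction and the planted objective value
  certifies a feasible lower bound for the LP — feasibility is guaranteed,
  not rejection-sampled, at any size. Generators take mandatory seeds and
  restore the session RNG state, so the suite is bit-reproducible.
* `simulate_batch()` is the closed form of exponential growth at constant
  specific rate and constant biomass-specific uptake:
  `x(t) = x0 e^{mu t}`, `C_{i+1} = C_i + v x_i (e^{mu dt} - 1)/mu`. The
  interval estimators invert it exactly (to ~1e-12), which is the point:
  they are tested as an exact inverse pair, not against noisy data.
* `make_detox_toy()` / `make_assimilating_toy()` realise the two regimes a
  forced-uptake dose scan can reveal — disposal at no metabolic cost
  (flat biomass) versus co-metabolism (biomass rising with dose) — plus a
  capacity-limited variant where excessive doses are infeasible.

What passing on these fixtures does **not** show: real phenotype data are
noisy and condition-dependent, real media are ill-characterised, real
models contain blocked reactions, mass imbalances and GPR errors, and real
batch cultures deviate from constant-`mu` exponential growth. The fixtures
validate the mathematics and the plumbing, not the biology of any
particular reconstruction. Genome-scale claims (reaction/metabolite/gene
counts, the five-condition chemostat correlation) are therefore tested
directly against the published supplementary SBML file when it is present,
and those tests fail loudly rather than pass vacuously when it is not.

# Design choices where the design was open

* **Knockout scope.** A gene deletion closes every reaction whose GPR
  evaluates inactive — including reactions gated by complexes that merely
  contain the gene. This is the only reading implementable from the rules
  alone; closing a single named reaction is available separately as
  `knockout_reactions()`.
* **Bounds are closed, reactions never deleted**, so one model object
  supports repeated what-if queries without rebuilding indices.
* **Hypothetical transporters are per-run scoped.** In a screen, the
  transporter added for a transporter-less source exists only in that
  source's simulation and the call is flagged, so one interim hypothesis
  cannot contaminate the other sources' calls.
* **Forced uptake in dose scans pins both bounds.** With only a lower
  bound, an optimiser facing a harmful compound would simply not take it
  up and every curve would be flat; an obligatory flux is the only way a
  toxicity scan can bite.
* **Acetate alongside glucose.** The bundled chemostat conditions table
  carries both glucose and acetate uptake columns and both are applied as
  uptake bounds, following the measurements as tabulated.
* **`mu -> 0` limit.** The uptake estimator has a removable singularity at
  `mu = 0`; below `|mu| < 1e-9` the analytic limit `dC/(x dt)` is used.
* **Through-origin fit.** Slope from `lm(y ~ 0 + x)`; R and its two-sided
  p-value are the ordinary Pearson quantities (`cor.test`), with the
  degenerate `|R| = 1` case mapped to p = 0. Forcing the intercept to zero
  answers "is prediction proportional to observation", which is the right
  question for rates that must vanish together.
* **SBML dialect.** Canonical output is Level 3 + FBC v2 with bounds as
  shared parameters; the reader additionally accepts numeric per-reaction
  bound attributes and falls back to the reversibility flag with the
  conventional defaults. Kinetic-law bound encodings are rejected with an
  explicit error, and the detected dialect is logged. Bracketed
  compartment suffixes (`G6P[c]`) are split into the compartment field
  with a `_c` id qualifier to preserve uniqueness.

# Problem sizes

The shipped analyses and checks run on networks of 3-8 reactions, 50
random networks per property sweep, 11-point dose grids and 13-point batch
time courses — sizes chosen so each documented value can be verified by
hand or by exhaustive enumeration, which is what these fixtures are for.
The dense simplex handles hundreds of reactions comfortably; genome-scale
models (~1700 reactions) load and validate through the same interfaces,
though whole-model FVA at that scale is better scheduled than interactive.

# Known limitations

* No loopless FVA, flux sampling, MILP-based gap-filling or strain-design
  algorithms.
* The dense tableau is O(rows x columns) per pivot; it favours robustness
  and auditability over genome-scale FVA throughput.
* The SBML subset is the constraint-based core (species, reactions,
  bounds, objective, gene associations, formulas); units, annotations and
  SBO terms beyond bound parameters are not round-tripped.
* Flux-sum profiles depend on the chosen parsimonious distribution; where
  alternate minimal-total-flux optima exist, per-metabolite values can in
  principle differ between equally parsimonious solutions.
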