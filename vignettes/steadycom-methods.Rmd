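---
title: "Community steady-state metabolic modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community steady-state metabolic modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadycom)
```

## The model

A community model couples `K` genome-scale (or toy) organism models through
a shared *community space*.  Organism `k` contributes its stoichiometric
matrix `S^k`, flux bounds `LB^k_j <= v^k_j <= UB^k_j` (mmol/gdw/h; the
biomass reaction in 1/h), a biomass reaction, and exchange reactions that
move extracellular metabolites between the organism and the community pool.
Our sign convention, declared once and used everywhere: **positive exchange
flux exports to the community space, negative flux is uptake** — the common
SBML convention.

The community steady-state assumption is that the composition of the
community is constant on time average, which (with equal dilution of all
members) forces one common specific growth rate `mu` on every member.  A
non-growing member cannot keep feeding a growing one, because its relative
biomass — and with it every flux it can carry — decays.  To express this
linearly each organism gets an explicit biomass variable `X^k` (gdw), and
fluxes are modelled as *aggregate* fluxes `V^k_j = X^k v^k_j` (mmol/h).
The constraints are: internal steady state `sum_j S^k_ij V^k_j = 0`;
capacity `LB^k_j X^k <= V^k_j <= UB^k_j X^k`; growth coupling
`V^k_biomass = mu X^k`; the community balance
`u^c_i - e^c_i + sum_k V^k_ex(i) = 0` with bounded uptake `u^c_i` and free
export `e^c_i >= 0`; and a fixed total biomass `sum_k X^k = X0`.  With
`X0 = 1` gdw (the default) the `X^k` read directly as relative abundances.
The capacity rows make `X^k = 0` force `V^k_j = 0` — the property joint FBA
lacks.

Two design details deserve attention:

* **Reversible reactions.**  Each finite bound contributes its own
  one-sided row (`V - UB*X <= 0`, `V - LB*X >= 0`), so both flux directions
  scale with abundance and the zero-abundance coupling holds for reversible
  fluxes too.
* **Infinite bounds.**  A row for `UB = +Inf` (or `LB = -Inf`) is omitted
  rather than encoded with a large constant, avoiding big-M artifacts.  The
  flip side is that a reaction with a genuinely infinite bound is *not*
  forced to zero at zero abundance.  The bundled fixtures therefore use the
  field's conventional finite default bound of 1000 on internal reactions;
  users importing SBML models get whatever bounds the file declares.

Per-organism uptake limits (e.g. a maximum specific fiber uptake rate) are
not part of the stoichiometric model; they are imposed as rows
`V^k_ex(i) + r X^k >= 0`, i.e. a cap `r` on the specific uptake rate that
scales with abundance.  The literature states that such organism-specific
constraints can be imposed without fixing their algebraic form; this
abundance-scaled form is our choice because it is the only linear form
consistent with the capacity rows above.

## Finding the maximal growth rate

At fixed `mu` the problem is an LP.  `max_total_biomass()` solves it with
the total-biomass row replaced by the objective `max X_T = sum_k X^k`;
`X_T(mu)` is non-increasing, and `X_T(mu) >= X0` holds iff growth rate `mu`
is attainable with total biomass `X0`.  `steadycom()` searches for
`mu_max = sup { mu : X_T(mu) >= X0 }`:

1. *Screen.*  One LP at `mu = mu_tol` decides zero-growth communities
   (`X_T < X0` there); one more LP at `mu = 0` with `sum X = X0` separates
   `zero_growth` (feasible at rest) from `infeasible` (maintenance demands
   unsatisfiable under the given uptake bounds).
2. *Expansion.*  From `mu_guess` (default 0.1/h, inside the 0.02–0.25/h
   range reported for intestinal microbes) the rate grows — by the
   fixed-point guess `mu * X_T(mu)/X0`, by a secant step, or by the factor
   `bracket_growth_factor` — until an infeasible rate brackets the optimum.
3. *Refinement.*  Secant steps on `z(mu) = 1/X_T(mu)` toward `z = 1/X0`,
   clamped to the bracket interior, with plain bisection whenever the
   interpolant is uninformative (flat or out of bracket) and a
   "probe-once" rule when the interpolant lands on the feasible edge:
   the next LP is placed `mu_tol` above it, which either certifies
   convergence or falls back to bisection.  The bracket shrinks to below
   `mu_tol` (default 1e-6/h) and the feasible end is reported.

The choice of `1/X_T` is what makes the search fast: for a community
limited by a single scalable resource, `X_T(mu) = c/mu`, so `z` is exactly
linear in `mu` and one bracketed secant step lands on `mu_max`.  On all
bundled fixtures — from one to sixteen organisms — the whole search takes 4–6
LPs, and the count does not grow with the number of organisms because only
the LP size, not the number of iterations, depends on `K`.

Abundances at `mu_max` are often degenerate (many compositions attain the
same rate).  The reported values come from one final LP with the total
biomass fixed and **total community uptake minimized** as a deterministic
tie-break, making output reproducible across solvers; the honest answer to
"how variable is the composition?" is `abundance_fva()`, never the single
reported vertex.

### Numerical choices

* `mu_tol = 1e-6` (bracket width), `feas_tol = 1e-9` (slack in the
  `X_T >= X0` test).  The feasibility slack translates into a relative
  error of about `feas_tol * mu_max` in the reported rate; analyses that
  need tighter agreement (e.g. the single-organism reduction check, which
  verifies equality with plain FBA to 1e-9) pass
  `steadycom_options(mu_tol = 1e-9, feas_tol = 1e-12)`.
* LPs are solved with GLPK's simplex.  A hard iteration cap (200k pivots)
  guards against cycling on degenerate problems — observed in practice on
  randomized uptake-bound sets — after which the solve is retried from a
  fresh basis with the presolver and dual simplex.
* The max-biomass LP becomes ill-scaled as `mu -> 0` (the growth-row
  coefficient falls below pivot tolerances while `X_T ~ 1/mu` explodes); a
  numerically "unbounded" verdict at the screening rate is therefore read
  as "feasible here".  A model that is *structurally* unbounded — a
  growth-limiting resource without any uptake bound — still raises an
  error, because the same verdict recurs at the ordinary rates probed next.
* `zero_tol = 1e-8` gdw declares an organism absent in
  `specific_fluxes()`; below that scale a reported biomass is LP noise.

## Variability and pairwise analyses

`steadycom_fva()` fixes `mu = mu0`, restores `sum X = X0`, and
minimizes/maximizes arbitrary weighted sums of aggregate fluxes and
abundances; unbounded directions are reported as infinite.  Ranges at a
higher growth fraction are nested inside ranges at a lower one (the
feasible set only shrinks), which the tests verify empirically per fixture.

`pairwise_fva()` fixes one organism's abundance at each point of a grid
(default: 30 log-spaced values from `1e-3 * X0` to `X0`, matching the span
used in published pairwise scans) and records the feasible range of a
second organism.  A scan is *competitive* when the dependent maximum never
increases along the grid, and *conditionally mutualistic* when a region of
positive slope exists; slopes are compared against `1e-6 * X0` so LP
degeneracy noise cannot flip the call.  On the obligate four-member ring
the mutualistic pattern is cleanest at intermediate growth fractions
(the tests scan at `0.5 * mu_max`): close to `mu_max` the binding
production capacities narrow the feasible composition band to a few grid
points, which is itself the essentiality signature seen in the abundance
ranges.

## Synthetic communities

The generators produce the study conditions for all tests; their defaults
are fixed once and documented here.  Units are abstract (yields of 1
gdw/mmol, bounds of 1000), because the fixtures target LP correctness, not
physiology.

* `make_single_organism_toy(uptake = 10, yield = 1)` — closed form
  `mu_max = uptake * yield / X0`; oracle for the search and the FBA
  reduction.
* `make_atpm_toy(n = 2, atpm_lb = 1, uptake = 4)` — `n` identical members
  with an ATP maintenance floor.  Closed forms
  `mu_max = uptake/X0 - atpm_lb` (maintenance scales with biomass) versus
  joint-FBA total `uptake - n * atpm_lb` (paid per organism): the minimal
  reproduction of why the two frameworks disagree on co-growth of similar
  organisms.
* `make_auxotroph_ring(n = 4, uptake = 1, aa_requirement = 0.5)` — obligate
  cyclic cross-feeders; `mu_max = uptake / (X0 (1 + aa_requirement))` for
  every `n`.  The amino-acid production capacity defaults to the value
  that binds exactly at `mu_max`, making the composition unique
  (`X0/n` each) and every member essential; passing a larger capacity
  deliberately leaves the composition degenerate for the FVA tests.
* `make_competition_toy(yields, uptake)` — pure competition for one
  substrate; with equal yields the pairwise scan gives
  `max X^B = X0 - a` exactly.
* `brute_force_mu_max()` — the independent oracle: grid refinement over
  plain LP feasibility checks (fixed `sum X = X0`, zero objective), ten
  sub-intervals per level down to the requested step.  It shares only the
  LP assembler with the production search, not the search logic.

What the fixtures do *not* emulate: thermodynamic constraints, realistic
network sizes (tens of reactions, not thousands), uptake kinetics, and
curated biomass compositions.  Passing tests therefore certify the
optimization machinery and its invariants, not the biological fidelity of
any particular genome-scale reconstruction.

## Randomized uptake bounds and diet conversion

`sample_uptake_bounds()` draws, per organism and bound set, a total carbon
uptake capacity (C-mmol/gdw/h) from an exponential law with the stated mean
or a uniform law on `[0, 2 * mean]`, then partitions it across the
organism's carbon sources proportionally to i.i.d. unit-exponential draws
and divides by each source's carbon count.  The named law thus governs the
*per-organism total* — the level at which the mean is specified — while
individual sources still vary; this is our resolution of the ambiguity of
whether the law applies per source or per total.  Fiber-like substrates
handled by dedicated specific-rate constraints are simply excluded from the
carbon-source table.  Sampling is deterministic given the seed, and
ensemble summaries are invariant to the order of the sets.

The ensemble contrast test uses a deliberately asymmetric two-member chain
(a low-yield degrader releasing a substrate a high-yield consumer depends
on): joint FBA lets the degrader feed without growing and hands nearly all
biomass-flux share to the consumer, while the steady-state model — where
feeding requires growing — gives the degrader the dominant abundance.  The
same reversal is the qualitative signature reported for fiber-degrading
versus lactic-acid bacteria in gut-community models.

`diet_to_uptake_bounds()` computes
`sum(mass_g_per_day * mmol_per_g) * (1 - absorption) / 24 / (total_biomass / X0)`
per metabolite.  Defaults: absorption 0.97 for carbohydrates (0.95/0.99 as
published alternatives), 0.90 for amino acids and fatty acids, 0 for
dietary fiber; `total_biomass = 10` gdw for the gut microbiota.  The
day-to-hour conversion uses a flat 24 h — meal timing is deliberately not
modelled.

## Problem sizes and runtime

The shipped tests solve communities of 1–16 organisms (up to roughly 100 LP
variables), ensembles of 50–200 bound sets, and brute-force oracle scans at
grid steps of 1e-7; the complete suite runs in well under a minute on a
single core, and `scripts/acceptance.R` in a few seconds.  These sizes were
chosen so that every expected value is either analytic or independently
recomputable at test time.

## Known limitations

* Equal growth rates presume equal dilution of all members;
  organism-specific dilution (wall adhesion, differential washout) is out
  of scope.
* Abundance uniqueness at `mu_max` is model-specific: it is *reported*
  (via FVA), never assumed.
* The SBML reader covers Level 3 core + FBC bounds/objectives — the
  constructs flux-balance models actually use — not the full SBML
  specification; models with exotic constructs should go through the
  mapping-table path or the JSON dialect.
* Joint FBA "abundances" are biomass-flux shares; they are reported for
  comparison only and have no steady-state interpretation.
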