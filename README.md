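# steadycom

Constraint-based metabolic modelling of microbial communities under a
**community steady-state** assumption, in R.

## The problem

Flux balance analysis (FBA) predicts the growth of a single organism from its
genome-scale metabolic network by linear programming.  The direct
multi-organism extension — *joint FBA*, which maximizes the summed biomass
fluxes of all members over a shared metabolite pool — has a structural flaw:
nothing couples an organism's exchange fluxes to its population size, so a
non-growing organism may feed the rest of the community indefinitely, and the
member with the highest biomass yield soaks up every substrate.  Such
solutions cannot persist: in a community whose composition is stable over
time, every member must grow (on time average) at the same specific rate
`mu`, or the fastest grower takes over.

This package implements the community steady-state formulation.  Each
organism `k` gets an explicit biomass variable `X^k` (gdw) and *aggregate*
fluxes `V^k_j = X^k v^k_j` (mmol/h), giving the optimization problem

```
max mu  subject to, for every organism k:
  sum_j S^k_ij V^k_j = 0                 (internal steady state)
  LB^k_j X^k <= V^k_j <= UB^k_j X^k      (capacity scales with abundance)
  V^k_biomass = mu X^k                   (equal specific growth rate)
  X^k >= 0
and for every shared metabolite i:
  u^c_i - e^c_i + sum_k V^k_ex(i) = 0    (community-space balance)
  0 <= u^c_i <= community uptake bound,  e^c_i >= 0
  sum_k X^k = X0                         (total biomass, default 1 gdw)
```

For fixed `mu` this is an LP, and the maximal total biomass `X_T(mu)`
(obtained by replacing the last row with the objective `max sum_k X^k`) is
non-increasing in `mu` with `X_T(mu) >= X0` exactly when growth rate `mu` is
attainable.  `steadycom()` exploits this to find `mu_max` by an iterated LP
feasibility search — typically well under ten LPs regardless of the number of
organisms, because the search interpolates on `1/X_T(mu)`, which is exactly
linear in `mu` whenever growth is limited by a scalable resource.  With one
organism the formulation collapses to ordinary FBA.

Because the problem stays linear at fixed `mu`, classical constraint-based
analyses carry over: `steadycom_fva()` computes min/max ranges of any
weighted combination of fluxes *and abundances* at a fixed growth rate,
`abundance_fva()` tabulates per-organism abundance ranges across growth-rate
fractions, and `pairwise_fva()` scans how one organism's feasible abundance
responds to fixing another's — classifying each pair as *competitive*
(non-increasing response) or *conditionally mutualistic* (a region of
positive slope).  `sample_uptake_bounds()` / `run_ensemble()` randomize
per-organism uptake capacities and summarize the resulting abundance
distributions, and `diet_to_uptake_bounds()` converts a diet table
(g/day × mmol/g, less host absorption) into community uptake bounds.

Organism models are read from SBML Level 3 (+FBC bounds) via
`read_organism_sbml()` or from a compact JSON dialect; synthetic communities
with analytically known optima (`make_single_organism_toy()`,
`make_atpm_toy()`, `make_auxotroph_ring()`, `make_competition_toy()`) make
everything testable offline.  LPs are solved with GLPK through a bundled C
wrapper.

## Worked example

Two identical organisms share one substrate (community uptake bound
4 mmol/h) and each carries a non-growth-associated ATP maintenance (ATPM)
demand of 1 mmol/gdw/h:

```r
library(steadycom)

cm <- make_atpm_toy(n = 2, atpm_lb = 1, uptake = 4)
fit <- steadycom(cm)
fit
#> Community steady-state fit
#>   status:     optimal
#>   mu_max:     3 1/h
#>   iterations: 6 LPs
#>   abundances (gdw, total 1 ):
#> org1 org2
#>    1    0

joint_fba(cm)
#> Joint FBA solution
#>   weighted biomass objective: 2
#>   per-organism growth (1/h):
#> org1 org2
#>    2    0
```

The community grows at 3/h under the steady-state model but the joint-FBA
biomass sum is only 2/h: maintenance scales with biomass (one unit in total)
in the first case, but is paid once per organism — twice — in the second.
This is the mechanism that makes joint FBA systematically underestimate the
growth of communities of similar members.

The reported abundances (all biomass in `org1`) are one vertex of a
degenerate optimum; the variability analysis shows the full range:

```r
abundance_fva(cm, mu_fracs = c(0, 0.9), mu_max = fit$mu_max)
#>   organism frac  mu min max
#> 1     org1  0.0 0.0   0   1
#> 2     org2  0.0 0.0   0   1
#> 3     org1  0.9 2.7   0   1
#> 4     org2  0.9 2.7   0   1
```

Either organism may hold any share of the biomass — they are interchangeable
competitors — whereas on an obligate cross-feeding fixture
(`make_auxotroph_ring(4)`) the same analysis pins every member's abundance
away from zero (each is essential) and `pairwise_fva()` exhibits the
positive-slope mutualistic pattern.

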