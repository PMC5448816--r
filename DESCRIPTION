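Package: steadycom
Title: Steady-State Metabolic Modelling of Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modelling of microbial communities under
    a community steady-state assumption: all member organisms share one
    time-averaged specific growth rate so that relative abundances remain
    constant.  The package builds a community model from per-organism
    genome-scale metabolic models (SBML Level 3 with FBC flux bounds, or a
    compact JSON dialect for small models), finds the maximum community growth
    rate and the member abundances by an iterated linear-programming
    feasibility search, and extends flux variability analysis to community
    abundances and fluxes at any fixed growth rate, including pairwise
    abundance dependency scans.  A joint-FBA baseline (summed biomass
    objective without growth-rate coupling), randomized uptake-bound
    ensembles, and diet-to-uptake-bound conversion are included, together
    with synthetic community generators with analytically known optima.
    Linear programs are solved with the GNU Linear Programming Kit.
License: MIT + file LICENSE
Encoding: UTF-8
SystemRequirements: GLPK (>= 4.65)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
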