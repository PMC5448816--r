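# Hand-built organisms used across test files (independent of the toy
# generators, so generator bugs cannot mask core bugs).

simple_organism <- function(id = "org1", yield = 1, substrate = "s") {
  met <- paste0(substrate, "_e")
  ex <- paste0("EX_", met)
  organism_model(
    id = id,
    stoich = data.frame(metabolite = c(met, met),
                        reaction = c(ex, "biomass"),
                        coef = c(-1, -1 / yield)),
    lb = stats::setNames(c(-1000, 0), c(ex, "biomass")),
    ub = stats::setNames(c(1000, 1000), c(ex, "biomass")),
    biomass_reaction = "biomass",
    exchange_map = stats::setNames(ex, substrate))
}

# One-way cross-feeding pair: a low-yield degrader releases a high-value
# substrate that a high-yield consumer depends on.  Joint FBA lets the
# degrader feed the consumer without growing; under community steady-state
# the degrader must grow to carry flux.
feeder_pair_community <- function(uptake = 10) {
  feeder <- organism_model(
    id = "feeder",
    stoich = data.frame(
      metabolite = c("fiber_e", "fds_e", "fiber_e", "fds_e", "fiber_e"),
      reaction   = c("EX_fiber_e", "EX_fds_e", "degrade", "degrade", "biomass"),
      coef       = c(-1, -1, -1, 2, -5)),
    lb = c(EX_fiber_e = -1000, EX_fds_e = -1000, degrade = 0, biomass = 0),
    ub = c(EX_fiber_e = 1000, EX_fds_e = 1000, degrade = 1000, biomass = 1000),
    biomass_reaction = "biomass",
    exchange_map = c(fiber = "EX_fiber_e", fds = "EX_fds_e"))
  eater <- organism_model(
    id = "eater",
    stoich = data.frame(metabolite = c("fds_e", "fds_e"),
                        reaction = c("EX_fds_e", "biomass"),
                        coef = c(-1, -1)),
    lb = c(EX_fds_e = -1000, biomass = 0),
    ub = c(EX_fds_e = 1000, biomass = 1000),
    biomass_reaction = "biomass",
    exchange_map = c(fds = "EX_fds_e"))
  build_community(list(feeder, eater), uptake_ub = c(fiber = uptake))
}

# value of a weighted abundance/flux target in a steadycom fit
fit_target_value <- function(fit, target) {
  v <- 0
  if (!is.null(target$X))
    v <- v + sum(unlist(target$X) * fit$abundance[names(target$X)])
  if (!is.null(target$V))
    for (r in seq_len(nrow(target$V)))
      v <- v + target$V$weight[r] *
        fit$aggregate_flux[[target$V$organism[r]]][[target$V$reaction[r]]]
  v
}
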