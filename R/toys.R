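## Synthetic community generators.  Units are abstract (substrate uptake in
## mmol/h per X0, yields in gdw/mmol, growth in 1/h); the fixtures target LP
## correctness with analytically derivable optima, not physiology.  Internal
## reactions carry the conventional finite default bound of 1000 so that the
## abundance-scaled capacity rows keep zero-abundance organisms at zero flux.

DEFAULT_BOUND <- 1000

#' Single-organism toy community
#'
#' One organism converting a single community substrate `s` into biomass
#' with a fixed yield.  The maximal community growth rate has the closed
#' form `mu_max = uptake * yield / X0`, making this the basic oracle for the
#' growth-rate search and for the reduction of the community formulation to
#' plain single-organism FBA.
#'
#' @param uptake community uptake bound on the substrate (mmol/h per X0).
#' @param yield biomass yield on the substrate (gdw/mmol).
#' @param X0 total community biomass (gdw).
#' @param id organism id.
#' @return A [build_community()] model.
#' @export
make_single_organism_toy <- function(uptake = 10, yield = 1, X0 = 1,
                                     id = "org1") {
  stopifnot(yield > 0, uptake >= 0)
  om <- organism_model(
    id = id,
    stoich = data.frame(
      metabolite = c("s_e", "s_e"),
      reaction = c("EX_s_e", "biomass"),
      coef = c(-1, -1 / yield)),
    lb = c(EX_s_e = -DEFAULT_BOUND, biomass = 0),
    ub = c(EX_s_e = DEFAULT_BOUND, biomass = DEFAULT_BOUND),
    biomass_reaction = "biomass",
    exchange_map = c(s = "EX_s_e"))
  build_community(list(om), uptake_ub = c(s = uptake), X0 = X0)
}

#' ATPM toy community
#'
#' `n` identical organisms sharing one substrate, each with a biomass yield
#' of one and a non-growth-associated ATP maintenance (ATPM) demand
#' `atpm_lb` (mmol/gdw/h).  Under community steady-state the maintenance
#' scales with biomass, so `mu_max = uptake / X0 - atpm_lb`; under joint FBA
#' every organism pays the full maintenance regardless of biomass, so the
#' summed growth is `uptake - n * atpm_lb`.  This is the minimal fixture
#' exhibiting the ATPM-apportioning difference between the two formulations.
#'
#' @param n number of organisms.
#' @param atpm_lb ATPM lower bound per organism (mmol/gdw/h).
#' @param uptake community uptake bound on the shared substrate.
#' @param X0 total community biomass (gdw).
#' @return A [build_community()] model.
#' @export
make_atpm_toy <- function(n = 2, atpm_lb = 1, uptake = 4, X0 = 1) {
  stopifnot(n >= 1, atpm_lb >= 0, uptake >= 0)
  mk <- function(k) organism_model(
    id = paste0("org", k),
    stoich = data.frame(
      metabolite = c("s_e", "s_e", "atp", "atp", "s_e"),
      reaction = c("EX_s_e", "conv_atp", "conv_atp", "ATPM", "biomass"),
      coef = c(-1, -1, 1, -1, -1)),
    lb = c(EX_s_e = -DEFAULT_BOUND, conv_atp = 0, ATPM = atpm_lb, biomass = 0),
    ub = c(EX_s_e = DEFAULT_BOUND, conv_atp = DEFAULT_BOUND,
           ATPM = DEFAULT_BOUND, biomass = DEFAULT_BOUND),
    biomass_reaction = "biomass",
    atpm_reaction = "ATPM",
    exchange_map = c(s = "EX_s_e"))
  build_community(lapply(seq_len(n), mk), uptake_ub = c(s = uptake), X0 = X0)
}

#' Obligate cross-feeding ring community
#'
#' `n` organisms in a cyclic cross-feeding topology: organism `k` requires
#' `aa_requirement` mmol of the amino acid produced exclusively by organism
#' `k - 1` per gdw of biomass, and secretes its own amino acid for organism
#' `k + 1`.  All organisms share one substrate `s` (the only community
#' uptake); every member is obligate, so removing any one drives the
#' community growth rate to zero.  The closed form is
#' `mu_max = uptake / (X0 * (1 + aa_requirement))` for every `n`.
#'
#' By default the amino-acid production capacity `prod_capacity` is set to
#' `aa_requirement * mu_max`, which binds exactly at maximal growth and
#' makes the abundance profile unique (all `X0 / n`); pass a larger value to
#' leave the composition degenerate.
#'
#' @param n number of organisms (>= 2).
#' @param uptake community uptake bound on the shared substrate.
#' @param aa_requirement amino-acid demand per unit biomass (mmol/gdw).
#' @param prod_capacity upper bound of the amino-acid production reaction
#'   (mmol/gdw/h); `NULL` for the binding default.
#' @param X0 total community biomass (gdw).
#' @return A [build_community()] model.
#' @export
make_auxotroph_ring <- function(n = 4, uptake = 1, aa_requirement = 0.5,
                                prod_capacity = NULL, X0 = 1) {
  stopifnot(n >= 2, uptake > 0, aa_requirement > 0)
  mu_max <- uptake / (X0 * (1 + aa_requirement))
  if (is.null(prod_capacity)) prod_capacity <- aa_requirement * mu_max
  mk <- function(k) {
    prev <- if (k == 1) n else k - 1
    aa_in <- paste0("aa", prev)
    aa_out <- paste0("aa", k)
    mets <- c("s_e", paste0(aa_in, "_e"), paste0(aa_out, "_e"))
    rxns <- c("EX_s_e", paste0("EX_", aa_in, "_e"), paste0("EX_", aa_out, "_e"),
              "prod_aa", "biomass")
    organism_model(
      id = paste0("org", k),
      stoich = data.frame(
        metabolite = c(mets[1], mets[2], mets[3],
                       mets[1], mets[3],
                       mets[1], mets[2]),
        reaction = c(rxns[1], rxns[2], rxns[3],
                     "prod_aa", "prod_aa",
                     "biomass", "biomass"),
        coef = c(-1, -1, -1,
                 -1, 1,
                 -1, -aa_requirement)),
      lb = stats::setNames(c(-DEFAULT_BOUND, -DEFAULT_BOUND, -DEFAULT_BOUND,
                             0, 0), rxns),
      ub = stats::setNames(c(DEFAULT_BOUND, DEFAULT_BOUND, DEFAULT_BOUND,
                             prod_capacity, DEFAULT_BOUND), rxns),
      biomass_reaction = "biomass",
      exchange_map = stats::setNames(rxns[1:3], c("s", aa_in, aa_out)))
  }
  build_community(lapply(seq_len(n), mk), uptake_ub = c(s = uptake), X0 = X0)
}

#' Competing organisms on a single shared substrate
#'
#' Organisms that differ only in biomass yield and compete for one community
#' substrate — the minimal purely competitive topology: below the maximal
#' growth rate, fixing one organism's abundance at `a` leaves exactly
#' `X0 - a` for the other.
#'
#' @param yields named numeric vector of biomass yields (gdw/mmol), one per
#'   organism; names become organism ids (default `orgA`, `orgB`, ...).
#' @param uptake community uptake bound on the substrate.
#' @param X0 total community biomass (gdw).
#' @return A [build_community()] model.
#' @export
make_competition_toy <- function(yields = c(orgA = 1, orgB = 1), uptake = 10,
                                 X0 = 1) {
  stopifnot(all(yields > 0), length(yields) >= 1)
  if (is.null(names(yields)))
    names(yields) <- paste0("org", LETTERS[seq_along(yields)])
  mk <- function(k) organism_model(
    id = names(yields)[k],
    stoich = data.frame(
      metabolite = c("s_e", "s_e"),
      reaction = c("EX_s_e", "biomass"),
      coef = c(-1, -1 / yields[[k]])),
    lb = c(EX_s_e = -DEFAULT_BOUND, biomass = 0),
    ub = c(EX_s_e = DEFAULT_BOUND, biomass = DEFAULT_BOUND),
    biomass_reaction = "biomass",
    exchange_map = c(s = "EX_s_e"))
  build_community(lapply(seq_along(yields), mk),
                  uptake_ub = c(s = uptake), X0 = X0)
}

#' Random single-organism toy community
#'
#' Draws a random linear pathway (substrate through 0-3 intermediates to
#' biomass) with random yield, uptake bound, and an optional maintenance
#' demand.  Used to exercise the reduction of the community formulation to
#' single-organism FBA on models without a hand-computed optimum.
#'
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param X0 total community biomass (gdw).
#' @return A [build_community()] model with one organism.
#' @export
make_random_toy <- function(seed, X0 = 1) {
  set.seed(seed)
  yield <- stats::runif(1, 0.2, 2)
  uptake <- stats::runif(1, 1, 20)
  n_mid <- sample(0:3, 1)
  atpm <- if (stats::runif(1) < 0.5) stats::runif(1, 0, 0.5) else 0

  mets <- c("s_e", if (n_mid > 0) paste0("m", seq_len(n_mid)))
  chain_in <- mets
  chain_out <- c(if (n_mid > 0) paste0("m", seq_len(n_mid)), "bm_pre")
  mets <- unique(c(mets, "bm_pre"))
  rxns <- c("EX_s_e", paste0("conv", seq_len(n_mid + 1)), "biomass")
  sto <- data.frame(metabolite = "s_e", reaction = "EX_s_e", coef = -1)
  for (i in seq_len(n_mid + 1)) {
    sto <- rbind(sto,
                 data.frame(metabolite = c(chain_in[i], chain_out[i]),
                            reaction = rep(paste0("conv", i), 2),
                            coef = c(-1, 1)))
  }
  sto <- rbind(sto, data.frame(metabolite = "bm_pre", reaction = "biomass",
                               coef = -1 / yield))
  lb <- stats::setNames(c(-DEFAULT_BOUND, rep(0, n_mid + 1), 0), rxns)
  ub <- stats::setNames(rep(DEFAULT_BOUND, length(rxns)), rxns)
  if (atpm > 0) {
    sto <- rbind(sto, data.frame(metabolite = "bm_pre", reaction = "ATPM",
                                 coef = -1))
    lb <- c(lb, ATPM = atpm)
    ub <- c(ub, ATPM = DEFAULT_BOUND)
  }
  om <- organism_model(id = "rnd", stoich = sto, lb = lb, ub = ub,
                       biomass_reaction = "biomass",
                       atpm_reaction = if (atpm > 0) "ATPM" else NULL,
                       exchange_map = c(s = "EX_s_e"))
  build_community(list(om), uptake_ub = c(s = uptake), X0 = X0)
}

#' Brute-force oracle for the maximal community growth rate
#'
#' Locates the largest feasible community growth rate by plain grid
#' refinement over LP feasibility checks (total biomass fixed at `X0`,
#' zero objective) — entirely independent of the interpolated search in
#' [steadycom()].  Each refinement level scans ten equal sub-intervals of
#' the current bracket in ascending order, exploiting that feasibility is
#' monotone in the growth rate.
#'
#' @param cm a [build_community()] model.
#' @param mu_grid_step final grid resolution (1/h).
#' @param mu_upper optional known upper bound for the scan; found by
#'   doubling from 1 when `NULL`.
#' @return The largest growth rate on the final grid that is feasible.
#' @export
brute_force_mu_max <- function(cm, mu_grid_step = 1e-7, mu_upper = NULL) {
  feasible_at <- function(mu) {
    lp <- assemble_steadycom_lp(cm, mu, fix_total_biomass = TRUE)
    solve_lp(lp)$status == "optimal"
  }
  if (!feasible_at(mu_grid_step)) return(0)
  lo <- mu_grid_step
  if (is.null(mu_upper)) {
    hi <- 1
    while (feasible_at(hi)) {
      lo <- hi
      hi <- hi * 2
      if (hi > 2^30) stop("no infeasible growth rate found below 2^30")
    }
  } else {
    hi <- mu_upper
    if (feasible_at(hi)) return(hi)
  }
  while (hi - lo > mu_grid_step) {
    step <- (hi - lo) / 10
    base <- lo
    for (i in 1:9) {
      mu <- base + step * i
      if (feasible_at(mu)) lo <- mu else { hi <- mu; break }
    }
    ## with or without a break the bracket is now one sub-interval wide
  }
  lo
}
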