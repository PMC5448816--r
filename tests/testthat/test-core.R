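test_that("build_community assembles shared metabolites and default bounds", {
  cm <- build_community(list(simple_organism("a"), simple_organism("b")),
                        uptake_ub = c(s = 5))
  expect_s3_class(cm, "community_model")
  expect_equal(cm$community_metabolites, "s")
  expect_length(cm$organisms, 2)
  expect_equal(cm$uptake_ub, c(s = 5))

  # metabolites absent from uptake_ub are bounded at zero
  cm0 <- build_community(list(simple_organism("a")))
  expect_equal(unname(cm0$uptake_ub), 0)
})

test_that("build_community rejects invalid input", {
  expect_error(build_community(list(simple_organism("a"), simple_organism("a"))),
               "duplicate organism id")
  expect_error(build_community(list(simple_organism("a")),
                               uptake_ub = c(s = -1)), "negative")
  expect_error(build_community(list(simple_organism("a")), X0 = 0),
               "positive")
  expect_error(build_community(list(simple_organism("a")),
                               uptake_ub = c(nope = 1)), "not exchanged")
  # exchange reaction touching two metabolites
  expect_error(organism_model(
    id = "bad",
    stoich = data.frame(metabolite = c("s_e", "p_e", "s_e"),
                        reaction = c("EX_s_e", "EX_s_e", "biomass"),
                        coef = c(-1, 1, -1)),
    lb = c(EX_s_e = -1000, biomass = 0),
    ub = c(EX_s_e = 1000, biomass = 1000),
    biomass_reaction = "biomass",
    exchange_map = c(s = "EX_s_e")), "exactly one metabolite")
})

test_that("toy generator output re-validates through build_community", {
  cm <- make_atpm_toy(2, 1, 4)
  cm2 <- build_community(cm$organisms, uptake_ub = cm$uptake_ub, X0 = cm$X0)
  expect_equal(cm2, cm)
})

test_that("the steady-state LP behaves at growth-rate extremes", {
  cm <- make_single_organism_toy(uptake = 10, yield = 1)
  expect_error(assemble_steadycom_lp(cm, -0.1), "non-negative")

  # mu = 0 is feasible with X = X0 and zero biomass flux
  lp0 <- assemble_steadycom_lp(cm, 0)
  s0 <- solve_lp(lp0)
  expect_equal(s0$status, "optimal")
  expect_equal(s0$x[["X[org1]"]], 1)
  expect_equal(s0$x[["V[org1][biomass]"]], 0)

  # ATPM toy: feasible exactly up to mu = uptake - atpm
  atpm <- make_atpm_toy(2, 1, 4)
  expect_equal(solve_lp(assemble_steadycom_lp(atpm, 3))$status, "optimal")
  expect_equal(solve_lp(assemble_steadycom_lp(atpm, 3 + 1e-3))$status,
               "infeasible")
})

test_that("zero abundance forces zero flux for every reaction", {
  for (cm in list(make_atpm_toy(2, 1, 4), make_auxotroph_ring(3))) {
    lp <- assemble_steadycom_lp(cm, 0.1, fix_total_biomass = FALSE)
    org <- names(cm$organisms)[1]
    lp <- lp_set_var_bounds(lp, paste0("X[", org, "]"), 0, 0)
    for (rxn in cm$organisms[[org]]$reactions) {
      v <- paste0("V[", org, "][", rxn, "]")
      hi <- solve_lp(lp_set_objective(lp, stats::setNames(1, v), TRUE))
      lo <- solve_lp(lp_set_objective(lp, stats::setNames(1, v), FALSE))
      expect_equal(hi$objval, 0, tolerance = 1e-9)
      expect_equal(lo$objval, 0, tolerance = 1e-9)
    }
  }
})

test_that("community metabolites are conserved and biomass sums to X0", {
  for (cm in list(make_atpm_toy(2, 1, 4), make_auxotroph_ring(4),
                  make_competition_toy(c(a = 1, b = 0.5)))) {
    fit <- steadycom(cm)
    expect_equal(sum(fit$abundance), cm$X0, tolerance = 1e-8)
    for (met in cm$community_metabolites) {
      vex <- sum(vapply(cm$organisms, function(om) {
        if (met %in% names(om$exchange_map))
          fit$aggregate_flux[[om$id]][[om$exchange_map[[met]]]] else 0
      }, numeric(1)))
      expect_equal(fit$community_uptake[[met]] - fit$community_export[[met]] +
                     vex, 0, tolerance = 1e-8)
    }
    expect_true(all(fit$community_uptake <= cm$uptake_ub + 1e-9))
  }
})

test_that("scaling X0 and uptake bounds scales biomass but not growth", {
  base <- make_atpm_toy(2, 1, 4)
  f1 <- steadycom(base)
  c <- 3.7
  scaled <- build_community(base$organisms, uptake_ub = base$uptake_ub * c,
                            X0 = base$X0 * c)
  f2 <- steadycom(scaled)
  expect_equal(f2$mu_max, f1$mu_max, tolerance = 2e-6)
  expect_equal(sum(f2$abundance), c * sum(f1$abundance), tolerance = 1e-6)
})

test_that("joint FBA reduces to standard FBA for one organism", {
  cm <- make_single_organism_toy(uptake = 10, yield = 1)
  jf <- joint_fba(cm)
  expect_equal(jf$objective, 10, tolerance = 1e-9)
  expect_equal(unname(jf$growth), 10, tolerance = 1e-9)
})

test_that("joint FBA pays maintenance per organism, not per unit biomass", {
  cm <- make_atpm_toy(2, 1, 4)
  jf <- joint_fba(cm)
  expect_equal(jf$objective, 2, tolerance = 1e-9)

  # single-organism objective weighting
  jf1 <- joint_fba(cm, c(org1 = 1, org2 = 0))
  expect_equal(jf1$objective, jf1$growth[["org1"]])
  expect_gte(jf1$growth[["org1"]], jf$growth[["org1"]] - 1e-9)
})

test_that("specific fluxes divide by biomass and flag absent organisms", {
  cm <- make_atpm_toy(2, 1, 4)
  fit <- steadycom(cm)
  v <- specific_fluxes(fit)
  present <- names(fit$abundance)[fit$abundance > 1e-8]
  absent <- setdiff(names(fit$abundance), present)
  expect_equal(attr(v, "absent"), absent)
  for (org in present) {
    expect_equal(v[[org]], fit$aggregate_flux[[org]] / fit$abundance[[org]])
    # maintenance is met per unit biomass by every present organism
    expect_gte(v[[org]][["ATPM"]], 1 - 1e-6)
    expect_equal(v[[org]][["biomass"]], fit$mu_max, tolerance = 1e-6)
  }
  for (org in absent) expect_true(all(v[[org]] == 0))
})
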