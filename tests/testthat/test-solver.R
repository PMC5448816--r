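test_that("maximal total biomass follows the closed form u*Y/mu", {
  cm <- make_single_organism_toy(uptake = 10, yield = 1)
  expect_equal(max_total_biomass(cm, 5)$XT, 2, tolerance = 1e-9)
  expect_equal(max_total_biomass(cm, 10)$XT, 1, tolerance = 1e-9)
  expect_equal(max_total_biomass(cm, 20)$XT, 0.5, tolerance = 1e-9)
  # beyond every biomass capacity bound nothing can grow
  expect_equal(max_total_biomass(cm, 2000)$XT, 0, tolerance = 1e-9)
})

test_that("total biomass is non-increasing in the growth rate", {
  for (cm in list(make_single_organism_toy(10, 1), make_atpm_toy(2, 1, 4),
                  make_auxotroph_ring(4))) {
    mus <- seq(0.05, 12, length.out = 20)
    XT <- vapply(mus, function(m) max_total_biomass(cm, m)$XT, numeric(1))
    expect_true(all(diff(XT) <= 1e-9))
  }
})

test_that("the growth-rate search matches closed forms on the toys", {
  fit <- steadycom(make_single_organism_toy(uptake = 10, yield = 1))
  expect_equal(fit$mu_max, 10, tolerance = 1e-6)
  expect_equal(unname(fit$abundance), 1, tolerance = 1e-8)
  expect_equal(fit$status, "optimal")

  expect_equal(steadycom(make_single_organism_toy(10, 0.5))$mu_max, 5,
               tolerance = 1e-6)

  fit2 <- steadycom(make_atpm_toy(2, 1, 4))
  expect_equal(fit2$mu_max, 3, tolerance = 1e-6)

  fit3 <- steadycom(make_auxotroph_ring(4, uptake = 1, aa_requirement = 0.5))
  expect_equal(fit3$mu_max, 1 / 1.5, tolerance = 1e-6)
  expect_equal(unname(fit3$abundance), rep(0.25, 4), tolerance = 1e-6)
})

test_that("degenerate communities get the right status", {
  # nothing to eat, nothing to maintain: zero growth, all fluxes zero
  z <- steadycom(make_single_organism_toy(uptake = 0, yield = 1))
  expect_equal(z$status, "zero_growth")
  expect_equal(z$mu_max, 0)
  expect_equal(sum(z$abundance), 1)
  expect_true(all(abs(unlist(z$aggregate_flux)) < 1e-9))

  # maintenance demand with no substrate: no feasible community at all
  i <- steadycom(make_atpm_toy(2, 1, uptake = 0))
  expect_equal(i$status, "infeasible")
})

test_that("a missing uptake bound on the limiting resource is reported", {
  cm <- make_single_organism_toy(uptake = 10, yield = 1)
  cm$uptake_ub[["s"]] <- Inf
  expect_error(steadycom(cm), "uptake bound")

  # joint FBA only becomes unbounded once the specific-rate caps go too
  om <- cm$organisms[[1]]
  om$lb[["EX_s_e"]] <- -Inf
  om$ub[["biomass"]] <- Inf
  cmu <- build_community(list(om), uptake_ub = c(s = Inf))
  expect_error(joint_fba(cmu), "uptake bound")
})

test_that("the search is deterministic and iteration-frugal", {
  cm <- make_auxotroph_ring(4)
  f1 <- steadycom(cm)
  f2 <- steadycom(cm)
  expect_identical(f1$mu_max, f2$mu_max)
  expect_identical(f1$abundance, f2$abundance)
  expect_identical(f1$iterations, f2$iterations)
  expect_lte(f1$iterations, 10)
})

test_that("individual maximal growth uses the community environment", {
  expect_equal(max_individual_growth(make_single_organism_toy(10, 1), "org1"),
               10, tolerance = 1e-9)

  # obligate pair: the partner can feed without growing under joint FBA...
  ring2 <- make_auxotroph_ring(2, uptake = 1)
  expect_gt(max_individual_growth(ring2, "org2"), 0)
  # ...but alone the organism cannot grow at all
  alone <- build_community(ring2$organisms["org2"],
                           uptake_ub = c(s = 1), X0 = 1)
  expect_equal(max_individual_growth(alone, "org2"), 0, tolerance = 1e-9)

  # maximizing one organism is a relaxation of the equal-weight optimum
  jf <- joint_fba(ring2)
  for (org in names(ring2$organisms))
    expect_gte(max_individual_growth(ring2, org), jf$growth[[org]] - 1e-9)
})

test_that("community growth exceeds per-capita joint FBA when ATPM binds", {
  cm <- make_atpm_toy(2, 1, 4)
  expect_gt(steadycom(cm)$mu_max, joint_fba(cm)$objective / 2)
})
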