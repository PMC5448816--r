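test_that("abundance of a lone organism is pinned at X0", {
  cm <- make_single_organism_toy(uptake = 10, yield = 1)
  fit <- steadycom(cm)
  r <- steadycom_fva(cm, fit$mu_max, list("org1"))
  expect_equal(r$min, 1, tolerance = 1e-8)
  expect_equal(r$max, 1, tolerance = 1e-8)
})

test_that("at zero growth either maintenance-capable organism may dominate", {
  cm <- make_atpm_toy(2, 1, 4)
  r <- steadycom_fva(cm, 0, list("org1", "org2"))
  expect_equal(r$min, c(0, 0), tolerance = 1e-9)
  expect_equal(r$max, c(1, 1), tolerance = 1e-9)
})

test_that("requesting variability above the maximal growth rate errors", {
  cm <- make_atpm_toy(2, 1, 4)
  expect_error(steadycom_fva(cm, 3.5, list("org1")), "infeasible")
})

test_that("every optimal-solution target value lies inside its FVA range", {
  cm <- make_auxotroph_ring(4)
  fit <- steadycom(cm)
  targets <- c(lapply(names(cm$organisms), function(o)
    list(X = stats::setNames(1, o))),
    list(list(V = data.frame(organism = "org1", reaction = "biomass",
                             weight = 1),
              X = c(org2 = 0.5))))
  r <- steadycom_fva(cm, fit$mu_max, targets)
  for (i in seq_along(targets)) {
    v <- fit_target_value(fit, targets[[i]])
    expect_gte(v, r$min[i] - 1e-7)
    expect_lte(v, r$max[i] + 1e-7)
  }
})

test_that("obligate partners are essential at maximal community growth", {
  cm <- make_auxotroph_ring(4)
  fit <- steadycom(cm)
  r <- abundance_fva(cm, 1, fit$mu_max)
  # the binding production capacity pins the composition at X0/n
  expect_true(all(r$min > 0.2))
  expect_equal(r$max, rep(0.25, 4), tolerance = 1e-4)

  # essentiality cross-check: fixing any organism at zero is infeasible
  lp <- assemble_steadycom_lp(cm, fit$mu_max * 0.999)
  for (org in names(cm$organisms)) {
    lp0 <- lp_set_var_bounds(lp, paste0("X[", org, "]"), 0, 0)
    expect_equal(solve_lp(lp0)$status, "infeasible")
  }
})

test_that("abundance ranges are nested as growth approaches the maximum", {
  cm <- make_auxotroph_ring(4, prod_capacity = 1)  # slack capacity: degenerate
  fit <- steadycom(cm)
  r <- abundance_fva(cm, c(0.9, 0.99), fit$mu_max)
  for (org in unique(r$organism)) {
    lo <- r[r$organism == org & r$frac == 0.90, ]
    hi <- r[r$organism == org & r$frac == 0.99, ]
    expect_gte(hi$min, lo$min - 1e-8)
    expect_lte(hi$max, lo$max + 1e-8)
  }
})

test_that("a zero abundance minimum coincides with dispensability", {
  cm <- make_competition_toy(c(a = 1, b = 1), uptake = 10)
  fit <- steadycom(cm)
  r <- abundance_fva(cm, 0.5, fit$mu_max)
  expect_equal(r$min, c(0, 0), tolerance = 1e-9)
  lp <- assemble_steadycom_lp(cm, 0.5 * fit$mu_max)
  for (org in c("a", "b")) {
    lp0 <- lp_set_var_bounds(lp, paste0("X[", org, "]"), 0, 0)
    expect_equal(solve_lp(lp0)$status, "optimal")
  }
})

test_that("joint FBA leaves composition analogs unconstrained on obligate toys", {
  # under joint FBA a non-growing organism can still feed its partner, so at
  # sub-maximal community growth any biomass-flux share between 0 and the
  # total is attainable — unlike the steady-state ranges above
  cm <- make_auxotroph_ring(2, uptake = 1)
  opt <- joint_fba(cm)$objective
  lp <- assemble_joint_fba_lp(cm)
  lp <- lp_add_row(lp, stats::setNames(rep(1, 2),
                                       c("V[org1][biomass]", "V[org2][biomass]")),
                   0.9 * opt, 0.9 * opt)
  for (org in c("org1", "org2")) {
    v <- paste0("V[", org, "][biomass]")
    mn <- solve_lp(lp_set_objective(lp, stats::setNames(1, v), FALSE))
    mx <- solve_lp(lp_set_objective(lp, stats::setNames(1, v), TRUE))
    expect_equal(mn$objval, 0, tolerance = 1e-9)
    expect_equal(mx$objval, 0.9 * opt, tolerance = 1e-9)
  }
})

test_that("shared-substrate competitors trade abundance one for one", {
  cm <- make_competition_toy(c(a = 1, b = 1), uptake = 10)
  fit <- steadycom(cm)
  scan <- pairwise_fva(cm, "a", "b", mu_frac = 0.5, mu_max = fit$mu_max)
  expect_s3_class(scan, "pairwise_scan")
  expect_equal(scan$classification, "competitive")
  feas <- scan$ranges[scan$ranges$feasible, ]
  expect_equal(feas$dep_max, cm$X0 - feas$fixed_value, tolerance = 1e-8)
})

test_that("cross-feeders show a positive-slope (mutualistic) region", {
  cm <- make_auxotroph_ring(4)
  fit <- steadycom(cm)
  scan <- pairwise_fva(cm, "org1", "org2", mu_frac = 0.5, mu_max = fit$mu_max)
  expect_equal(scan$classification, "conditionally mutualistic")
  feas <- scan$ranges[scan$ranges$feasible, ]
  expect_true(any(diff(feas$dep_max) > 1e-6))
  # monopolizing the community starves the obligate partners
  expect_false(scan$ranges$feasible[nrow(scan$ranges)])
})
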