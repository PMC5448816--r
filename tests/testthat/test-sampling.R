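test_that("diet conversion follows the mass-composition-absorption formula", {
  diet <- data.frame(component = "starch", category = "carbohydrate",
                     mass_g_per_day = 240, mmol_per_g = 1, metabolite = "glc")
  expect_equal(diet_to_uptake_bounds(diet), c(glc = 240 * 0.03 / 24 / 10))

  # degenerate inputs
  diet$mass_g_per_day <- 0
  expect_equal(unname(diet_to_uptake_bounds(diet)), 0)
  diet$mass_g_per_day <- 240
  expect_equal(unname(diet_to_uptake_bounds(
    diet, absorption = c(carbohydrate = 1))), 0)

  expect_error(diet_to_uptake_bounds(
    transform(diet, category = "mystery")), "unknown diet category")
  expect_error(diet_to_uptake_bounds(
    diet, absorption = c(carbohydrate = 1.2)), "\\[0, 1\\]")
})

test_that("diet conversion is linear in mass and in (1 - absorption)", {
  diet <- data.frame(component = c("x", "y"),
                     category = c("carbohydrate", "amino acid"),
                     mass_g_per_day = c(100, 50), mmol_per_g = c(2, 3),
                     metabolite = c("glc", "ala"))
  b1 <- diet_to_uptake_bounds(diet)
  b2 <- diet_to_uptake_bounds(transform(diet, mass_g_per_day = mass_g_per_day * 3))
  expect_equal(b2, b1 * 3)
  b3 <- diet_to_uptake_bounds(diet, absorption = c(carbohydrate = 0.94,
                                                   "amino acid" = 0.80))
  expect_equal(unname(b3["glc"] / b1["glc"]), 0.06 / 0.03)
  expect_equal(unname(b3["ala"] / b1["ala"]), 0.20 / 0.10)

  # components mapping to one metabolite accumulate
  diet2 <- rbind(diet, transform(diet[1, ], component = "maltose"))
  b4 <- diet_to_uptake_bounds(diet2)
  expect_equal(unname(b4["glc"]), unname(2 * b1["glc"]))
})

test_that("uptake-bound sampling is deterministic and law-abiding", {
  cm <- make_competition_toy(c(a = 1, b = 1), uptake = 10)
  carbons <- c(s = 6)
  s1 <- sample_uptake_bounds(cm, carbons, 120, "exponential", 5, seed = 42)
  s2 <- sample_uptake_bounds(cm, carbons, 120, "exponential", 5, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(unlist(lapply(s1, function(s) s$bounds$max_uptake)) >= 0))

  # uniform law: carbon-weighted per-organism totals never exceed twice the mean
  su <- sample_uptake_bounds(cm, carbons, 120, "uniform", 200, seed = 7)
  totals <- unlist(lapply(su, function(s)
    tapply(s$bounds$max_uptake * carbons[s$bounds$metabolite],
           s$bounds$organism, sum)))
  expect_true(all(totals <= 240 + 1e-9))

  # exponential law: mean of per-organism totals approaches the stated mean
  se <- sample_uptake_bounds(cm, carbons, 120, "exponential", 1000, seed = 7)
  totals <- unlist(lapply(se, function(s)
    tapply(s$bounds$max_uptake * carbons[s$bounds$metabolite],
           s$bounds$organism, sum)))
  expect_lt(abs(mean(totals) - 120) / 120, 0.05)

  expect_error(sample_uptake_bounds(cm, carbons, 120, "exponential", 0, 1),
               "at least 1")
  expect_error(sample_uptake_bounds(cm, c(nope = 6), 120, "exponential", 1, 1),
               "not a community metabolite")
})

test_that("an ensemble of identical bound sets has zero variance", {
  cm <- make_competition_toy(c(a = 1, b = 1), uptake = 10)
  one <- sample_uptake_bounds(cm, c(s = 6), 30, "exponential", 1, seed = 3)
  sets <- rep(one, 10)
  ens <- run_ensemble(cm, sets, method = "steadycom")
  expect_equal(ens$n_failed, 0)
  expect_equal(unname(ens$summary[, "sd"]), c(0, 0))
  single <- steadycom(build_community(cm$organisms, cm$uptake_ub, cm$X0,
                                      organism_uptake_ub = one[[1]]$bounds))
  expect_equal(ens$summary[, "mean"], single$abundance)
})

test_that("symmetric organisms and sampling give symmetric mean abundances", {
  cm <- make_competition_toy(c(a = 1, b = 1), uptake = 10)
  sets <- sample_uptake_bounds(cm, c(s = 6), 3, "exponential", 200, seed = 11)
  ens <- run_ensemble(cm, sets, method = "steadycom")
  m <- ens$summary[, "mean"]
  expect_lt(abs(m[["a"]] - m[["b"]]), 0.1)
  expect_equal(sum(m), 1, tolerance = 1e-6)

  # summaries do not depend on the order of the sets
  ens_rev <- run_ensemble(cm, rev(sets), method = "steadycom")
  expect_equal(ens_rev$summary[, "mean"], ens$summary[, "mean"])

  # taxon aggregation sums member abundances
  ens_tx <- run_ensemble(cm, sets, method = "steadycom",
                         taxa = c(a = "T1", b = "T1"))
  expect_equal(unname(ens_tx$taxon_summary["T1", "mean"]), 1, tolerance = 1e-6)
})

test_that("joint FBA concentrates mass on the high-yield consumer", {
  # Joint FBA lets the degrader supply substrate without growing, so the
  # high-yield consumer collects nearly all the biomass-flux share; under
  # community steady-state the degrader must grow to sustain its own flux
  # and ends up dominating instead.
  cm <- feeder_pair_community(uptake = 10)
  sets <- sample_uptake_bounds(cm, c(fiber = 6, fds = 3), 30,
                               "exponential", 50, seed = 5)
  jf <- run_ensemble(cm, sets, method = "joint_fba")
  sc <- run_ensemble(cm, sets, method = "steadycom")
  expect_equal(jf$n_failed, 0)
  expect_equal(sc$n_failed, 0)
  expect_gt(jf$summary["eater", "mean"], 0.8)
  expect_gt(sc$summary["feeder", "mean"], 0.8)
})
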