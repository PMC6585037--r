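# FBA / pFBA / FVA and the coupling classifier

test_that("FBA reproduces the toy optima and failure modes", {
  expect_equal(fba(toyA(), "R_ex")$objective_value, 10, tolerance = 1e-9)
  expect_equal(fba(toyB())$objective_value, 10, tolerance = 1e-9)
  ko <- apply_knockouts(toyB(), "R_s")
  expect_equal(fba(ko)$objective_value, 0, tolerance = 1e-9)
  # infeasible model reports status instead of raising
  bad <- set_environment(toyB(), environment_spec(R_bio = c(50, 100)))
  expect_equal(fba(bad)$status, "infeasible")
})

test_that("pFBA picks the parsimonious route", {
  pa <- pfba(toyA())
  expect_equal(unname(pa$fluxes), rep(10, 4), tolerance = 1e-4)
  expect_equal(pa$total_flux, 40, tolerance = 1e-3)

  pb <- pfba(toyB())    # R_2 route (total 30) beats R_1/R_3 route (50)
  expect_equal(unname(pb$fluxes["R_2"]), 10, tolerance = 1e-4)
  expect_equal(unname(pb$fluxes["R_p"]), 0, tolerance = 1e-6)
  expect_equal(pb$total_flux, 30, tolerance = 1e-3)

  pk <- pfba(apply_knockouts(toyB(), "R_2"))
  expect_equal(unname(pk$fluxes["R_bio"]), 10, tolerance = 1e-4)
  expect_equal(unname(pk$fluxes["R_p"]), 10, tolerance = 1e-4)
})

test_that("pFBA biomass equals the FBA optimum; total flux no larger", {
  for (model in list(toyA(), toyB(), toyC(),
                     random_network(4, 3, 0.3, seed = 5))) {
    f <- fba(model); p <- pfba(model)
    expect_equal(p$objective_value, f$objective_value,
                 tolerance = 1e-5)
    expect_lte(p$total_flux, sum(abs(f$fluxes)) + 1e-6)
  }
})

test_that("FVA matches closed-form toy ranges and brackets pFBA", {
  fv1 <- fva(toyA(), fraction = 1)
  expect_equal(fv1$min, rep(10, 4), tolerance = 1e-6)
  expect_equal(fv1$max, rep(10, 4), tolerance = 1e-6)
  fv05 <- fva(toyA(), fraction = 0.5, reactions = "R_1")
  expect_equal(fv05$min, 5, tolerance = 1e-6)
  expect_equal(fv05$max, 10, tolerance = 1e-6)
  fvB <- fva(apply_knockouts(toyB(), "R_2"), fraction = 0.9, reactions = "R_p")
  expect_equal(fvB$min, 9, tolerance = 1e-3)
  expect_equal(fvB$max, 10, tolerance = 1e-6)
  # bracketing property on a random model
  net <- random_network(4, 3, 0.3, seed = 8)
  p <- pfba(net)
  fv <- fva(net, fraction = 1)
  expect_true(all(fv$min - 1e-5 <= p$fluxes[fv$reaction]))
  expect_true(all(p$fluxes[fv$reaction] <= fv$max + 1e-5))
  # FVA min of the objective equals fraction * optimum
  fvo <- fva(net, fraction = 0.7, reactions = net$objective_id)
  expect_equal(fvo$min, 0.7 * attr(fvo, "objective_value"), tolerance = 1e-5)
})

test_that("coupling classifier separates strong/weak/none", {
  expect_equal(classify_coupling(toyB(), "R_2", "R_p")$class, "weak")
  expect_equal(classify_coupling(toyB(maintenance_lb = 1), "R_2", "R_p")$class,
               "strong")
  expect_equal(classify_coupling(toyB(), character(0), "R_p")$class, "none")
  # monotone in p_min: raising it can only move strong -> weak -> none
  lvl <- c(none = 0, weak = 1, strong = 2)
  m <- toyB(maintenance_lb = 1)
  classes <- vapply(c(1e-4, 0.5, 2, 20), function(p)
    lvl[[classify_coupling(m, "R_2", "R_p", p_min = p)$class]], 0)
  expect_true(all(diff(classes) <= 0))
})
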