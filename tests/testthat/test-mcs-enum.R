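# dual system construction and k-shortest cut set enumeration

test_that("dual system has the Farkas block dimensions", {
  tb <- toyB()
  tgt <- toyB_target(tb)
  dual <- build_dual_system(tb, tgt)
  n <- 7; m <- 4
  expect_length(dual$idx_u, m)
  expect_length(dual$idx_v, n)
  expect_length(dual$idx_h, n)
  # w rows: 2 target rows + one per engaged finite bound (all 7 ubs finite)
  expect_length(dual$idx_w, 2 + 7)
  expect_equal(nrow(dual$A), n + 1)          # reaction rows + witness
  expect_error(build_dual_system(toyA(), tgt), "unknown reactions")
})

test_that("any feasible dual point's support blocks the target", {
  set.seed(12)
  for (seed in c(2, 6, 11)) {
    net <- random_network(4, 3, rev_fraction = ifelse(seed %% 2, 0, 0.3),
                          seed = seed)
    tgt <- build_target_space(net, random_net_params("MCSf"))
    if (!flux_space_feasible(net, tgt)) next
    dual <- build_dual_system(net, tgt)
    # random positive objective pushes towards varied feasible points
    out <- lp_solve(runif(ncol(dual$A)), dual$A, dual$rlb, dual$rub,
                    dual$lb, pmin(dual$ub, 50))
    if (out$status != "optimal") out <- lp_solve(rep(0, ncol(dual$A)),
                                                 dual$A, dual$rlb, dual$rub,
                                                 dual$lb, dual$ub)
    expect_equal(out$status, "optimal")
    supp <- dual_support(dual, out$x)
    expect_gt(length(supp), 0)
    expect_false(flux_space_feasible(net, tgt, supp))
  }
})

test_that("TOY-B enumeration finds exactly the three singletons", {
  tb <- toyB()
  tgt <- toyB_target(tb)
  res <- enumerate_mcs(tb, tgt, max_size = 2)
  expect_equal(res$status, "complete")
  expect_setequal(cutset_keys(res$cutsets), c("R_s", "R_2", "R_bio"))
  sizes <- vapply(res$cutsets, `[[`, 0L, "size")
  expect_true(all(diff(sizes) >= 0))         # non-decreasing ordering
  expect_true(all(vapply(res$cutsets, `[[`, TRUE, "minimal")))
  # soundness: every returned set blocks the target
  for (cs in res$cutsets)
    expect_false(flux_space_feasible(tb, tgt, cs$reactions))

  one <- enumerate_mcs(tb, tgt, max_size = 2, max_solutions = 1)
  expect_length(one$cutsets, 1)
  expect_equal(one$cutsets[[1]]$size, 1L)
  expect_length(enumerate_mcs(tb, tgt, max_size = 0)$cutsets, 0)
})

test_that("verify_minimality reduces supersets and flags non-blockers", {
  tb <- toyB(); tgt <- toyB_target(tb)
  v <- verify_minimality(tb, tgt, "R_2")
  expect_true(v$minimal); expect_true(v$blocking)
  v2 <- verify_minimality(tb, tgt, c("R_2", "R_1"))
  expect_false(v2$minimal)
  expect_equal(v2$reactions, "R_2")
  v3 <- verify_minimality(tb, tgt, character(0))
  expect_false(v3$minimal); expect_false(v3$blocking)
})

test_that("constrain_mcs keeps exactly the non-lethal cut sets", {
  tb <- toyB(); tgt <- toyB_target(tb)
  sets <- enumerate_mcs(tb, tgt, max_size = 2)$cutsets
  desired <- build_desired_space(tb, environment_spec(R_s = c(0, 10)),
                                 min_biomass = 1e-4)
  kept <- constrain_mcs(tb, sets, desired)
  expect_equal(cutset_keys(kept), "R_2")
  expect_true(all(vapply(kept, `[[`, TRUE, "constrained")))
  # vacuous desired space (satisfied even at zero flux) keeps everything
  vac <- linear_flux_space(matrix(coupledesign:::.unit_row(tb, "R_s"), 1), 0)
  expect_length(constrain_mcs(tb, sets, vac), length(sets))
  # all-lethal input
  lethal <- list(cut_set("R_s"), cut_set("R_bio"))
  expect_length(constrain_mcs(tb, lethal, desired), 0)
})

test_that("already-blocked targets short-circuit", {
  tb <- toyB()
  blocked <- linear_flux_space(matrix(coupledesign:::.unit_row(tb, "R_p"), 1),
                               5000)          # beyond any reachable flux
  dual <- build_dual_system(tb, blocked)
  res <- enumerate_shortest(dual, max_size = 2)
  expect_equal(res$status, "target already blocked")
  expect_length(res$cutsets, 0)
})
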