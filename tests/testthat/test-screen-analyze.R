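# filtering and strategy analytics

test_that("filter_strategies keeps the right subset with reasons", {
  tb <- toyB()
  crit <- filter_criteria("R_p")
  out <- filter_strategies(tb, list(character(0), "R_2", "R_s"), crit)
  expect_length(out$kept, 1)
  expect_equal(out$kept[[1]], "R_2")
  expect_equal(out$rejected$reason,
               c("coupling", "growth"))       # wild-type, then R_s
  expect_equal(nrow(filter_strategies(tb, list(), crit)$rejected), 0)
  # idempotence: re-filtering a kept set is the identity
  again <- filter_strategies(tb, out$kept, crit)
  expect_identical(again$kept, out$kept)
  # infeasible mutant fails the environment criterion
  crit2 <- filter_criteria("R_p", env = environment_spec(R_m = c(5, 5)))
  out2 <- filter_strategies(tb, list("R_2", c("R_1", "R_2")), crit2)
  expect_equal(out2$rejected$reason, "environment")
})

test_that("production robustness matches the toy identities", {
  tb <- toyB()
  expect_equal(production_robustness(tb, "R_2", "R_p", 0.9), 9,
               tolerance = 1e-3)
  expect_equal(production_robustness(tb, "R_2", "R_p", 0.01), 0.1,
               tolerance = 1e-3)
  expect_equal(production_robustness(tb, character(0), "R_p", 0.9), 0,
               tolerance = 1e-6)
  # non-decreasing in the growth fraction on a coupled mutant; always >= 0
  vals <- vapply(c(0.01, 0.25, 0.5, 0.9), function(x)
    production_robustness(tb, "R_2", "R_p", x), 0)
  expect_true(all(diff(vals) >= -1e-9))
  expect_true(all(vals >= 0))
})

test_that("BPCY and carbon yield identities", {
  expect_equal(bpcy(10, 10, 10), 10)
  expect_equal(bpcy(0.2, 0.5, 1.15), 0.08696, tolerance = 1e-4)
  expect_equal(bpcy(0, 5, 1), 0)
  expect_error(bpcy(1, 1, 0), "undefined")
  expect_equal(carbon_yield(1, 1.15, 4, 6), 0.5797, tolerance = 1e-4)
  expect_equal(carbon_yield(0, 1.15, 4, 6), 0)
  expect_equal(carbon_yield(1.5, 1, 4, 6), 1)       # conservation bound case
  expect_error(carbon_yield(1, 1, 0, 6), "carbon counts")
  expect_equal(carbon_count("C6H12O6"), 6L)
  expect_equal(carbon_count("CaCl2"), 0L)           # Ca/Cl are not carbon
})

test_that("pathway distributions and deltas follow the counting formula", {
  tb <- toyB()
  pm <- pathway_matrix(data.frame(
    reaction_id = c("R_s", "R_1", "R_2", "R_3"),
    pathway = c("P1", "P1", "P2", "P2")))
  v <- setNames(c(1, 1, 0, 1, 0, 0, 0), tb$reaction_ids)
  expect_equal(pathway_distribution(v, pm), c(P1 = 1.0, P2 = 0.5))
  expect_equal(pathway_distribution(v * 0, pm), c(P1 = 0, P2 = 0))
  expect_equal(pathway_distribution(abs(v) + 1, pm), c(P1 = 1, P2 = 1))
  expect_warning(pathway_matrix(data.frame(reaction_id = "ghost",
                                           pathway = "empty"),
                                reaction_ids = tb$reaction_ids),
                 "without member")
  # delta: wild-type uses R_2 (P2 = 0.5), mutant uses R_3 (P2 = 0.5) -> 0
  wt <- pfba(tb)
  mut <- pfba(apply_knockouts(tb, "R_2"))
  delta <- pathway_delta(list(mut), wt, pm)
  expect_equal(unname(delta["P2"]), 0, tolerance = 1e-9)
  expect_equal(pathway_delta(list(wt), wt, pm),
               c(P1 = 0, P2 = 0))                  # self-difference
  expect_true(all(delta >= -1 & delta <= 1))
})

test_that("knockout frequencies count singles and pairs", {
  kf <- knockout_frequency(list("R_2", c("R_2", "R_s")))
  freq <- setNames(kf$frequency, kf$combo)
  expect_equal(unname(freq["R_2"]), 1.0)
  expect_equal(unname(freq["R_s"]), 0.5)
  expect_equal(unname(freq["R_2+R_s"]), 0.5)
  expect_equal(nrow(knockout_frequency(list())), 0)
  same <- knockout_frequency(rep(list(c("a", "b")), 4))
  expect_true(all(same$frequency == 1))
})

test_that("build_report assembles consistent per-strategy metrics", {
  tb <- toyB()
  crit <- filter_criteria("R_p")
  pm <- pathway_matrix(data.frame(
    reaction_id = c("R_1", "R_3", "R_2"),
    pathway = c("upper", "upper", "lower")))
  rep <- build_report(tb, list("R_2"), crit, "R_s", pmat = pm,
                      carbon = c(R_p = 4, R_s = 6))
  row <- rep$reports[1, ]
  expect_equal(row$max_growth, 10, tolerance = 1e-6)
  expect_equal(row$bpcy, 10, tolerance = 1e-3)
  expect_equal(row$robustness_90, 9, tolerance = 1e-3)
  expect_equal(row$carbon_yield, 10 * 4 / (10 * 6), tolerance = 1e-3)
  expect_equal(row$coupling, "weak")
  # FVA consistency: robustness at 90% cannot exceed the FVA max there
  fv <- fva(apply_knockouts(tb, "R_2"), fraction = 0.9, reactions = "R_p")
  expect_lte(row$robustness_90, fv$max + 1e-6)
  expect_warning(empty <- build_report(tb, list(), crit, "R_s"), "empty")
  expect_equal(nrow(empty$reports), 0)
})
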