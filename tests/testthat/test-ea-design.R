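# SPEA2 fitness, variation operators and candidate evaluation

test_that("evaluate_candidate reproduces the toy objective vectors", {
  tb <- toyB()
  wt <- evaluate_candidate(tb, NULL, character(0), "EAw", "R_p")
  expect_equal(wt$objectives, c(10, 0), tolerance = 1e-4)
  ko <- evaluate_candidate(tb, NULL, "R_2", "EAw", "R_p")
  expect_equal(ko$objectives, c(10, 10), tolerance = 1e-4)
  m <- evaluate_candidate(tb, NULL, "R_2", "EAm", "R_p")
  expect_equal(m$objectives, c(10, 10), tolerance = 1e-4)
  expect_true(m$accepted)
  wtm <- evaluate_candidate(tb, NULL, character(0), "EAm", "R_p")
  expect_false(wtm$accepted)                   # no product at half growth
  dead <- evaluate_candidate(tb, NULL, c("R_2", "R_1"), "EAw", "R_p")
  expect_false(dead$feasible)
  expect_equal(dead$objectives, c(0, 0))
})

test_that("SPEA2 strength and raw fitness match hand enumeration", {
  f <- spea2_fitness(rbind(A = c(1, 1), B = c(2, 2), C = c(1, 2)))
  expect_equal(unname(f$strength), c(0, 2, 1))
  expect_equal(unname(f$raw), c(3, 0, 2))
  # single candidate: nothing dominates it
  expect_equal(spea2_fitness(matrix(c(1, 1), 1))$raw, 0)
  # duplicates never dominate each other
  fd <- spea2_fitness(rbind(c(1, 1), c(1, 1)))
  expect_equal(unname(fd$raw), c(0, 0))
  # dominated candidates score strictly worse than some dominator
  set.seed(3)
  obj <- matrix(runif(40), ncol = 2)
  f2 <- spea2_fitness(obj)
  for (i in seq_len(nrow(obj))) {
    dominators <- which(apply(obj, 1, function(o)
      all(o >= obj[i, ]) && any(o > obj[i, ])))
    if (length(dominators))
      expect_gt(f2$fitness[i], min(f2$fitness[dominators]))
  }
})

test_that("variation respects pool, cap and determinism", {
  cfg <- ea_config("EAw", product_id = "R_p", max_knockouts = 2,
                   mutation_rate = 1, crossover_rate = 1)
  pool <- c("a", "b", "c", "d")
  set.seed(1)
  kids <- vary_offspring(list(c("a", "b"), c("b", "c")), cfg, pool, 50)
  for (k in kids) {
    expect_lte(length(k), 2)
    expect_true(all(k %in% pool))
  }
  # removing from a singleton may yield the wild-type (empty) candidate
  cfg2 <- ea_config("EAw", product_id = "R_p", max_knockouts = 2,
                    mutation_rate = 1, crossover_rate = 0)
  set.seed(2)
  kids2 <- vary_offspring(rep(list("a"), 100), cfg2, pool, 100)
  expect_true(any(lengths(kids2) == 0))
  set.seed(7); a <- vary_offspring(list(c("a", "b")), cfg, pool, 10)
  set.seed(7); b <- vary_offspring(list(c("a", "b")), cfg, pool, 10)
  expect_identical(a, b)
})

test_that("run_ea honours budgets and keeps the archive nondominated", {
  tb <- toyB()
  cfg <- ea_config("EAw", product_id = "R_p", max_knockouts = 3,
                   max_evaluations = 0, pop_size = 10, archive_size = 5,
                   seed = 4)
  r0 <- run_ea(tb, NULL, cfg)      # evaluates only the initial population
  expect_equal(r0$evaluations, 10)
  cfg$max_evaluations <- 300
  r <- run_ea(tb, NULL, cfg)
  expect_lte(r$evaluations, 300)
  objs <- do.call(rbind, lapply(r$archive, `[[`, "objectives"))
  expect_true(all(spea2_fitness(objs)$raw == 0))
  # reproducibility with a fixed seed
  r2 <- run_ea(tb, NULL, cfg)
  expect_identical(lapply(r$archive, `[[`, "knockouts"),
                   lapply(r2$archive, `[[`, "knockouts"))
})

test_that("EAm archives only candidates passing the acceptance test", {
  tb <- toyB()
  cfg <- ea_config("EAm", product_id = "R_p", max_knockouts = 3,
                   max_evaluations = 300, pop_size = 15, archive_size = 8,
                   seed = 6)
  r <- run_ea(tb, NULL, cfg)
  expect_gt(length(r$archive), 0)
  for (cand in r$archive) {
    expect_true(cand$accepted)
    chk <- evaluate_candidate(tb, NULL, cand$knockouts, "EAm", "R_p")
    expect_true(chk$accepted)
  }
})
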