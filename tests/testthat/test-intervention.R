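# target / desired flux spaces and the origin-point rule

test_that("formulation parameter checks name missing entries", {
  expect_error(formulation_params("MCSf", product = "R_p", substrate = "R_s",
                                  s_max = 10), "y_min")
  expect_error(formulation_params("MCSe", product = "R_p", substrate = "R_s",
                                  atpm = "R_m", s_max = 10, y_min = 0.3),
               "m_atp")
  expect_silent(formulation_params("MCSw", product = "R_p", biomass = "R_bio",
                                   F = 0.1))
})

test_that("target spaces encode the formulation rows", {
  tb <- toyB()
  e <- build_target_space(tb, formulation_params(
    "MCSe", product = "R_p", substrate = "R_s", atpm = "R_m",
    s_max = 1.15, y_min = 0.3, m_atp = 1))
  expect_equal(nrow(e$T), 3L)
  expect_equal(e$b, c(0, -1.15, 1))
  expect_equal(unname(e$T[1, c("R_s", "R_p")]), c(0.3, -1))

  f <- build_target_space(tb, formulation_params(
    "MCSf", product = "R_p", substrate = "R_s", s_max = 1.15, y_min = 0.3))
  expect_equal(nrow(f$T), 3L)                       # yield + equality pair
  expect_equal(f$b, c(0, 1.15, -1.15))

  w <- build_target_space(tb, formulation_params(
    "MCSw", product = "R_p", biomass = "R_bio", eps = 1e-4, F = 0.1))
  expect_equal(nrow(w$T), 2L)
  expect_equal(w$b, c(-1e-4, 1), tolerance = 1e-9)  # b_max = 10 from FBA
})

test_that("substrate rows follow the uptake sign convention", {
  tb <- toyB()
  tb$lb["R_s"] <- -1.15; tb$ub["R_s"] <- 0       # BiGG-style exchange
  f <- build_target_space(tb, formulation_params(
    "MCSf", product = "R_p", substrate = "R_s", s_max = 1.15, y_min = 0.3))
  # uptake magnitude = -v_s, so the fixed-rate rows pin v_s = -1.15
  v <- setNames(numeric(7), tb$reaction_ids); v["R_s"] <- -1.15
  expect_true(all(f$T[2:3, ] %*% v >= f$b[2:3] - 1e-9))
})

test_that("sampled vectors satisfy target rows iff the plain condition holds", {
  tb <- toyB()
  tgt <- build_target_space(tb, formulation_params(
    "MCSe", product = "R_p", substrate = "R_s", atpm = "R_m",
    s_max = 10, y_min = 0.3, m_atp = 1))
  set.seed(9)
  for (k in 1:50) {
    v <- setNames(runif(7, 0, 12), tb$reaction_ids)
    plain <- (v["R_p"] / v["R_s"] <= 0.3) && (v["R_s"] <= 10) && (v["R_m"] >= 1)
    rows <- all(tgt$T %*% v >= tgt$b - 1e-12)
    expect_equal(rows, unname(plain))
  }
})

test_that("desired space construction and validation", {
  tb <- toyB()
  d <- build_desired_space(tb, environment_spec(R_s = c(0, 10)),
                           min_biomass = 1e-4)
  expect_equal(nrow(d$T), 3L)        # two finite env bounds + biomass demand
  expect_true(flux_space_feasible(tb, d))
  expect_error(build_desired_space(tb, NULL, min_biomass = 0), "min_biomass")
})

test_that("origin-point rule flags unblockable homogeneous targets", {
  tb <- toyB()
  # product <= eps alone with a non-fixed substrate: origin included
  bad <- linear_flux_space(matrix(-coupledesign:::.unit_row(tb, "R_p"), 1),
                           -1e-4, "homogeneous-ish")
  val <- validate_target_space(tb, bad)
  expect_false(val$valid)
  expect_true(val$origin_included)
  expect_error(enumerate_mcs(tb, bad), "origin")
  # and the oracle agrees: no cut set of any size
  bf <- brute_force_mcs(tb, bad, max_size = 3)
  expect_equal(bf$status, "unblockable")
  expect_length(bf$cutsets, 0)
  # inhomogeneous rows restore validity
  expect_true(validate_target_space(tb, toyB_target())$valid)
  mf <- build_target_space(tb, formulation_params(
    "MCSf", product = "R_p", substrate = "R_s", s_max = 10, y_min = 0.3))
  expect_true(validate_target_space(tb, mf)$valid)
})
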