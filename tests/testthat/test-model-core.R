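# model construction, SBML I/O, splitting, knockouts, environments

test_that("SBML round-trip preserves structure and bounds", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  tb <- toyB()
  write_sbml(tb, tmp)
  m <- load_model(tmp)
  expect_equal(m$reaction_ids, tb$reaction_ids)
  expect_equal(m$metabolite_ids, tb$metabolite_ids)
  expect_equal(unname(m$S), unname(tb$S))
  expect_equal(m$lb, tb$lb)
  expect_equal(m$ub, tb$ub)
  expect_equal(m$objective_id, "R_bio")
  # deterministic ordering: loading twice gives identical matrices
  m2 <- load_model(tmp)
  expect_identical(m$S, m2$S)
})

test_that("toy counts match their definitions", {
  expect_equal(dim(toyA()$S), c(3L, 4L))
  expect_equal(dim(toyB()$S), c(4L, 7L))
  expect_equal(dim(toyC()$S), c(4L, 9L))
})

test_that("missing bounds fall back to COBRA defaults with a warning", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  lines <- readLines(write_sbml(toyA(), tmp))
  lines <- gsub(' fbc:lowerFluxBound="[^"]*" fbc:upperFluxBound="[^"]*"', "", lines)
  lines[grepl('reaction id="R_1"', lines)] <-
    sub('reversible="false"', 'reversible="true"', lines[grepl('reaction id="R_1"', lines)])
  writeLines(lines, tmp)
  expect_warning(m <- load_model(tmp), "defaults")
  expect_equal(unname(m$lb[c("R_s", "R_1")]), c(0, -1000))
  expect_equal(unname(m$ub[c("R_s", "R_1")]), c(1000, 1000))
})

test_that("Level 2 kinetic-law bounds are honoured", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="l2toy"><listOfSpecies>',
    '<species id="A" compartment="c"/><species id="X" compartment="c" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="R_in" reversible="false"><listOfReactants><speciesReference species="X"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A"/></listOfProducts>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="7.5"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '<reaction id="R_out" reversible="true"><listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<kineticLaw><listOfParameters>',
    '<parameter id="LOWER_BOUND" value="-2"/><parameter id="UPPER_BOUND" value="999"/>',
    '</listOfParameters></kineticLaw></reaction>',
    '</listOfReactions></model></sbml>'), tmp)
  m <- load_model(tmp, objective = "R_out")
  expect_equal(m$metabolite_ids, "A")          # boundary species dropped
  expect_equal(unname(m$ub["R_in"]), 7.5)
  expect_equal(unname(m$lb["R_out"]), -2)
  expect_true(reversible(m)["R_out"])
  expect_equal(fba(m)$objective_value, 7.5, tolerance = 1e-9)
})

test_that("format errors and missing objectives are explicit", {
  tmp <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfReac", tmp)   # truncated
  expect_error(load_model(tmp), "format error")
  # file without an objective block
  write_sbml(toyA(), tmp)
  lines <- readLines(tmp)
  writeLines(lines[!grepl("fbc:listOfObjectives|fbc:objective|fluxObjective", lines)], tmp)
  expect_error(load_model(tmp), "no objective")
  expect_equal(load_model(tmp, objective = "R_ex")$objective_id, "R_ex")
})

test_that("split_reversible maps reversible reactions to pairs", {
  tb <- toyB()
  sp0 <- split_reversible(tb)
  expect_equal(length(sp0$model$reaction_ids), 7L)    # nothing reversible
  expect_equal(nrow(sp0$pairing), 0L)

  tb$lb["R_1"] <- -5
  sp <- split_reversible(tb)
  expect_equal(length(sp$model$reaction_ids), 8L)     # 7 - 1 + 2
  expect_equal(nrow(sp$pairing), 1L)
  expect_true(all(sp$model$lb >= 0))
  bwd <- sp$pairing[1, "bwd"]
  expect_equal(unname(sp$model$ub[bwd]), 5)
  expect_equal(unname(sp$model$S[, bwd]), unname(-tb$S[, "R_1"]))
  # fwd - bwd reconstruction
  v <- setNames(numeric(8), sp$model$reaction_ids)
  v[sp$pairing[1, "fwd"]] <- 3; v[sp$pairing[1, "bwd"]] <- 1
  expect_equal(unname(recombine_fluxes(sp, v)["R_1"]), 2)
})

test_that("split model's feasible cone maps onto the original region", {
  set.seed(42)
  net <- random_network(4, 3, rev_fraction = 0.4, seed = 3)
  sp <- split_reversible(net)
  for (k in 1:5) {
    obj <- rnorm(length(net$reaction_ids))
    orig <- coupledesign:::.model_lp(net, obj, "max")
    objsp <- numeric(length(sp$model$reaction_ids))
    for (i in seq_along(objsp)) {
      if (!is.na(sp$fwd_of[i])) objsp[i] <- objsp[i] + obj[match(sp$fwd_of[i], net$reaction_ids)]
      if (!is.na(sp$bwd_of[i])) objsp[i] <- objsp[i] - obj[match(sp$bwd_of[i], net$reaction_ids)]
    }
    split <- coupledesign:::.model_lp(sp$model, objsp, "max")
    expect_equal(split$objval, orig$objval, tolerance = 1e-6)
  }
})

test_that("apply_knockouts zeroes bounds without touching the input", {
  tb <- toyB()
  ko <- apply_knockouts(tb, "R_2")
  expect_equal(unname(ko$lb["R_2"]), 0)
  expect_equal(unname(ko$ub["R_2"]), 0)
  expect_equal(unname(tb$ub["R_2"]), 1000)            # original untouched
  expect_identical(apply_knockouts(tb, character(0)), tb)
  expect_error(apply_knockouts(tb, "nope"), "nope")
})

test_that("set_environment overrides exactly the listed reactions", {
  tb <- toyB()
  env <- environment_spec(R_s = c(-1.15, -1.15))
  m <- set_environment(tb, env)
  expect_equal(unname(m$lb["R_s"]), -1.15)
  expect_equal(unname(m$ub["R_s"]), -1.15)
  expect_equal(m$ub[-1], tb$ub[-1])
  expect_identical(set_environment(tb, NULL), tb)
  expect_error(set_environment(tb, list(R_s = c(2, 1))), "lb > ub")
  expect_error(set_environment(tb, list(ghost = c(0, 1))), "ghost")
  # order independence on disjoint reactions
  a <- set_environment(apply_knockouts(tb, "R_2"), environment_spec(R_s = c(0, 5)))
  b <- apply_knockouts(set_environment(tb, environment_spec(R_s = c(0, 5))), "R_2")
  expect_identical(a, b)
})
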