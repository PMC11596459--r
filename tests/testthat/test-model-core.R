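test_that("reaction formula grammar parses coefficients, sides and arrows", {
  p <- parse_reaction_formula("a -> b")
  expect_equal(p$stoich, c(a = -1, b = 1))
  expect_false(p$reversible)

  p <- parse_reaction_formula("2 h_c + 0.5 o2_c -> h2o_c")
  expect_equal(p$stoich[c("h_c", "o2_c", "h2o_c")],
               c(h_c = -2, o2_c = -0.5, h2o_c = 1))

  p <- parse_reaction_formula("atp_c + thr__L_c <-> adp_c + thrp_c")
  expect_true(p$reversible)
  expect_length(p$stoich, 4)

  # boundary reaction: one empty side
  expect_equal(parse_reaction_formula("prod_c ->")$stoich, c(prod_c = -1))
})

test_that("formula parse errors name the offending position", {
  expect_error(parse_reaction_formula("a + -> b"), "dangling '\\+'")
  expect_error(parse_reaction_formula("a + a -> b"), "duplicate metabolite 'a'")
  expect_error(parse_reaction_formula("two a -> b"), "coefficient")
  expect_error(parse_reaction_formula("a b c -> d"), "unknown token")
  expect_error(parse_reaction_formula("a = b"), "arrow")
})

test_that("type invariants are enforced at construction", {
  expect_error(reaction("r", setNames(numeric(0), character(0))), "non-empty")
  expect_error(reaction("r", c(a = 1), lb = 2, ub = 1), "lower bound")
  expect_error(reaction("r", c(a = 1), ec = "1.2.3"), "malformed EC")
  expect_error(metabolite("m", compartment = ""), "compartment")
  # zero coefficients are dropped, never stored
  r <- reaction("r", c(a = 1, b = 0))
  expect_named(r$stoich, "a")
  # model invariants: unknown metabolite, missing objective
  m1 <- metabolite("a_c")
  expect_error(metabolic_model(list(m1), list(reaction("r", c(zz = 1))), "r"),
               "unknown metabolite")
  expect_error(metabolic_model(list(m1), list(reaction("r", c(a_c = 1))), "nope"),
               "objective")
})

test_that("add_reaction appends one column, defaults bounds by reversibility", {
  model <- chain_model()
  spec <- reaction_spec("1.1.1.1", "new step", "m1_c -> m3_c", id = "NEWR")
  out <- add_reaction(model, spec)
  expect_length(out$reactions, length(model$reactions) + 1)
  expect_equal(dim(stoichiometric_matrix(out)) - dim(stoichiometric_matrix(model)),
               c(0, 1))
  expect_equal(out$reactions$NEWR$lb, 0)
  expect_equal(out$reactions$NEWR$ub, FLUX_MAX)
  rev <- add_reaction(model, reaction_spec("1.1.1.1", "rev", "m1_c <-> m3_c",
                                           id = "REVR"))
  expect_equal(rev$reactions$REVR$lb, -FLUX_MAX)
  # non-destructive: the input model is unchanged
  expect_length(model$reactions, 4)
  expect_error(add_reaction(out, spec), "conflict")
})

test_that("add_reaction creates missing metabolites in a stated compartment", {
  model <- chain_model()
  out <- add_reaction(model, reaction_spec("1.1.1.1", "x", "m1_c -> brandnew_e",
                                           id = "XR"))
  row <- out$metabolites[out$metabolites$id == "brandnew_e", ]
  expect_identical(row$compartment, "e")
})

test_that("adding a reaction never decreases a fixed maximized objective", {
  set.seed(11)
  for (seed in 1:10) {
    model <- make_random_network(4, 6, seed = seed)
    base <- solve_fba(model)$objective_value
    met_pair <- sample(model$metabolites$id, 2)
    spec <- reaction_spec("1.1.1.1", "extra",
                          paste(met_pair[1], "->", met_pair[2]),
                          id = "EXTRA")
    grown <- add_reaction(model, spec)
    expect_gte(solve_fba(grown)$objective_value, base - 1e-6)
  }
})

test_that("knock_out zeroes bounds, errors on unknown ids, is non-destructive", {
  model <- chain_model()
  ko <- knock_out(model, "CONV_1")
  expect_equal(unlist(ko$reactions$CONV_1[c("lb", "ub")], use.names = FALSE),
               c(0, 0))
  expect_equal(model$reactions$CONV_1$ub, FLUX_MAX)
  expect_error(knock_out(model, "NOPE"), "NOPE")
  # empty set is the identity
  expect_true(model_equal(knock_out(model, character(0)), model))
  # deleting the only route to the objective forces optimum 0
  expect_equal(solve_fba(ko)$objective_value, 0, tolerance = 1e-12)
})

test_that("optima are non-increasing under knockout-set inclusion", {
  set.seed(12)
  for (seed in 1:8) {
    model <- make_random_network(4, 8, seed = seed)
    deletable <- setdiff(names(model$reactions), c("EX_in", "EX_out"))
    a <- sample(deletable, 1)
    b <- c(a, sample(setdiff(deletable, a), 1))
    opt0 <- solve_fba(model)$objective_value
    optA <- solve_fba(knock_out(model, a))$objective_value
    optB <- solve_fba(knock_out(model, b))$objective_value
    expect_lte(optA, opt0 + 1e-6)
    expect_lte(optB, optA + 1e-6)
  }
})

test_that("add_reaction then knock_out restores the original optimum", {
  toy <- make_toy_model(toy_spec(knockin_bypass = FALSE))
  base <- solve_fba(toy$model, "DM_prod_c")$objective_value
  spec <- reaction_spec("1.1.1.1", "shortcut", "a_c -> prod_c", id = "SHORT")
  grown <- add_reaction(toy$model, spec)
  again <- solve_fba(knock_out(grown, "SHORT"), "DM_prod_c")$objective_value
  expect_lt(abs(again - base), 1e-6)
})

test_that("EC lookup matches annotations, splits compound queries, validates", {
  model <- chain_model()
  model$reactions$CONV_1$ec <- "1.4.4.2"
  model$reactions$CONV_2$ec <- c("1.2.4.2", "5.5.5.5")
  expect_identical(find_reactions_by_ec(model, "1.4.4.2"), "CONV_1")
  expect_identical(find_reactions_by_ec(model, "9.9.9.9"), character(0))
  # compound entry: union of matches for both ECs
  hits <- find_reactions_by_ec(model, "1.8.1.4-1.2.4.2")
  expect_identical(hits, "CONV_2")
  hits2 <- find_reactions_by_ec(model, "1.4.4.2/1.2.4.2")
  expect_setequal(hits2, c("CONV_1", "CONV_2"))
  expect_error(find_reactions_by_ec(model, "not-an-ec"), "malformed EC")
  # every returned reaction is in the model and carries a queried EC
  for (h in hits2) {
    expect_true(h %in% names(model$reactions))
    expect_true(length(intersect(model$reactions[[h]]$ec,
                                 c("1.4.4.2", "1.2.4.2"))) > 0)
  }
})
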