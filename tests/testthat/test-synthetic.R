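test_that("toy analytic optima are reproduced by the solver", {
  grid <- list(
    toy_spec(uptake_rate = 10, competitor_capacity = 0),
    toy_spec(uptake_rate = 10, competitor_forced = 4, competitor_capacity = 5),
    toy_spec(n_pathway_steps = 1, uptake_rate = 3),
    toy_spec(n_pathway_steps = 6, uptake_rate = 2.5, competitor_forced = 1,
             competitor_capacity = 2),
    toy_spec(uptake_rate = 10, knockin_bypass = TRUE, bypass_capacity = 2),
    toy_spec(uptake_rate = 4, competitor_forced = 4, competitor_capacity = 6,
             knockin_bypass = TRUE, bypass_capacity = 1))
  for (spec in grid) {
    toy <- make_toy_model(spec)
    got_b <- solve_fba(toy$model)
    got_p <- solve_fba(toy$model, toy$product_objective)
    expect_equal(got_b$objective_value, toy$expected_optima$biomass,
                 tolerance = 1e-6)
    expect_equal(got_p$objective_value, toy$expected_optima$product,
                 tolerance = 1e-6)
  }
})

test_that("the knockin bypass raises the product optimum by its capacity", {
  without <- make_toy_model(toy_spec(uptake_rate = 10))
  with_bp <- make_toy_model(toy_spec(uptake_rate = 10, knockin_bypass = TRUE,
                                     bypass_capacity = 2))
  v0 <- solve_fba(without$model, "DM_prod_c")$objective_value
  v1 <- solve_fba(with_bp$model, "DM_prod_c")$objective_value
  expect_gt(v1, v0)
  expect_equal(v1 - v0, 2, tolerance = 1e-6)
})

test_that("infeasible toy specs are rejected", {
  expect_error(toy_spec(uptake_rate = 3, competitor_forced = 4,
                        competitor_capacity = 6), "exceeds the uptake")
  expect_error(toy_spec(competitor_forced = 4, competitor_capacity = 2),
               "capacity")
  expect_error(toy_spec(uptake_rate = 0), "uptake_rate")
})

test_that("toy generation is deterministic and seed only permutes storage", {
  a <- make_toy_model(toy_spec(seed = 5))
  b <- make_toy_model(toy_spec(seed = 5))
  expect_identical(names(a$model$reactions), names(b$model$reactions))
  expect_true(model_equal(a$model, b$model))
  c2 <- make_toy_model(toy_spec(seed = 9))
  expect_true(model_equal(a$model, c2$model))  # same network, any seed
})

test_that("random networks are reproducible, connected and well-formed", {
  a <- make_random_network(5, 9, seed = 4)
  b <- make_random_network(5, 9, seed = 4)
  expect_true(model_equal(a, b))
  expect_identical(names(a$reactions), names(b$reactions))
  expect_length(a$reactions, 9)
  expect_equal(nrow(a$metabolites), 5)
  # every internal metabolite appears in at least two reactions
  S <- as.matrix(stoichiometric_matrix(a))
  internal <- setdiff(rownames(S), c())
  usage <- rowSums(S != 0)
  expect_true(all(usage >= 2))
  expect_error(make_random_network(1, 5), "unsatisfiable")
  expect_error(make_random_network(4, 4), "unsatisfiable")
})

test_that("bounded random networks never yield unbounded LPs", {
  set.seed(99)
  for (seed in 1:100) {
    model <- make_random_network(sample(2:6, 1), sample(8:12, 1), seed = seed)
    sol <- solve_fba(model)
    expect_true(sol$status %in% c("optimal", "infeasible"))
    expect_identical(sol$status, "optimal")  # all-finite bounds, 0 feasible
  }
})
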