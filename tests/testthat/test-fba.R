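test_that("a bound-limited linear chain attains its uptake rate", {
  model <- chain_model(n_mets = 3, uptake = 10)
  sol <- solve_fba(model)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes[sol$objective_reaction_id]),
               sol$objective_value, tolerance = 1e-9)
})

test_that("with all exchange lower bounds at zero the optimum is zero", {
  toy <- make_toy_model(toy_spec())$model
  for (rid in names(toy$reactions)) {
    if (is_exchange(toy$reactions[[rid]]) && toy$reactions[[rid]]$lb < 0)
      toy$reactions[[rid]]$lb <- 0
  }
  expect_equal(solve_fba(toy)$objective_value, 0, tolerance = 1e-12)
  expect_equal(solve_fba(toy, "DM_prod_c")$objective_value, 0, tolerance = 1e-12)
})

test_that("objective resolution handles declared, id, and EC forms", {
  toy <- make_toy_model(toy_spec())$model
  expect_identical(resolve_objective(toy, NULL), "BIOMASS")
  expect_identical(resolve_objective(toy, "biomass"), "BIOMASS")
  expect_identical(resolve_objective(toy, "COMP"), "COMP")
  expect_identical(resolve_objective(toy, "ec:9.1.1.1"), "COMP")
  expect_error(resolve_objective(toy, "NOPE"), "not in model")
  expect_error(resolve_objective(toy, "ec:7.7.7.7"), "no reaction")
})

test_that("ensure_product_sink adds a drain only when none exists", {
  toy <- make_toy_model(toy_spec(product_sink = FALSE))
  model <- toy$model
  # dead-end product: flux cannot reach it at steady state
  expect_equal(solve_fba(model, toy$product_objective)$objective_value, 0,
               tolerance = 1e-12)
  with_sink <- ensure_product_sink(model, "prod_c")
  expect_length(with_sink$reactions, length(model$reactions) + 1)
  expect_equal(solve_fba(with_sink, "DM_prod_c")$objective_value,
               toy$spec$uptake_rate, tolerance = 1e-6)
  # idempotent: a second call adds nothing
  twice <- ensure_product_sink(with_sink, "prod_c")
  expect_true(model_equal(twice, with_sink))
  # a metabolite with an existing exchange is left alone
  expect_true(model_equal(ensure_product_sink(model, "w_c"), model))
  expect_error(ensure_product_sink(model, "ghost_c"), "unknown metabolite")
})

test_that("prepare_product_objective drains dead-end products of the target", {
  toy <- make_toy_model(toy_spec(product_sink = FALSE))
  prep <- prepare_product_objective(toy$model, toy$product_objective)
  expect_identical(prep$objective, toy$product_objective)
  sol <- solve_fba(prep$model, prep$objective)
  expect_equal(sol$objective_value, toy$spec$uptake_rate, tolerance = 1e-6)
})

test_that("micromole reporting is a pure x1000 rescale", {
  expect_equal(report_in_micromol(0), 0)
  expect_equal(report_in_micromol(3.59e-4), 0.359)
  expect_equal(report_in_micromol(2.83e-5), 2.83e-2)
  expect_error(report_in_micromol(Inf))
})

test_that("flux_solution accessors and serializers are consistent", {
  model <- chain_model()
  sol <- solve_fba(model)
  expect_s3_class(sol, "flux_solution")
  expect_equal(coef(sol), sol$fluxes)
  df <- as.data.frame(sol)
  expect_identical(df$reaction_id, names(sol$fluxes))
  tf <- tempfile(fileext = ".tsv"); write_flux_tsv(sol, tf)
  back <- read.delim(tf)
  expect_equal(back$flux, unname(sol$fluxes), tolerance = 1e-12)
  tj <- tempfile(fileext = ".json"); write_flux_json(sol, tj)
  j <- jsonlite::read_json(tj)
  expect_equal(j$objective_value, sol$objective_value)
  expect_output(print(sol), "optimal")
  expect_output(print(summary(sol)), "carry flux")
  unlink(c(tf, tj))
})
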