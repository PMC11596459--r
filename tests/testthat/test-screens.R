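test_that("deletion-set enumeration has the exact subset counts and order", {
  sets <- enumerate_deletion_sets(vector("list", 4), 2)
  expect_length(sets, choose(4, 1) + choose(4, 2))  # 10
  # size-then-lexicographic order, each subset once
  expect_identical(sets[[1]], 1L)
  expect_identical(sets[[5]], c(1L, 2L))
  expect_identical(sets[[10]], c(3L, 4L))
  expect_false(any(duplicated(lapply(sets, paste, collapse = ","))))
  expect_error(enumerate_deletion_sets(vector("list", 4), 0), "between")
  expect_error(enumerate_deletion_sets(vector("list", 4), 5), "between")
})

test_that("the deletion screen recovers the planted best subsets, matching a
          brute-force reference", {
  toy <- planted_deletion_toy(uptake = 10, forced = c(2, 1, 0))
  res <- run_deletion_screen(toy$model, empty_medium(), toy$candidates,
                             max_size = 3,
                             product_objective = toy$product_objective)
  expect_equal(nrow(res), 7)  # C(3,1)+C(3,2)+C(3,3)
  # planted optimum: deleting both forced branches recovers all uptake;
  # the size-2 set outranks the tied size-3 superset
  expect_identical(res$intervention[1], "branch1 + branch2")
  expect_equal(res$b12_umol[1], report_in_micromol(10), tolerance = 1e-3)
  expect_identical(res$intervention[2], "branch1 + branch2 + branch3")
  # baseline reported separately, never as a subset row
  expect_false(any(res$size == 0))
  base <- attr(res, "baseline")
  expect_equal(base$b12_umol, report_in_micromol(7), tolerance = 1e-3)
  # biomass untouched by any deletion in this topology
  expect_true(all(abs(res$biomass - 5) < 1e-6))

  # independent brute force: same values, same ranking
  resolved <- resolve_candidates(toy$model, toy$candidates)
  ref <- brute_force_deletion_reference(toy$model, resolved, 3,
                                        toy$product_objective)
  ref <- ref[order(-ref$b12_umol, ref$size, ref$labels, method = "radix"), ]
  expect_equal(res$intervention, ref$labels)
  expect_equal(res$b12_umol, ref$b12_umol, tolerance = 1e-6)
})

test_that("screens are deterministic: identical inputs, byte-identical tables", {
  toy <- planted_deletion_toy()
  run <- function() {
    res <- run_deletion_screen(toy$model, empty_medium(), toy$candidates, 2,
                               product_objective = toy$product_objective)
    tf <- tempfile(fileext = ".tsv")
    write_screen_tsv(res, tf)
    on.exit(unlink(tf))
    readLines(tf)
  }
  expect_identical(run(), run())
})

test_that("candidate resolution honours compound ECs and unresolved policy", {
  toy <- planted_deletion_toy()
  cand <- deletion_candidate("both", "8.1.1.1-8.2.2.2")
  resolved <- resolve_candidates(toy$model, list(cand))
  expect_setequal(resolved$both, c("COMP1", "COMP2"))
  ghost <- deletion_candidate("ghost", "7.7.7.7")
  expect_error(resolve_candidates(toy$model, list(ghost)), "ghost")
  expect_warning(r2 <- resolve_candidates(toy$model, list(cand, ghost),
                                          on_unresolved = "skip"), "skipped")
  expect_named(r2, "both")
})

test_that("the knockin screen reports baseline plus variants in input order
          and recovers the analytic bypass improvement", {
  toy <- make_toy_model(toy_spec(uptake_rate = 10, knockin_bypass = FALSE,
                                 competitor_capacity = 0))
  bypass <- curation_bundle("bypass", list(
    reaction_spec("9.2.1.1", "bypass supply", "-> y_c", id = "EX_y_c"),
    reaction_spec("9.2.1.2", "bypass entry", "y_c -> a_c", id = "BYPASS")))
  res <- run_knockin_screen(toy$model, empty_medium(), list(list(bypass)),
                            product_objective = toy$product_objective)
  expect_identical(res$intervention[1], "none")
  expect_equal(res$b12_umol[1], report_in_micromol(10), tolerance = 1e-3)
  # the new supply route raises the product optimum
  expect_gt(res$b12_umol[2], res$b12_umol[1])
  # biomass is unchanged by the knockin (growth neutrality)
  expect_lt(abs(res$biomass[2] - res$biomass[1]), 1e-6)
})

test_that("knockin improvement percentage matches the closed form", {
  spec0 <- toy_spec(uptake_rate = 10, competitor_capacity = 0)
  spec1 <- toy_spec(uptake_rate = 10, competitor_capacity = 0,
                    knockin_bypass = TRUE, bypass_capacity = 2)
  v0 <- solve_fba(make_toy_model(spec0)$model, "DM_prod_c")$objective_value
  v1 <- solve_fba(make_toy_model(spec1)$model, "DM_prod_c")$objective_value
  expect_equal(percent_increase(v1, v0), 100 * 2 / 10, tolerance = 1e-6)
})

test_that("screen failures are recorded per-variant, not fatal", {
  toy <- make_toy_model(toy_spec())
  broken <- curation_bundle("broken", list(
    reaction_spec("1.1.1.1", "dup of COMP", "a_c -> w_c", id = "COMP")))
  res <- run_knockin_screen(toy$model, empty_medium(), list(list(broken)),
                            product_objective = toy$product_objective)
  expect_identical(res$status_b12[2], "error")
  expect_true(is.na(res$b12_umol[2]))
  expect_identical(res$status_b12[1], "optimal")
})

test_that("summaries report per-size counts, bests and near-zero fraction", {
  toy <- planted_deletion_toy()
  res <- run_deletion_screen(toy$model, empty_medium(), toy$candidates, 3,
                             product_objective = toy$product_objective)
  sm <- summarize_screen(res)
  expect_equal(sm$per_size$n, c(3, 3, 1))
  expect_identical(sm$best$intervention, "branch1 + branch2")
  expect_equal(sm$frac_near_zero, 0)
  expect_output(print(sm), "best:")
  one <- summarize_screen(res[1, ])
  expect_identical(one$best$intervention, res$intervention[1])
  # all-failed screens have no defined best and are flagged
  allna <- res; allna$b12_umol <- NA_real_
  smna <- summarize_screen(allna)
  expect_true(smna$all_failed)
  expect_null(smna$best)
  expect_error(summarize_screen(res[0, ]), "empty")
})
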