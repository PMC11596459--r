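# Small model builders shared across tests.

# linear chain: EX_in (lb = -uptake) -> m1 -> ... -> mn -> EX_out (objective)
chain_model <- function(n_mets = 3, uptake = 10) {
  mets <- sprintf("m%d_c", seq_len(n_mets))
  rxns <- list(reaction("EX_in", setNames(-1, mets[1]), lb = -uptake,
                        ub = FLUX_MAX))
  for (i in seq_len(n_mets - 1)) {
    rxns <- c(rxns, list(reaction(sprintf("CONV_%d", i),
                                  setNames(c(-1, 1), mets[c(i, i + 1)]))))
  }
  rxns <- c(rxns, list(reaction("EX_out", setNames(-1, mets[n_mets]),
                                lb = 0, ub = FLUX_MAX)))
  metabolic_model(lapply(mets, metabolite), rxns, objective = "EX_out",
                  id = "chain")
}

# toy with three EC-annotated competitor branches; deleting branch k recovers
# its forced drain, so the best deletion sets are known analytically
planted_deletion_toy <- function(uptake = 10, forced = c(2, 1, 0),
                                 capacity = c(3, 3, 3)) {
  rxns <- list(
    reaction("EX_a_c", c(a_c = -1), lb = -uptake, ub = FLUX_MAX),
    reaction("PATH", c(a_c = -1, prod_c = 1)),
    reaction("DM_prod_c", c(prod_c = -1)),
    reaction("EX_s_c", c(s_c = -1), lb = -5, ub = FLUX_MAX),
    reaction("BIOMASS", c(s_c = -1)))
  ecs <- c("8.1.1.1", "8.2.2.2", "8.3.3.3")
  for (k in 1:3) {
    wk <- sprintf("w%d_c", k)
    rxns <- c(rxns, list(
      reaction(sprintf("COMP%d", k), setNames(c(-1, 1), c("a_c", wk)),
               lb = forced[k], ub = capacity[k], ec = ecs[k]),
      reaction(sprintf("EX_w%d_c", k), setNames(-1, wk))))
  }
  mets <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  model <- metabolic_model(lapply(mets, metabolite), rxns,
                           objective = "BIOMASS", id = "planted")
  candidates <- lapply(1:3, function(k)
    deletion_candidate(sprintf("branch%d", k), ecs[k]))
  list(model = model, candidates = candidates, forced = forced,
       product_objective = "DM_prod_c", uptake = uptake)
}

empty_medium <- function() medium_spec()
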