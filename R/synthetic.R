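# Toy-network generators. The toys mirror the structural features the
# pipeline relies on -- an uptake-limited precursor, a linear multi-step
# product pathway, a competing branch draining the shared precursor, an
# optional knockin bypass supplying extra precursor, and an independent
# biomass branch -- with FBA optima that are known in closed form, so the LP
# engine and both screens can be validated without a genome-scale model.

#' Specification of a toy vitamin-pathway network
#'
#' @param n_pathway_steps number of enzymatic steps from precursor to product
#'   (>= 1).
#' @param uptake_rate precursor uptake bound (mmol/gDW/h, > 0).
#' @param competitor_capacity maximum flux the competing branch can drain
#'   (>= 0).
#' @param competitor_forced flux the competing branch is forced to carry
#'   (its lower bound); must not exceed `competitor_capacity` nor
#'   `uptake_rate`.
#' @param knockin_bypass add a second precursor-supply route (a knockin)?
#' @param bypass_capacity uptake bound of the bypass route.
#' @param biomass_uptake uptake bound of the dedicated biomass substrate; the
#'   biomass optimum equals this value and is independent of the product
#'   pathway by construction.
#' @param product_sink include the terminal demand reaction for the product?
#'   With `FALSE` the product is a dead end and its optimum is 0 until
#'   [ensure_product_sink()] is applied.
#' @param seed integer; only permutes storage order (a structure-neutral
#'   decoration), never the network itself.
#' @return a `toy_spec`.
#' @export
toy_spec <- function(n_pathway_steps = 3, uptake_rate = 10,
                     competitor_capacity = 5, competitor_forced = 0,
                     knockin_bypass = FALSE, bypass_capacity = 2,
                     biomass_uptake = 5, product_sink = TRUE, seed = 1L) {
  stopifnot(n_pathway_steps >= 1, uptake_rate > 0, competitor_capacity >= 0,
            biomass_uptake > 0, bypass_capacity >= 0)
  if (competitor_forced < 0 || competitor_forced > competitor_capacity)
    stop("infeasible toy spec: forced competitor flux outside [0, capacity]")
  if (competitor_forced > uptake_rate)
    stop("infeasible toy spec: forced competitor flux exceeds the uptake rate")
  structure(as.list(environment()), class = "toy_spec")
}

#' Build a toy model with analytically known FBA optima
#'
#' @param spec a [toy_spec()].
#' @return list with `model` (a `metabolic_model`, biomass objective),
#'   `expected_optima` (named list `biomass`, `product`, computed in closed
#'   form from the spec, never from an LP), `product_objective` (reaction id
#'   of the product drain) and `competitor_reaction`/`bypass_reaction` ids.
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_pathway_steps
  path_mets <- if (n >= 2) paste0("p", seq_len(n - 1), "_c") else character(0)
  chain <- c("a_c", path_mets, "prod_c")
  rxns <- list(
    reaction("EX_a_c", c(a_c = -1), lb = -spec$uptake_rate, ub = FLUX_MAX,
             name = "precursor exchange"),
    reaction("COMP", c(a_c = -1, w_c = 1), lb = spec$competitor_forced,
             ub = spec$competitor_capacity, name = "competing branch",
             ec = "9.1.1.1"),
    reaction("EX_w_c", c(w_c = -1), lb = 0, ub = FLUX_MAX,
             name = "competitor export"),
    reaction("EX_s_c", c(s_c = -1), lb = -spec$biomass_uptake, ub = FLUX_MAX,
             name = "biomass substrate exchange"),
    reaction("BIOMASS", c(s_c = -1), lb = 0, ub = FLUX_MAX,
             name = "biomass pseudo-reaction")
  )
  for (i in seq_len(n)) {
    st <- setNames(c(-1, 1), c(chain[i], chain[i + 1]))
    rxns <- c(rxns, list(reaction(sprintf("PATH_%d", i), st,
                                  name = sprintf("pathway step %d", i))))
  }
  if (spec$product_sink) {
    rxns <- c(rxns, list(reaction("DM_prod_c", c(prod_c = -1), lb = 0,
                                  ub = FLUX_MAX, name = "product demand")))
  }
  if (spec$knockin_bypass) {
    rxns <- c(rxns, list(
      reaction("EX_y_c", c(y_c = -1), lb = -spec$bypass_capacity,
               ub = FLUX_MAX, name = "bypass supply exchange"),
      reaction("BYPASS", c(y_c = -1, a_c = 1), lb = 0, ub = FLUX_MAX,
               name = "knockin bypass", ec = "9.2.1.1")))
  }
  met_ids <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  mets <- lapply(met_ids, metabolite)
  # seed only shuffles storage order; the network is spec-determined
  perm <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    sample(length(rxns))
  })
  model <- metabolic_model(mets, rxns[perm], objective = "BIOMASS",
                           id = "toy_b12")
  product <- if (spec$product_sink) {
    spec$uptake_rate - spec$competitor_forced +
      if (spec$knockin_bypass) spec$bypass_capacity else 0
  } else 0
  list(model = model,
       expected_optima = list(biomass = spec$biomass_uptake, product = product),
       product_objective = if (spec$product_sink) "DM_prod_c"
                           else sprintf("PATH_%d", n),
       competitor_reaction = "COMP",
       bypass_reaction = if (spec$knockin_bypass) "BYPASS" else NULL,
       spec = spec)
}

#' Generate a random connected mass-balanced network
#'
#' A deterministic backbone (uptake exchange, a conversion chain visiting
#' every metabolite, an export exchange) guarantees connectivity and one
#' boundary reaction in each direction; the remaining reaction budget is
#' spent on random 1:1 conversions. All coefficients are +-1, so every
#' internal reaction conserves the (unit) toy mass, and all bounds are
#' finite, so the LP is never unbounded. Requires
#' `n_reactions >= n_metabolites + 1` (the backbone alone uses
#' `n_metabolites + 1` reactions).
#'
#' @param n_metabolites number of metabolites (>= 2).
#' @param n_reactions number of reactions (>= `n_metabolites + 1`).
#' @param seed RNG seed; same seed gives a structurally identical model.
#' @return a `metabolic_model` with the export exchange as objective.
#' @export
make_random_network <- function(n_metabolites, n_reactions, seed = 1L) {
  if (n_metabolites < 2) stop("unsatisfiable sizes: need >= 2 metabolites")
  if (n_reactions < n_metabolites + 1)
    stop("unsatisfiable sizes: a connected network with uptake and export ",
         "needs at least n_metabolites + 1 reactions")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  met_ids <- sprintf("m%d_c", seq_len(n_metabolites))
  rxns <- list(reaction("EX_in", setNames(-1, met_ids[1]), lb = -10,
                        ub = FLUX_MAX, name = "uptake"))
  for (i in seq_len(n_metabolites - 1)) {
    st <- setNames(c(-1, 1), met_ids[c(i, i + 1)])
    rxns <- c(rxns, list(reaction(sprintf("CONV_%d", i), st)))
  }
  rxns <- c(rxns, list(reaction("EX_out", setNames(-1, met_ids[n_metabolites]),
                                lb = 0, ub = FLUX_MAX, name = "export")))
  n_extra <- n_reactions - length(rxns)
  for (t in seq_len(n_extra)) {
    ij <- sample(n_metabolites, 2)
    st <- setNames(c(-1, 1), met_ids[ij])
    rxns <- c(rxns, list(reaction(sprintf("RND_%d", t), st)))
  }
  metabolic_model(lapply(met_ids, metabolite), rxns, objective = "EX_out",
                  id = sprintf("random_%d_%d_seed%d", n_metabolites,
                               n_reactions, seed))
}
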