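# Structural edits. All edits are copy-on-write: R's value semantics mean the
# input model is never mutated, so screens over many variants stay independent.

#' Create a reaction specification
#'
#' An EC-annotated reaction formula, the unit of model curation and knockin.
#'
#' @param ec EC number in dotted notation.
#' @param name display name of the enzyme/reaction.
#' @param formula reaction formula in the syntax of [parse_reaction_formula()].
#' @param reversible logical; overrides the arrow in `formula` when given.
#' @param source provenance note (e.g. a KEGG reaction id).
#' @param id reaction id to use in the model; defaults to a slug of `name`.
#' @return a `reaction_spec`.
#' @export
reaction_spec <- function(ec, name, formula, reversible = NULL, source = "",
                          id = NULL) {
  if (!grepl(ec_pattern, ec)) stop("malformed EC number: '", ec, "'")
  parsed <- parse_reaction_formula(formula)  # errors here fail the invariant
  id <- id %||% toupper(gsub("[^A-Za-z0-9]+", "_", name))
  structure(list(ec = ec, name = name, formula = formula,
                 reversible = reversible %||% parsed$reversible,
                 source = source, id = id),
            class = "reaction_spec")
}

#' Add a reaction to a model
#'
#' Metabolites referenced by the spec that are absent from the model are
#' created (compartment from the id suffix, else `compartment`). The input
#' model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param spec a [reaction_spec()].
#' @param bounds optional numeric pair `c(lb, ub)`; defaults to `(0, FLUX_MAX)`
#'   for irreversible and `(-FLUX_MAX, FLUX_MAX)` for reversible reactions.
#' @param compartment fallback compartment for newly created metabolites.
#' @return the extended model.
#' @export
add_reaction <- function(model, spec, bounds = NULL, compartment = "c") {
  stopifnot(inherits(spec, "reaction_spec"))
  if (spec$id %in% names(model$reactions))
    stop("reaction id conflict: '", spec$id, "' already in model")
  parsed <- parse_reaction_formula(spec$formula)
  if (is.null(bounds)) {
    bounds <- if (isTRUE(spec$reversible)) c(-FLUX_MAX, FLUX_MAX) else c(0, FLUX_MAX)
  }
  new_mets <- setdiff(names(parsed$stoich), model$metabolites$id)
  for (mid in new_mets) {
    comp <- if (grepl("_([a-z][a-z0-9]?)$", mid)) guess_compartment(mid) else compartment
    model$metabolites <- rbind(model$metabolites,
                               data.frame(id = mid, name = mid, compartment = comp,
                                          stringsAsFactors = FALSE))
  }
  rxn <- reaction(spec$id, parsed$stoich, lb = bounds[1], ub = bounds[2],
                  name = spec$name, ec = spec$ec)
  model$reactions[[spec$id]] <- rxn
  model
}

#' Knock out reactions
#'
#' Simulates enzyme loss by constraining the listed reactions to zero flux
#' (bounds `(0, 0)`); everything else is untouched. Non-destructive.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids character vector of reaction ids.
#' @return the constrained model.
#' @export
knock_out <- function(model, reaction_ids) {
  unknown <- setdiff(reaction_ids, names(model$reactions))
  if (length(unknown))
    stop("cannot knock out unknown reaction(s): ", paste(unknown, collapse = ", "))
  for (rid in reaction_ids) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  model
}

#' Find reactions by EC number
#'
#' Compound queries like `"1.8.1.4-1.2.4.2"` (hyphen, en-dash or slash
#' separated) match reactions annotated with any of the listed ECs.
#'
#' @param model a `metabolic_model`.
#' @param ec EC query string.
#' @return character vector of matching reaction ids (possibly empty).
#' @export
find_reactions_by_ec <- function(model, ec) {
  ecs <- split_ec_query(ec)
  hits <- vapply(model$reactions,
                 function(r) length(intersect(r$ec, ecs)) > 0L, TRUE)
  names(model$reactions)[hits]
}

#' Split a possibly compound EC query into individual EC numbers
#' @param ec query string, e.g. `"1.8.1.4-1.2.4.2"`.
#' @return character vector of validated EC numbers.
#' @export
split_ec_query <- function(ec) {
  stopifnot(is.character(ec), length(ec) == 1L)
  parts <- trimws(strsplit(ec, "[-–/]")[[1]])
  bad <- parts[!grepl(ec_pattern, parts)]
  if (length(bad))
    stop("malformed EC number(s) in query '", ec, "': ",
         paste(bad, collapse = ", "))
  parts
}

#' Ensure a metabolite has a drain
#'
#' Steady state forces zero net accumulation, so flux can only enter a
#' terminal product if some boundary reaction drains it. If no reaction can
#' already drain `metabolite_id`, a demand reaction `DM_<id>: met ->` with
#' bounds `(0, FLUX_MAX)` is added; otherwise the model is returned unchanged
#' (idempotent).
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite to drain.
#' @return the (possibly extended) model.
#' @export
ensure_product_sink <- function(model, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id)
    stop("unknown metabolite: '", metabolite_id, "'")
  for (r in model$reactions) {
    if (!is_exchange(r)) next
    if (names(r$stoich) != metabolite_id) next
    co <- unname(r$stoich)
    # can the reaction carry flux that removes the metabolite?
    if ((co < 0 && r$ub > 0) || (co > 0 && r$lb < 0)) return(model)
  }
  rid <- paste0("DM_", metabolite_id)
  if (rid %in% names(model$reactions))
    stop("reaction id conflict: '", rid, "' exists but cannot drain '",
         metabolite_id, "'")
  model$reactions[[rid]] <- reaction(rid, setNames(-1, metabolite_id),
                                     lb = 0, ub = FLUX_MAX,
                                     name = paste("demand:", metabolite_id))
  model
}
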