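#' @importFrom stats coef setNames
#' @importFrom utils combn head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default flux bound magnitude (mmol/gDW/h)
#'
#' Community convention for genome-scale models: reactions are "unbounded" at
#' +/-1000 mmol/gDW/h unless a measured rate constrains them.
#' @export
FLUX_MAX <- 1000

ec_pattern <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

#' Create a metabolite
#'
#' @param id unique metabolite identifier (BIGG style, compartment suffix
#'   such as `"_c"` is conventional but not required).
#' @param name human-readable name.
#' @param compartment compartment identifier, e.g. `"c"` (cytosol).
#' @return a `metabolite` list.
#' @export
metabolite <- function(id, name = id, compartment = guess_compartment(id)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!nzchar(compartment)) stop("metabolite '", id, "': compartment must be non-empty")
  structure(list(id = id, name = name, compartment = compartment),
            class = "metabolite")
}

# "_c" / "_e" style suffix, else cytosol
guess_compartment <- function(id) {
  m <- regmatches(id, regexpr("_([a-z][a-z0-9]?)$", id))
  if (length(m) == 1L && nzchar(m)) sub("^_", "", m) else "c"
}

#' Create a reaction
#'
#' Stoichiometry uses the signed convention of the stoichiometric matrix:
#' negative coefficients consume, positive produce. Exchange reactions are
#' single-metabolite boundary drains; negative flux through them is uptake.
#'
#' @param id unique reaction identifier.
#' @param stoich named numeric vector, metabolite id -> signed coefficient;
#'   zero entries are dropped.
#' @param lb,ub flux bounds (mmol/gDW/h), `lb <= ub`.
#' @param name human-readable name.
#' @param ec character vector of EC numbers annotating the reaction.
#' @return a `reaction` list.
#' @export
reaction <- function(id, stoich, lb = 0, ub = FLUX_MAX, name = id,
                     ec = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) stop("reaction '", id, "': stoichiometry must be non-empty")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "': stoichiometry must be named by metabolite id")
  if (anyDuplicated(names(stoich)))
    stop("reaction '", id, "': duplicate metabolite in stoichiometry")
  if (lb > ub) stop("reaction '", id, "': lower bound exceeds upper bound")
  ec <- as.character(ec)
  bad <- ec[!grepl(ec_pattern, ec)]
  if (length(bad)) stop("reaction '", id, "': malformed EC number(s): ",
                        paste(bad, collapse = ", "))
  structure(list(id = id, name = name, ec = ec, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub)),
            class = "reaction")
}

#' Is a reaction a boundary (exchange/demand/sink) reaction?
#' @param rxn a `reaction`.
#' @return logical.
#' @export
is_exchange <- function(rxn) length(rxn$stoich) == 1L

#' Assemble a metabolic model
#'
#' @param metabolites list of [metabolite()] objects, or a data.frame with
#'   columns `id`, `name`, `compartment`.
#' @param reactions list of [reaction()] objects.
#' @param objective id of the objective reaction (conventionally the biomass
#'   pseudo-reaction).
#' @param id model identifier.
#' @return a `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective, id = "model") {
  if (is.data.frame(metabolites)) {
    mets <- metabolites
    if (is.null(mets$name)) mets$name <- mets$id
    if (is.null(mets$compartment)) mets$compartment <- vapply(mets$id, guess_compartment, "")
  } else {
    mets <- data.frame(
      id = vapply(metabolites, `[[`, "", "id"),
      name = vapply(metabolites, `[[`, "", "name"),
      compartment = vapply(metabolites, `[[`, "", "compartment"),
      stringsAsFactors = FALSE)
  }
  rxns <- setNames(reactions, vapply(reactions, `[[`, "", "id"))
  mod <- structure(list(id = id, metabolites = mets, reactions = rxns,
                        objective = objective),
                   class = "metabolic_model")
  validate_metabolic_model(mod)
  mod
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks id uniqueness, that every metabolite referenced by a reaction
#' exists, bound ordering, and that the objective names an existing reaction.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; otherwise an error.
#' @export
validate_metabolic_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
                                   paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (any(!nzchar(mets$compartment))) stop("empty compartment on metabolite(s)")
  rids <- names(model$reactions)
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (r in model$reactions) {
    if (r$lb > r$ub) stop("reaction '", r$id, "': lb > ub")
    missing <- setdiff(names(r$stoich), mets$id)
    if (length(missing)) stop("reaction '", r$id, "' references unknown metabolite(s): ",
                              paste(missing, collapse = ", "))
  }
  if (!model$objective %in% rids)
    stop("objective reaction '", model$objective, "' not in model")
  invisible(model)
}

#' Stoichiometric matrix S of a model
#'
#' Rows are metabolites, columns reactions; entry `S[i, j]` is the signed
#' coefficient of metabolite i in reaction j (negative = consumed).
#'
#' @param model a `metabolic_model`.
#' @return a sparse `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- names(model$reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    ii <- c(ii, met_index[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Reaction bounds of a model
#' @param model a `metabolic_model`.
#' @return data.frame with columns `id`, `lb`, `ub`.
#' @export
reaction_bounds <- function(model) {
  data.frame(id = names(model$reactions),
             lb = vapply(model$reactions, `[[`, 0, "lb"),
             ub = vapply(model$reactions, `[[`, 0, "ub"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Structural equality of two models
#'
#' Compares metabolite and reaction sets, every stoichiometric coefficient,
#' bounds and the objective id, ignoring storage order.
#'
#' @param a,b `metabolic_model` objects.
#' @param tol absolute tolerance on coefficients and bounds.
#' @return logical.
#' @export
model_equal <- function(a, b, tol = 0) {
  if (!setequal(a$metabolites$id, b$metabolites$id)) return(FALSE)
  if (!setequal(names(a$reactions), names(b$reactions))) return(FALSE)
  if (!identical(a$objective, b$objective)) return(FALSE)
  for (rid in names(a$reactions)) {
    ra <- a$reactions[[rid]]; rb <- b$reactions[[rid]]
    if (!setequal(names(ra$stoich), names(rb$stoich))) return(FALSE)
    if (any(abs(ra$stoich[names(rb$stoich)] - rb$stoich) > tol)) return(FALSE)
    if (abs(ra$lb - rb$lb) > tol || abs(ra$ub - rb$ub) > tol) return(FALSE)
  }
  TRUE
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "'\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:   ", length(x$reactions), "\n", sep = "")
  cat("  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  ex <- vapply(object$reactions, is_exchange, TRUE)
  ec <- vapply(object$reactions, function(r) length(r$ec) > 0L, TRUE)
  out <- list(id = object$id,
              n_metabolites = nrow(object$metabolites),
              n_reactions = length(object$reactions),
              n_exchanges = sum(ex),
              n_ec_annotated = sum(ec),
              n_compartments = length(unique(object$metabolites$compartment)),
              objective = object$objective)
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$id, "': ", x$n_metabolites, " metabolites, ",
      x$n_reactions, " reactions (", x$n_exchanges, " boundary, ",
      x$n_ec_annotated, " EC-annotated), ", x$n_compartments,
      " compartment(s)\n", sep = "")
  cat("objective: ", x$objective, "\n", sep = "")
  invisible(x)
}
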