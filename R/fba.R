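# Flux balance analysis: maximize the objective reaction's flux v_obj subject
# to steady state S v = 0 and bound constraints lb <= v <= ub.

#' Solve the FBA linear program
#'
#' @param model a `metabolic_model`.
#' @param objective the objective reaction: `NULL` or `"biomass"` to use the
#'   model's declared objective, a reaction id, or `"ec:<number>"` to resolve
#'   by EC annotation (error unless exactly one reaction matches).
#' @return a `flux_solution`: list with `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`), `objective_value`, `fluxes` (named numeric over all
#'   reactions), `objective_reaction_id` and `residual` (the steady-state
#'   residual max |S v|). Only the objective value is stable across runs and
#'   solvers; individual fluxes of degenerate alternate optima are not.
#' @examples
#' toy <- make_toy_model(toy_spec(uptake_rate = 10))
#' sol <- solve_fba(toy$model, objective = "DM_prod_c")
#' sol$objective_value  # 10, the uptake bound
#' @export
solve_fba <- function(model, objective = NULL) {
  obj_id <- resolve_objective(model, objective)
  S <- stoichiometric_matrix(model)
  bounds <- reaction_bounds(model)
  cvec <- as.numeric(bounds$id == obj_id)
  res <- lp_maximize(S, rep(0, nrow(S)), cvec, bounds$lb, bounds$ub)
  fluxes <- setNames(res$x, bounds$id)
  residual <- NA_real_
  if (res$status == "optimal") {
    residual <- max(abs(as.vector(S %*% res$x)))
    if (residual > 1e-6)
      warning("steady-state residual ", format(residual), " exceeds 1e-6")
    if (any(res$x < bounds$lb - 1e-9) || any(res$x > bounds$ub + 1e-9))
      warning("bound violation beyond 1e-9 in LP solution")
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes,
                 objective_reaction_id = obj_id,
                 residual = residual,
                 model_id = model$id,
                 dims = c(metabolites = nrow(S), reactions = ncol(S))),
            class = "flux_solution")
}

#' Resolve an objective argument to a reaction id
#' @param model a `metabolic_model`.
#' @param objective see [solve_fba()].
#' @return a reaction id.
#' @export
resolve_objective <- function(model, objective = NULL) {
  if (is.null(objective) || identical(objective, "biomass"))
    return(model$objective)
  stopifnot(is.character(objective), length(objective) == 1L)
  if (startsWith(objective, "ec:")) {
    hits <- find_reactions_by_ec(model, sub("^ec:", "", objective))
    if (length(hits) == 0L)
      stop("objective '", objective, "': no reaction carries that EC")
    if (length(hits) > 1L)
      stop("objective '", objective, "': ambiguous, matches ",
           paste(hits, collapse = ", "))
    return(hits)
  }
  if (!objective %in% names(model$reactions))
    stop("objective reaction '", objective, "' not in model")
  objective
}

#' Report a model flux on the micromole scale
#'
#' Model fluxes are mmol/gDW/h; cobalamin yields are conventionally quoted in
#' umol/gDW/h.
#'
#' @param value flux in mmol/gDW/h.
#' @return flux in umol/gDW/h (`value * 1000`).
#' @export
report_in_micromol <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  value * 1000
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution (", x$model_id, ", objective ", x$objective_reaction_id,
      ")\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  optimum:   ", format(x$objective_value), " mmol/gDW/h\n", sep = "")
    cat("  residual:  ", format(x$residual), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.flux_solution <- function(object, ...) {
  act <- sum(abs(object$fluxes) > 1e-9, na.rm = TRUE)
  out <- list(status = object$status,
              objective_reaction_id = object$objective_reaction_id,
              objective_value = object$objective_value,
              residual = object$residual,
              n_reactions = length(object$fluxes),
              n_active = act)
  class(out) <- "summary.flux_solution"
  out
}

#' @export
print.summary.flux_solution <- function(x, ...) {
  cat("FBA ", x$status, "; objective ", x$objective_reaction_id, " = ",
      format(x$objective_value), " mmol/gDW/h; ", x$n_active, "/",
      x$n_reactions, " reactions carry flux; max |S v| = ",
      format(x$residual), "\n", sep = "")
  invisible(x)
}

#' @export
coef.flux_solution <- function(object, ...) object$fluxes

#' @export
as.data.frame.flux_solution <- function(x, ...) {
  data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}

#' Write a flux solution as TSV (reaction id, flux)
#' @param sol a `flux_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(sol, path) {
  utils::write.table(as.data.frame(sol), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a flux solution to JSON
#' @param sol a `flux_solution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_json <- function(sol, path) {
  jsonlite::write_json(list(status = sol$status,
                            objective_reaction_id = sol$objective_reaction_id,
                            objective_value = sol$objective_value,
                            fluxes = as.list(sol$fluxes)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Prepare a terminal-reaction production objective
#'
#' Resolves the production objective (by default the terminal cobalamin
#' assembly step, adenosylcobinamide-GDP ribazoltransferase, EC 2.7.8.26) and
#' applies [ensure_product_sink()] to every dead-end product of that reaction,
#' so the steady-state constraint cannot silence the objective for want of a
#' drain.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id or `"ec:<number>"`; default `"ec:2.7.8.26"`.
#' @return list with `model` (possibly extended with demand reactions) and
#'   `objective` (the resolved reaction id).
#' @export
prepare_product_objective <- function(model, objective = "ec:2.7.8.26") {
  obj_id <- resolve_objective(model, objective)
  rxn <- model$reactions[[obj_id]]
  products <- names(rxn$stoich)[rxn$stoich > 0]
  for (met in products) {
    consumed_elsewhere <- any(vapply(model$reactions, function(r)
      r$id != obj_id && !is.null(r$stoich[met]) && !is.na(r$stoich[met]) &&
        ((r$stoich[met] < 0 && r$ub > 0) || (r$stoich[met] > 0 && r$lb < 0)),
      TRUE))
    if (!consumed_elsewhere) model <- ensure_product_sink(model, met)
  }
  list(model = model, objective = obj_id)
}
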