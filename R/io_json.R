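# BIGG-style model JSON (the cobrapy JSON schema subset this package uses:
# metabolites, reactions with stoichiometry/bounds/objective_coefficient/
# annotation, compartments). Gene lists are carried through untouched but not
# interpreted (reactions, not genes, are deleted in the screens).

#' Load a metabolic model from file
#'
#' @param path model file.
#' @param format `"bigg-json"` or `"sbml-fbc"`; default guessed from the
#'   extension (`.json` vs `.xml`/`.sbml`).
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "bigg-json", "sbml-fbc")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "bigg-json" else "sbml-fbc"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format,
         "bigg-json" = read_model_json(path),
         "sbml-fbc" = read_model_sbml(path))
}

#' Write a metabolic model to file
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @param format see [load_model()].
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "bigg-json", "sbml-fbc")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "bigg-json" else "sbml-fbc"
  }
  validate_metabolic_model(model)
  switch(format,
         "bigg-json" = write_model_json(model, path),
         "sbml-fbc" = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("unreadable model JSON ", path, ": ",
                                           conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("format error in ", path, ": missing 'metabolites' or 'reactions'")
  mets <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("format error in ", path, ": metabolite without id")
    metabolite(m$id, m$name %||% m$id,
               m$compartment %||% guess_compartment(m$id))
  })
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("format error in ", path, ": reaction without id")
    if (is.null(r$metabolites) || length(r$metabolites) == 0L)
      stop("format error in ", path, ": reaction '", r$id,
           "' has no stoichiometry")
    if (is.null(r$lower_bound) || is.null(r$upper_bound))
      stop("format error in ", path, ": reaction '", r$id, "' has no bounds")
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective <<- objective %||% r$id
    ec <- character()
    if (!is.null(r$annotation) && !is.null(r$annotation[["ec-code"]]))
      ec <- unlist(r$annotation[["ec-code"]])
    reaction(r$id,
             setNames(vapply(r$metabolites, as.numeric, 0), names(r$metabolites)),
             lb = r$lower_bound, ub = r$upper_bound,
             name = r$name %||% r$id, ec = ec)
  })
  if (is.null(objective))
    stop("format error in ", path, ": no reaction has a nonzero ",
         "objective_coefficient")
  metabolic_model(mets, rxns, objective = objective,
                  id = doc$id %||% tools::file_path_sans_ext(basename(path)))
}

write_model_json <- function(model, path) {
  comps <- unique(model$metabolites$compartment)
  doc <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, name = r$name,
                  metabolites = as.list(r$stoich),
                  lower_bound = r$lb, upper_bound = r$ub,
                  gene_reaction_rule = "",
                  objective_coefficient = if (r$id == model$objective) 1 else 0)
      if (length(r$ec)) out$annotation <- list(`ec-code` = as.list(r$ec))
      out
    }),
    genes = list(),
    compartments = setNames(as.list(comps), comps),
    version = "1")
  tryCatch(jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA),
           error = function(e) stop("cannot write model JSON ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
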