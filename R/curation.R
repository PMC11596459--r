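# Curation: named bundles of EC-annotated reaction specs applied to a base
# model. The shipped bundle library encodes the three missing-reaction
# curations plus the knockin candidates of the strain-design screen.

#' Create a curation bundle
#'
#' @param name bundle name (unique within a library).
#' @param specs non-empty list of [reaction_spec()] objects.
#' @param description free-text description.
#' @return a `curation_bundle`.
#' @export
curation_bundle <- function(name, specs, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(specs) == 0L) stop("bundle '", name, "': specs must be non-empty")
  stopifnot(all(vapply(specs, inherits, TRUE, "reaction_spec")))
  structure(list(name = name, specs = specs, description = description),
            class = "curation_bundle")
}

#' Load a bundle library from YAML
#'
#' @param path YAML file with a top-level `bundles` mapping of
#'   bundle-name -> `{description, reactions: [{id, ec, name, formula,
#'   reversible, source}]}`.
#' @return named list of [curation_bundle()] objects.
#' @export
load_bundles <- function(path) {
  if (!file.exists(path)) stop("bundle file not found: ", path)
  raw <- yaml::read_yaml(path)$bundles
  if (is.null(raw)) stop("bundle file ", path, " has no 'bundles' mapping")
  out <- lapply(names(raw), function(nm) {
    specs <- lapply(raw[[nm]]$reactions, function(e)
      reaction_spec(ec = e$ec, name = e$name, formula = e$formula,
                    reversible = e$reversible, source = e$source %||% "",
                    id = e$id))
    curation_bundle(nm, specs, raw[[nm]]$description %||% "")
  })
  setNames(out, names(raw))
}

#' Built-in curation and knockin bundles
#'
#' Returns the shipped bundle library: `base_curation` (EC 6.3.5.9,
#' 1.13.11.79, 1.14.13.83), `aminopropanol_linker` (EC 2.7.1.177 + 4.1.1.81),
#' `ala_synthase` (EC 2.3.1.37), `thr_dehydrogenase` (EC 1.1.1.103) and
#' `gly_acetyltransferase` (EC 2.3.1.29).
#'
#' @return named list of [curation_bundle()] objects.
#' @export
builtin_bundles <- function() {
  load_bundles(system.file("extdata", "reactions", "kegg_specs.yaml",
                           package = "b12flux", mustWork = TRUE))
}

#' Apply curation bundles to a model
#'
#' All specs across all bundles are checked for reaction-id collisions (with
#' each other and with the model), then added in id-sorted order, so the
#' result is independent of bundle order.
#'
#' @param model a `metabolic_model`.
#' @param bundles list of [curation_bundle()] objects, or a character vector
#'   of built-in bundle names.
#' @return the extended model.
#' @export
apply_bundles <- function(model, bundles) {
  if (is.character(bundles)) {
    lib <- builtin_bundles()
    unknown <- setdiff(bundles, names(lib))
    if (length(unknown)) stop("unknown bundle name(s): ",
                              paste(unknown, collapse = ", "))
    bundles <- lib[bundles]
  }
  if (length(bundles) == 0L) return(model)
  stopifnot(all(vapply(bundles, inherits, TRUE, "curation_bundle")))
  specs <- unlist(lapply(bundles, `[[`, "specs"), recursive = FALSE)
  ids <- vapply(specs, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("reaction id conflict across bundles: ",
                        paste(unique(dup), collapse = ", "))
  clash <- intersect(ids, names(model$reactions))
  if (length(clash)) stop("reaction id conflict with model: ",
                          paste(clash, collapse = ", "))
  for (sp in specs[order(ids)]) model <- add_reaction(model, sp)
  model
}
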