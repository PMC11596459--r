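# SBML Level 3 Version 1 + FBC v2 reader/writer for the constraint-based
# subset: compartments, species, reactions with stoichiometry, flux bounds as
# shared parameters, the active maximisation objective, and EC annotations as
# identifiers.org ec-code resources. Kinetic laws, events and unit systems
# are out of scope. Ids are written with the conventional "M_"/"R_" SBML
# prefixes and stripped again on read.

sbml_ns_core <- "http://www.sbml.org/sbml/level3/version1/core"
sbml_ns_fbc <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
ns_rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
ns_bqbiol <- "http://biomodels.net/biology-qualifiers/"

num17 <- function(x) sprintf("%.17g", x)

write_model_sbml <- function(model, path) {
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = sbml_ns_core,
    "xmlns:fbc" = sbml_ns_fbc,
    "xmlns:rdf" = ns_rdf,
    "xmlns:bqbiol" = ns_bqbiol,
    level = "3", version = "1",
    "fbc:required" = "false")
  mod <- xml2::xml_add_child(root, "model", id = model$id,
                             "fbc:strict" = "true")

  comps <- unique(model$metabolites$compartment)
  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in comps)
    xml2::xml_add_child(loc, "compartment", id = cp, constant = "true")

  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(los, "species",
                        id = paste0("M_", model$metabolites$id[i]),
                        name = model$metabolites$name[i],
                        compartment = model$metabolites$compartment[i],
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false",
                        constant = "false")
  }

  # flux bounds as shared constant parameters (FBC-strict convention)
  bvals <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  bid <- setNames(sprintf("fb_%d", seq_along(bvals)), num17(bvals))
  lop <- xml2::xml_add_child(mod, "listOfParameters")
  for (v in bvals)
    xml2::xml_add_child(lop, "parameter", id = bid[[num17(v)]],
                        value = num17(v), constant = "true")

  lor <- xml2::xml_add_child(mod, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(lor, "reaction",
                              id = paste0("R_", r$id),
                              name = r$name,
                              reversible = if (r$lb < 0) "true" else "false",
                              fast = "false",
                              "fbc:lowerFluxBound" = bid[[num17(r$lb)]],
                              "fbc:upperFluxBound" = bid[[num17(r$ub)]])
    if (length(r$ec)) {
      ann <- xml2::xml_add_child(rn, "annotation")
      rdf <- xml2::xml_add_child(ann, "rdf:RDF")
      desc <- xml2::xml_add_child(rdf, "rdf:Description",
                                  "rdf:about" = paste0("#R_", r$id))
      bag <- xml2::xml_add_child(xml2::xml_add_child(desc, "bqbiol:is"), "rdf:Bag")
      for (e in r$ec)
        xml2::xml_add_child(bag, "rdf:li",
                            "rdf:resource" = paste0("https://identifiers.org/ec-code/", e))
    }
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(subs))
        xml2::xml_add_child(lre, "speciesReference", species = paste0("M_", m),
                            stoichiometry = num17(-subs[[m]]), constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prods))
        xml2::xml_add_child(lpr, "speciesReference", species = paste0("M_", m),
                            stoichiometry = num17(prods[[m]]), constant = "true")
    }
  }

  loo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", model$objective),
                      "fbc:coefficient" = "1")

  tryCatch(xml2::write_xml(root, path),
           error = function(e) stop("cannot write SBML ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

# attribute lookup tolerant of namespace prefixes
attr_any <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- names(a) == name | endsWith(names(a), paste0(":", name))
  if (any(hit)) unname(a[hit][1]) else NA_character_
}

strip_sid <- function(id, prefix) sub(paste0("^", prefix, "_"), "", id)

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  mod <- xml2::xml_find_first(doc, "./model")
  if (is.na(mod)) stop("format error in ", path, ": no <model> element")

  mets <- lapply(xml2::xml_find_all(mod, "./listOfSpecies/species"), function(s) {
    id <- attr_any(s, "id")
    if (is.na(id)) stop("format error in ", path, ": species without id")
    metabolite(strip_sid(id, "M"),
               name = attr_any(s, "name") %|na|% strip_sid(id, "M"),
               compartment = attr_any(s, "compartment") %|na|% "c")
  })

  pars <- xml2::xml_find_all(mod, "./listOfParameters/parameter")
  pval <- setNames(as.numeric(vapply(pars, attr_any, "", "value")),
                   vapply(pars, attr_any, "", "id"))

  rxns <- lapply(xml2::xml_find_all(mod, "./listOfReactions/reaction"), function(rn) {
    rid_raw <- attr_any(rn, "id")
    if (is.na(rid_raw)) stop("format error in ", path, ": reaction without id")
    rid <- strip_sid(rid_raw, "R")
    lbp <- attr_any(rn, "lowerFluxBound"); ubp <- attr_any(rn, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp))
      stop("format error in ", path, ": reaction '", rid_raw,
           "' lacks fbc flux bounds")
    if (!lbp %in% names(pval) || !ubp %in% names(pval))
      stop("format error in ", path, ": reaction '", rid_raw,
           "' references undefined bound parameter")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      m <- strip_sid(attr_any(sr, "species"), "M")
      co <- as.numeric(attr_any(sr, "stoichiometry") %|na|% "1")
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) - co
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      m <- strip_sid(attr_any(sr, "species"), "M")
      co <- as.numeric(attr_any(sr, "stoichiometry") %|na|% "1")
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) + co
    }
    if (length(st) == 0L)
      stop("format error in ", path, ": reaction '", rid_raw,
           "' has no stoichiometry")
    resources <- xml2::xml_find_all(rn, "./annotation//*[local-name()='li']")
    ec <- character()
    for (li in resources) {
      res <- attr_any(li, "resource")
      m <- regmatches(res, regexpr("ec-code[/:]([0-9.]+)$", res))
      if (length(m) && nzchar(m)) ec <- c(ec, sub("^ec-code[/:]", "", m))
    }
    reaction(rid, st, lb = pval[[lbp]], ub = pval[[ubp]],
             name = attr_any(rn, "name") %|na|% rid, ec = unique(ec))
  })

  fo <- xml2::xml_find_first(mod, ".//*[local-name()='fluxObjective']")
  if (is.na(fo)) stop("format error in ", path, ": no FBC objective")
  objective <- strip_sid(attr_any(fo, "reaction"), "R")

  metabolic_model(mets, rxns, objective = objective,
                  id = attr_any(mod, "id") %|na|%
                    tools::file_path_sans_ext(basename(path)))
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a
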