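# Fermentation medium handling: a medium is a table of compound uptake rates
# plus an explicit compound -> exchange-reaction mapping. The mapping is
# explicit in the file because silent name-matching of exchanges is the main
# reproducibility hazard in medium application.

#' Create a medium specification
#'
#' @param compound character vector of compound names.
#' @param rate uptake rates, mmol/gDW/h, all >= 0.
#' @param exchange_id exchange-reaction id each compound maps to.
#' @return a `medium_spec` (a data.frame subclass).
#' @export
medium_spec <- function(compound = character(), rate = numeric(),
                        exchange_id = character()) {
  stopifnot(length(compound) == length(rate),
            length(compound) == length(exchange_id))
  if (any(rate < 0)) stop("medium validation error: negative uptake rate for ",
                          paste(compound[rate < 0], collapse = ", "))
  if (anyDuplicated(compound))
    stop("medium validation error: duplicate compound(s): ",
         paste(unique(compound[duplicated(compound)]), collapse = ", "))
  structure(data.frame(compound = as.character(compound),
                       rate = as.numeric(rate),
                       exchange_id = as.character(exchange_id),
                       stringsAsFactors = FALSE),
            class = c("medium_spec", "data.frame"))
}

#' Load a medium from file
#'
#' TSV files need columns `compound`, `rate_mmol_per_gdw_h`, `exchange_id`;
#' YAML files a list of mappings with the same keys.
#'
#' @param path `.tsv`/`.txt` or `.yml`/`.yaml` file.
#' @return a [medium_spec()].
#' @export
load_medium <- function(path) {
  if (!file.exists(path)) stop("medium file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    entries <- yaml::read_yaml(path)
    if (length(entries) == 0L) return(medium_spec())
    df <- do.call(rbind, lapply(entries, function(e)
      data.frame(compound = e$compound,
                 rate_mmol_per_gdw_h = as.numeric(e$rate_mmol_per_gdw_h),
                 exchange_id = e$exchange_id, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) return(medium_spec())
  }
  need <- c("compound", "rate_mmol_per_gdw_h", "exchange_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("medium file ", path, " lacks column(s): ",
                            paste(missing, collapse = ", "))
  medium_spec(df$compound, df$rate_mmol_per_gdw_h, df$exchange_id)
}

#' The Table 1 fermentation medium shipped with the package
#'
#' Six compounds with measured consumption rates: oxygen 18.5, glucose 11.7,
#' L-threonine 0.48, succinate 0.95, glycine 0.1 and cobalt(2+) 0.0375
#' mmol/gDW/h, mapped to the iJN1463 exchange reactions.
#'
#' @return a [medium_spec()].
#' @export
b12_medium <- function() {
  load_medium(system.file("extdata", "media", "table1_b12.tsv",
                          package = "b12flux", mustWork = TRUE))
}

#' Apply a medium to a model
#'
#' For each compound the mapped exchange reaction's lower bound is set to
#' `-rate` (negative exchange flux = uptake). Upper bounds and all unlisted
#' exchanges are untouched unless `strict = TRUE`, which first closes every
#' uptake (all negative exchange lower bounds raised to 0) so that only the
#' medium feeds the model.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_spec()].
#' @param strict close all other uptakes first?
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium, strict = FALSE) {
  stopifnot(inherits(medium, "medium_spec"))
  missing <- setdiff(medium$exchange_id, names(model$reactions))
  if (length(missing))
    stop("medium lookup error: exchange reaction(s) not in model: ",
         paste(missing, collapse = ", "))
  if (strict) {
    for (rid in names(model$reactions)) {
      r <- model$reactions[[rid]]
      if (is_exchange(r) && r$lb < 0) model$reactions[[rid]]$lb <- 0
    }
  }
  for (k in seq_len(nrow(medium))) {
    model$reactions[[medium$exchange_id[k]]]$lb <- -medium$rate[k]
  }
  model
}
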