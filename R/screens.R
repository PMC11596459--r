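# The two in silico experiments: a knockin screen over curation-bundle
# combinations and an exhaustive deletion screen over all 1..max_size subsets
# of EC-annotated candidate reactions. Both evaluate two FBA objectives
# (biomass and the vitamin product drain) per intervention and are fully
# deterministic.

#' Create a deletion candidate
#'
#' @param label human-readable candidate name.
#' @param ec EC query string; compound entries such as `"1.8.1.4-1.2.4.2"` are
#'   split into alternative annotations of the same candidate slot.
#' @return a `deletion_candidate` with fields `label` and `ec_list`.
#' @export
deletion_candidate <- function(label, ec) {
  ecs <- unlist(lapply(ec, split_ec_query))
  if (length(ecs) == 0L) stop("candidate '", label, "': empty EC list")
  structure(list(label = label, ec_list = ecs), class = "deletion_candidate")
}

#' Load deletion candidates from YAML
#' @param path YAML file: a list of mappings with keys `label` and `ec`.
#' @return list of [deletion_candidate()] objects.
#' @export
load_candidates <- function(path) {
  if (!file.exists(path)) stop("candidate file not found: ", path)
  raw <- yaml::read_yaml(path)$candidates
  if (is.null(raw)) stop("candidate file ", path, " has no 'candidates' list")
  lapply(raw, function(e) deletion_candidate(e$label, e$ec))
}

#' The 12 shipped deletion candidates of the porphyrin-pathway screen
#' @return list of [deletion_candidate()] objects.
#' @export
builtin_candidates <- function() {
  load_candidates(system.file("extdata", "candidates", "table2_candidates.yaml",
                              package = "b12flux", mustWork = TRUE))
}

#' Enumerate deletion subsets
#'
#' All subsets of sizes 1..`max_size` of the candidate list, each once, in
#' deterministic size-then-lexicographic order. The empty set is excluded by
#' construction (the baseline is reported separately by the screens).
#'
#' @param candidates list of candidates (any list; only its length matters).
#' @param max_size largest subset size, `1 <= max_size <= length(candidates)`.
#' @return list of integer index vectors; its length is
#'   `sum(choose(n, 1:max_size))`.
#' @export
enumerate_deletion_sets <- function(candidates, max_size) {
  n <- length(candidates)
  if (max_size < 1 || max_size > n)
    stop("max_size must be between 1 and ", n)
  out <- list()
  for (k in seq_len(max_size)) {
    out <- c(out, combn(n, k, simplify = FALSE))
  }
  out
}

solve_pair <- function(model, biomass_objective, product_objective) {
  bio <- tryCatch(solve_fba(model, biomass_objective),
                  error = function(e) list(status = "error", objective_value = NA_real_))
  b12 <- tryCatch(solve_fba(model, product_objective),
                  error = function(e) list(status = "error", objective_value = NA_real_))
  list(biomass = if (bio$status == "optimal") bio$objective_value else NA_real_,
       b12_umol = if (b12$status == "optimal") report_in_micromol(b12$objective_value) else NA_real_,
       status_biomass = bio$status, status_b12 = b12$status)
}

screen_row <- function(intervention, size, pair) {
  data.frame(intervention = intervention, size = size,
             biomass = pair$biomass, b12_umol = pair$b12_umol,
             status_biomass = pair$status_biomass,
             status_b12 = pair$status_b12,
             stringsAsFactors = FALSE)
}

#' Run the knockin screen
#'
#' Evaluates the unmodified base model (the baseline row, intervention
#' `"none"`) and then each bundle combination in input order. A variant whose
#' curation or solve fails is recorded with status `"error"` rather than
#' aborting the screen.
#'
#' @param base the (curated) base `metabolic_model`.
#' @param medium a [medium_spec()] applied before solving.
#' @param variants list of character vectors of bundle names (resolved via
#'   [builtin_bundles()]) or of lists of [curation_bundle()] objects.
#' @param product_objective objective for the product solve (reaction id or
#'   `"ec:..."`), see [solve_fba()].
#' @param biomass_objective objective for the growth solve; default the
#'   model's declared objective.
#' @param strict_medium passed to [apply_medium()].
#' @return a `screen_result` data.frame with columns `intervention`, `size`,
#'   `biomass` (mmol/gDW/h), `b12_umol` (umol/gDW/h), `status_biomass`,
#'   `status_b12`.
#' @export
run_knockin_screen <- function(base, medium, variants, product_objective,
                               biomass_objective = NULL,
                               strict_medium = FALSE) {
  base <- apply_medium(base, medium, strict = strict_medium)
  rows <- list(screen_row("none", 0L,
                          solve_pair(base, biomass_objective, product_objective)))
  for (v in variants) {
    label <- if (is.character(v)) paste(v, collapse = "+")
             else paste(vapply(v, `[[`, "", "name"), collapse = "+")
    pair <- tryCatch({
      mod <- apply_bundles(base, v)
      solve_pair(mod, biomass_objective, product_objective)
    }, error = function(e) list(biomass = NA_real_, b12_umol = NA_real_,
                                status_biomass = "error", status_b12 = "error"))
    rows <- c(rows, list(screen_row(label, length(v), pair)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Resolve deletion candidates to model reaction ids
#'
#' A candidate annotated with several ECs (compound Table entries) deletes
#' all matching reactions simultaneously.
#'
#' @param model a `metabolic_model`.
#' @param candidates list of [deletion_candidate()] objects.
#' @param on_unresolved `"error"` (default) or `"skip"` for candidates whose
#'   ECs match no reaction.
#' @return named list (by candidate label) of reaction-id character vectors;
#'   skipped candidates are dropped with a warning.
#' @export
resolve_candidates <- function(model, candidates,
                               on_unresolved = c("error", "skip")) {
  on_unresolved <- match.arg(on_unresolved)
  out <- list()
  for (cand in candidates) {
    ids <- unique(unlist(lapply(cand$ec_list, function(e)
      find_reactions_by_ec(model, e))))
    if (length(ids) == 0L) {
      msg <- paste0("candidate '", cand$label, "' (EC ",
                    paste(cand$ec_list, collapse = "/"),
                    ") matches no reaction in the model")
      if (on_unresolved == "error") stop(msg)
      warning(msg, "; skipped")
      next
    }
    out[[cand$label]] <- ids
  }
  out
}

#' Run the exhaustive deletion screen
#'
#' Enumerates all candidate subsets of sizes 1..`max_size`
#' ([enumerate_deletion_sets()]), knocks out the union of the reactions
#' matching each subset's ECs, solves both objectives, and returns results
#' sorted by product value descending with a deterministic tie-break
#' (biomass descending, then subset size ascending, then label). The base
#' model is untouched between subsets (edits are copy-on-write); the baseline
#' (no deletion) is attached as `attr(result, "baseline")`.
#'
#' @inheritParams run_knockin_screen
#' @param candidates list of [deletion_candidate()] objects.
#' @param max_size largest subset size.
#' @param on_unresolved see [resolve_candidates()].
#' @return a `screen_result` data.frame (see [run_knockin_screen()]).
#' @export
run_deletion_screen <- function(base, medium, candidates, max_size,
                                product_objective, biomass_objective = NULL,
                                strict_medium = FALSE,
                                on_unresolved = c("error", "skip")) {
  base <- apply_medium(base, medium, strict = strict_medium)
  resolved <- resolve_candidates(base, candidates, on_unresolved)
  labels <- names(resolved)
  subsets <- enumerate_deletion_sets(resolved, max_size)
  baseline <- screen_row("none", 0L,
                         solve_pair(base, biomass_objective, product_objective))
  rows <- vector("list", length(subsets))
  for (k in seq_along(subsets)) {
    idx <- subsets[[k]]
    ids <- unique(unlist(resolved[idx]))
    pair <- solve_pair(knock_out(base, ids), biomass_objective, product_objective)
    rows[[k]] <- screen_row(paste(labels[idx], collapse = " + "),
                            length(idx), pair)
  }
  out <- do.call(rbind, rows)
  ord <- order(-replace(out$b12_umol, is.na(out$b12_umol), -Inf),
               -replace(out$biomass, is.na(out$biomass), -Inf),
               out$size, out$intervention, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  attr(out, "baseline") <- baseline
  out
}

#' Summarize a screen
#'
#' @param results a `screen_result` data.frame.
#' @param near_zero_tol threshold below which a product value counts as
#'   "zero or very close to zero".
#' @return a `screen_summary`: per-size counts, best row per size, global
#'   best (NULL when every solve failed), and the fraction of near-zero
#'   product values.
#' @export
summarize_screen <- function(results, near_zero_tol = 1e-6) {
  if (is.null(results) || nrow(results) == 0L)
    stop("summarize_screen: empty results")
  sizes <- sort(unique(results$size))
  per_size <- data.frame(size = sizes,
                         n = vapply(sizes, function(s) sum(results$size == s), 0L))
  best_by_size <- lapply(sizes, function(s) {
    sub <- results[results$size == s & !is.na(results$b12_umol), , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub[which.max(sub$b12_umol), , drop = FALSE]
  })
  names(best_by_size) <- as.character(sizes)
  ok <- !is.na(results$b12_umol)
  best <- if (any(ok)) results[ok, , drop = FALSE][which.max(results$b12_umol[ok]), , drop = FALSE]
          else NULL
  structure(list(per_size = per_size,
                 best_by_size = best_by_size,
                 best = best,
                 all_failed = !any(ok),
                 frac_near_zero = mean(!ok | results$b12_umol < near_zero_tol)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary:", sum(x$per_size$n), "interventions\n")
  cat("  per size:", paste(sprintf("%d:%d", x$per_size$size, x$per_size$n),
                           collapse = "  "), "\n")
  if (x$all_failed) {
    cat("  best: undefined (all solves failed)\n")
  } else {
    cat("  best:", x$best$intervention, "->",
        format(x$best$b12_umol), "umol/gDW/h product,",
        format(x$best$biomass), "mmol/gDW/h biomass\n")
  }
  cat("  fraction near-zero product:", format(x$frac_near_zero), "\n")
  invisible(x)
}

#' Write a screen result as TSV
#'
#' Values are formatted to 3 decimals (the reporting precision of the
#' pipeline); use the data.frame itself for full precision.
#'
#' @param results a `screen_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(results, path) {
  out <- results
  out$biomass <- formatC(out$biomass, format = "f", digits = 3)
  out$b12_umol <- formatC(out$b12_umol, format = "f", digits = 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
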