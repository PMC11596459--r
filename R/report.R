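# End-to-end workflow: curate, solve baseline objectives, run both screens,
# compare against the fermentation benchmark, and write deterministic TSV/JSON
# reports. No values are computed in this layer beyond formatting; every row
# traces to a flux_solution or screen_result.

fmt3 <- function(x) formatC(x, format = "f", digits = 3)

#' Reproduce the full strain-design workflow
#'
#' Runs the pipeline end to end on a model: apply curation bundles, apply the
#' medium, solve the biomass and product baselines, run the knockin screen
#' over `knockin_variants`, run the exhaustive deletion screen (on the model
#' extended with `deletion_base_bundles`, the best-performing knockin), and
#' compare the best knockin yield against a fermentation benchmark record.
#'
#' Writes into `out_dir`: `baseline_fba.tsv`, `knockin_screen.tsv`,
#' `deletion_screen.tsv`, `deletion_summary.json`, `benchmark_comparison.tsv`
#' and `manifest.json` (stage completeness and a timestamp; the TSVs
#' themselves are byte-stable across reruns). If any stage fails the
#' remaining reports are still attempted, the manifest records the failure,
#' and the function then errors.
#'
#' @param model a `metabolic_model` or a model file path ([load_model()]).
#' @param medium a [medium_spec()]; default the shipped six-compound medium.
#' @param curation bundle names/objects applied to the base model first.
#' @param knockin_variants list of bundle-name vectors for the knockin screen.
#' @param deletion_base_bundles bundles added on top of the curated model
#'   before the deletion screen.
#' @param candidates deletion candidates; default the shipped 12.
#' @param max_size largest deletion-subset size.
#' @param product_objective production objective, see [solve_fba()].
#' @param benchmark_record a [fermentation_record()]; default SC510.
#' @param out_dir output directory (created if needed).
#' @param strict_medium passed to [apply_medium()].
#' @param on_unresolved passed to [resolve_candidates()].
#' @return invisible list with elements `baseline`, `knockin`, `deletion`,
#'   `deletion_summary`, `benchmark`, `manifest`.
#' @export
reproduce_workflow <- function(model,
                               medium = b12_medium(),
                               curation = "base_curation",
                               knockin_variants = default_knockin_variants(),
                               deletion_base_bundles = "aminopropanol_linker",
                               candidates = builtin_candidates(),
                               max_size = 5,
                               product_objective = "ec:2.7.8.26",
                               benchmark_record = sc510_record(),
                               out_dir,
                               strict_medium = FALSE,
                               on_unresolved = "error") {
  if (is.character(model)) model <- load_model(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), model_id = model$id)
  failures <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      failures <<- c(failures, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
    manifest$stages[[name]] <<- is.null(attr(res, "failed")) && !is.null(res)
    res
  }

  curated <- stage("curation", {
    m <- if (length(curation)) apply_bundles(model, curation) else model
    prep <- prepare_product_objective(m, product_objective)
    prep
  })

  baseline <- stage("baseline_fba", {
    m <- apply_medium(curated$model, medium, strict = strict_medium)
    bio <- solve_fba(m)
    b12 <- solve_fba(m, curated$objective)
    df <- data.frame(
      objective = c("biomass", "product"),
      reaction_id = c(bio$objective_reaction_id, b12$objective_reaction_id),
      value = c(bio$objective_value, report_in_micromol(b12$objective_value)),
      unit = c("mmol/gDW/h", "umol/gDW/h"),
      status = c(bio$status, b12$status),
      stringsAsFactors = FALSE)
    out <- df; out$value <- fmt3(out$value)
    utils::write.table(out, file.path(out_dir, "baseline_fba.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    df
  })

  knockin <- stage("knockin_screen", {
    ks <- run_knockin_screen(curated$model, medium, knockin_variants,
                             product_objective = curated$objective,
                             strict_medium = strict_medium)
    write_screen_tsv(ks, file.path(out_dir, "knockin_screen.tsv"))
    ks
  })

  deletion <- stage("deletion_screen", {
    base <- if (length(deletion_base_bundles))
      apply_bundles(curated$model, deletion_base_bundles) else curated$model
    ds <- run_deletion_screen(base, medium, candidates, max_size,
                              product_objective = curated$objective,
                              strict_medium = strict_medium,
                              on_unresolved = on_unresolved)
    write_screen_tsv(ds, file.path(out_dir, "deletion_screen.tsv"))
    ds
  })

  deletion_summary <- if (!is.null(deletion)) stage("deletion_summary", {
    sm <- summarize_screen(deletion)
    jsonlite::write_json(
      list(per_size = sm$per_size,
           best = sm$best,
           frac_near_zero = sm$frac_near_zero,
           baseline = attr(deletion, "baseline")),
      file.path(out_dir, "deletion_summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    sm
  }) else NULL

  benchmark <- if (!is.null(knockin)) stage("benchmark", {
    ref <- specific_productivity(benchmark_record)
    ok <- !is.na(knockin$b12_umol)
    best <- knockin[ok, , drop = FALSE][which.max(knockin$b12_umol[ok]), ]
    base_row <- knockin[knockin$intervention == "none", ]
    df <- data.frame(
      quantity = c("benchmark_specific_productivity",
                   "best_knockin_yield",
                   "fold_change_vs_benchmark",
                   "percent_increase_vs_baseline"),
      value = c(ref, best$b12_umol,
                fold_change(best$b12_umol, ref),
                percent_increase(best$b12_umol, base_row$b12_umol)),
      unit = c("umol/gDW/h", "umol/gDW/h", "fold", "percent"),
      detail = c(benchmark_record$strain, best$intervention, "", ""),
      stringsAsFactors = FALSE)
    out <- df; out$value <- fmt3(out$value)
    utils::write.table(out, file.path(out_dir, "benchmark_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    df
  }) else NULL

  manifest$complete <- length(failures) == 0L
  manifest$failures <- failures
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(failures))
    stop("workflow stage failure(s): ", paste(failures, collapse = "; "))
  invisible(list(baseline = baseline, knockin = knockin, deletion = deletion,
                 deletion_summary = deletion_summary, benchmark = benchmark,
                 manifest = manifest))
}

#' Knockin variants mirroring the shipped screen
#'
#' The seven bundle combinations evaluated on top of the curated model.
#' @return list of character vectors of bundle names.
#' @export
default_knockin_variants <- function() {
  list("aminopropanol_linker",
       "ala_synthase",
       c("ala_synthase", "gly_acetyltransferase"),
       c("aminopropanol_linker", "ala_synthase"),
       "thr_dehydrogenase",
       "gly_acetyltransferase",
       c("thr_dehydrogenase", "gly_acetyltransferase"))
}
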