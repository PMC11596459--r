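# Benchmark arithmetic: dimensional analysis of fermentation outcomes to
# specific productivity (umol/gDW/h) and the fold-change / percent-increase
# comparisons against it. All comparisons are done on the umol scale on both
# sides; nothing here coerces units implicitly.

#' Molar mass of cyanocobalamin (g/mol)
#'
#' Default molar mass used to convert vitamin B12 mass concentrations to
#' moles; override per record if the assayed form differs (e.g.
#' hydroxocobalamin).
#' @export
B12_MOLAR_MASS <- 1355.37

#' Create a fermentation record
#'
#' @param product_conc product concentration at harvest, mg/L (>= 0).
#' @param duration fermentation duration, h (> 0).
#' @param dcw dry cell weight, gDW/L (> 0).
#' @param molar_mass product molar mass, g/mol (> 0); default cyanocobalamin.
#' @param strain strain label.
#' @return a `fermentation_record`.
#' @export
fermentation_record <- function(product_conc, duration, dcw,
                                molar_mass = B12_MOLAR_MASS, strain = "") {
  if (product_conc < 0) stop("validation error: product_conc must be >= 0")
  if (duration <= 0 || dcw <= 0 || molar_mass <= 0)
    stop("validation error: duration, dcw and molar_mass must be > 0")
  structure(list(product_conc = product_conc, duration = duration, dcw = dcw,
                 molar_mass = molar_mass, strain = strain),
            class = "fermentation_record")
}

#' Load a fermentation record from YAML
#' @param path YAML file with keys `product_conc_mg_per_l`, `duration_h`,
#'   `dcw_g_per_l`, optionally `molar_mass_g_per_mol` and `strain`.
#' @return a [fermentation_record()].
#' @export
load_fermentation_record <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  e <- yaml::read_yaml(path)
  fermentation_record(product_conc = e$product_conc_mg_per_l,
                      duration = e$duration_h,
                      dcw = e$dcw_g_per_l,
                      molar_mass = e$molar_mass_g_per_mol %||% B12_MOLAR_MASS,
                      strain = e$strain %||% "")
}

#' The shipped P. denitrificans SC510 benchmark record
#'
#' 214 mg/L vitamin B12 over 168 h at 33.23 gDW/L, the industrial fermentation
#' benchmark the model yields are compared against.
#' @return a [fermentation_record()].
#' @export
sc510_record <- function() {
  load_fermentation_record(system.file("extdata", "benchmark", "sc510.yaml",
                                       package = "b12flux", mustWork = TRUE))
}

#' Specific productivity of a fermentation
#'
#' Converts (mg/L, h, gDW/L, g/mol) to umol/gDW/h:
#' `(product_conc / molar_mass) * 1000 / dcw / duration`.
#'
#' @param rec a [fermentation_record()].
#' @return rate in umol/gDW/h.
#' @export
specific_productivity <- function(rec) {
  stopifnot(inherits(rec, "fermentation_record"))
  (rec$product_conc / rec$molar_mass) * 1000 / rec$dcw / rec$duration
}

#' Fold change of a test rate over a reference rate
#' @param test,reference rates on the same scale; `reference > 0`.
#' @return `test / reference`.
#' @export
fold_change <- function(test, reference) {
  if (reference <= 0) stop("validation error: reference rate must be > 0")
  test / reference
}

#' Percent increase of a test rate over a baseline rate
#' @param test,baseline rates on the same scale; `baseline > 0`.
#' @return `100 * (test - baseline) / baseline`.
#' @export
percent_increase <- function(test, baseline) {
  if (baseline <= 0) stop("validation error: baseline rate must be > 0")
  100 * (test - baseline) / baseline
}
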