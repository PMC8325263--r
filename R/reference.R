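#' Reference heterotic QTL tables
#'
#' Machine-readable copies of the published heterotic-QTL summary tables
#' from a maize intermated-B73xMo17 triple-testcross study of seedling
#' biomass traits (leaf length LL, leaf width LW, leaf area LA, seedling
#' dry weight SDW), shipped with the package so that table-level aggregates
#' (QTL counts per dataset, summed phenotypic variance explained) can be
#' recomputed and compared against pipeline output. `"main"` holds the
#' one-dimensional Z1/Z2/Z3 hits (effects `a_star`, `d_star`, `da`, each
#' populated only for its own dataset); `"epistasis"` holds the
#' two-dimensional H3 (additive x additive) and Z3 (dominance x dominance)
#' interaction pairs.
#'
#' @param type `"main"` or `"epistasis"`.
#' @return A tibble.
#' @export
reference_qtl_table <- function(type = c("main", "epistasis")) {
  type <- match.arg(type)
  file <- switch(type, main = "heterotic_qtls.csv",
                 epistasis = "epistatic_interactions.csv")
  path <- system.file("extdata", file, package = "ttcqtl", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
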