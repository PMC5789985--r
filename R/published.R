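# Accessors for the published summary tables shipped with the package.
# These are cohort-level counts printed in the source study's tables (the
# raw per-mouse data are not redistributable); they serve as inputs to the
# weighted-average damage probability, the partial:total essential ratio
# and the viability proportions.

published_path <- function(file) {
  system.file("extdata", file, package = "enudamage", mustWork = TRUE)
}

#' Published filtering-cascade counts per mutation class
#'
#' Per-class mutation counts at each step of the filtering cascade of a
#' large ENU cohort: all genotyped coding/splicing mutations, the
#' 100-Mb-isolated subset, the subset from pedigrees with >= 3 G3 mice,
#' and the subset in known essential genes.
#'
#' @return Data frame with columns `mutation_class`, `all_mutations`,
#'   `isolated`, `min3_g3`, `essential`.
#' @export
published_class_counts <- function() {
  utils::read.delim(published_path("table1_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Published viability annotation counts
#'
#' `impc_viability()`: gene counts per viability category (viable,
#' subviable, lethal) from a large knockout-viability resource.
#' `essential_lethality_counts()`: among annotated-essential genes, how
#' many are partially vs totally lethal when disrupted; their ratio is
#' the estimator's default `partial_ratio`.
#'
#' @return A data frame of counts.
#' @export
impc_viability <- function() {
  utils::read.delim(published_path("impc_viability.tsv"),
                    stringsAsFactors = FALSE)
}

#' @rdname impc_viability
#' @export
essential_lethality_counts <- function() {
  utils::read.delim(published_path("essential_lethality.tsv"),
                    stringsAsFactors = FALSE)
}
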