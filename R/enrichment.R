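# Phenotype-linkage enrichment: the fraction of screen/mutation
# combinations whose Bonferroni-adjusted linkage P value falls below a
# threshold, with exact (Clopper-Pearson) binomial confidence intervals,
# compared between mutations in essential and non-essential genes.

#' Fraction of significant screen/mutation combinations
#'
#' Counts the proportion of combinations with `p_value` strictly below
#' `p_threshold` and attaches a Clopper-Pearson 95% interval (the exact
#' interval from the binomial distribution). When `collapse_models` is
#' `"min"` (default), records of the same (mutation, screen) pair under
#' different transmission models are collapsed to one combination by
#' taking their minimum adjusted P value; `"none"` counts each
#' (mutation, screen, model) record separately.
#'
#' @param records A `screen_linkage_table` (see [read_screen_linkage()]),
#'   already restricted to the mutation set of interest.
#' @param p_threshold Significance threshold (default 1e-5, strict `<`).
#' @param level CI coverage (default 0.95).
#' @param collapse_models `"min"` or `"none"`.
#' @param label Gene-set label carried into the result.
#' @return One-row data frame: `gene_set`, `n_combinations`,
#'   `n_significant`, `proportion`, `ci_low`, `ci_high`.
#' @export
significant_fraction <- function(records, p_threshold = 1e-5, level = 0.95,
                                 collapse_models = c("min", "none"),
                                 label = "all") {
  collapse_models <- match.arg(collapse_models)
  r <- as.data.frame(records)
  if (nrow(r) == 0) stop_fmt("no screen/mutation combinations to analyse")
  p <- if (collapse_models == "min") {
    as.numeric(tapply(r$p_value, paste(r$mutation_id, r$screen_id, sep = "\r"),
                      min))
  } else {
    r$p_value
  }
  x <- sum(p < p_threshold)
  n <- length(p)
  ci <- stats::binom.test(x, n, conf.level = level)$conf.int
  data.frame(gene_set = label, n_combinations = n, n_significant = x,
             proportion = x / n, ci_low = ci[1], ci_high = ci[2],
             stringsAsFactors = FALSE)
}

#' Enrichment of significant linkage in essential vs non-essential genes
#'
#' Splits the screen/mutation combinations by the essentiality of each
#' mutation's gene and computes [significant_fraction()] for both sets.
#' Also reports each set's class composition (fraction of
#' probably-damaging and of putative-null mutations) as a confounding
#' check: a higher significant fraction in essential genes is only
#' meaningful if the two sets carry comparably damaging mutation spectra.
#'
#' @param records A `screen_linkage_table`.
#' @param mutations A `mutation_table` resolving `mutation_id` to
#'   `gene_id` and `mutation_class`.
#' @param annotations An `essentiality_table`; genes absent from it count
#'   as non-essential.
#' @inheritParams significant_fraction
#' @return List with `enrichment` (two-row data frame) and `composition`
#'   (per-set class-fraction table).
#' @export
compare_gene_sets <- function(records, mutations, annotations,
                              p_threshold = 1e-5, level = 0.95,
                              collapse_models = c("min", "none")) {
  collapse_models <- match.arg(collapse_models)
  r <- as.data.frame(records)
  idx <- match(r$mutation_id, mutations$mutation_id)
  if (anyNA(idx))
    stop_fmt("screen records refer to unknown mutation(s): %s",
             paste(unique(r$mutation_id[is.na(idx)]), collapse = ", "))
  gene <- mutations$gene_id[idx]
  ess_genes <- annotations$gene_id[annotations$essential]
  set <- ifelse(gene %in% ess_genes, "essential", "non_essential")
  enr <- do.call(rbind, lapply(c("essential", "non_essential"), function(s) {
    sub <- r[set == s, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(gene_set = s, n_combinations = 0L, n_significant = 0L,
                        proportion = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE))
    significant_fraction(sub, p_threshold, level, collapse_models, label = s)
  }))
  mut_set <- ifelse(mutations$gene_id %in% ess_genes, "essential", "non_essential")
  used <- mutations$mutation_id %in% r$mutation_id
  comp <- do.call(rbind, lapply(c("essential", "non_essential"), function(s) {
    cls <- mutations$mutation_class[used & mut_set == s]
    data.frame(gene_set = s, n_mutations = length(cls),
               frac_probably_damaging = mean(cls == "probably_damaging"),
               frac_probably_null = mean(cls %in% c("null_class_I", "null_class_II")),
               stringsAsFactors = FALSE)
  }))
  list(enrichment = enr, composition = comp)
}
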