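# Filtering cascade applied before damage-probability estimation, plus the
# per-mutation homozygote proportion p_hom. Each filter is a pure predicate
# on the mutation table, so filters commute and the cascade equals the
# intersection of the individual subsets.

#' Keep mutations isolated from same-pedigree neighbours
#'
#' Removes mutations lying strictly closer than `threshold_bp` to any other
#' mutation on the same chromosome within the same pedigree, so that
#' phenotypic effects can be attributed to single genes (meiotic
#' unlinkage). The default 1e8 bp (100 Mb) keeps a mutation only if its
#' nearest same-chromosome, same-pedigree neighbour is at least 100 Mb
#' away; exactly 100 Mb apart is retained. Mutations on different
#' chromosomes, or in different pedigrees, never exclude each other.
#'
#' @param mutations A `mutation_table` (see [read_mutations()]).
#' @param threshold_bp Exclusion distance in base pairs (1 Mb = 1e6 bp).
#' @return The retained subset, same class.
#' @export
#' @examples
#' m <- validate_mutations(data.frame(
#'   mutation_id = c("a", "b"), pedigree_id = "P1", gene_id = c("g1", "g2"),
#'   chromosome = "chr1", position = c(10e6, 120e6),
#'   mutation_class = "probably_benign", score = 0.1))
#' nrow(filter_isolated(m))  # 110 Mb apart -> both kept
filter_isolated <- function(mutations, threshold_bp = 1e8) {
  if (nrow(mutations) == 0) return(mutations)
  keep <- rep(TRUE, nrow(mutations))
  groups <- split(seq_len(nrow(mutations)),
                  list(mutations$pedigree_id, mutations$chromosome),
                  drop = TRUE)
  for (idx in groups) {
    if (length(idx) < 2) next
    pos <- sort(mutations$position[idx])
    gaps <- diff(pos)
    # a sorted position is crowded iff the gap to either neighbour is < threshold
    crowded_sorted <- c(gaps < threshold_bp, FALSE) | c(FALSE, gaps < threshold_bp)
    crowded_pos <- unique(pos[crowded_sorted])
    keep[idx][mutations$position[idx] %in% crowded_pos] <- FALSE
  }
  mutations[keep, , drop = FALSE]
}

#' Keep mutations from pedigrees with enough G3 mice
#'
#' Retains mutations whose pedigree has at least `min_g3` genotyped G3
#' mice of any genotype (the boundary is inclusive: exactly `min_g3`
#' passes).
#'
#' @param mutations A `mutation_table`.
#' @param genotypes A `genotype_table` covering the mutations' pedigrees.
#' @param min_g3 Minimum number of G3 mice (default 3).
#' @return The retained subset.
#' @export
filter_min_g3 <- function(mutations, genotypes, min_g3 = 3) {
  if (nrow(mutations) == 0) return(mutations)
  mice <- mice_of(genotypes)
  unknown <- setdiff(mutations$pedigree_id, mice$pedigree_id)
  if (length(unknown) > 0)
    stop_fmt("no genotyped mice for pedigree(s): %s",
             paste(unknown, collapse = ", "))
  g3 <- mice[mice$generation == "G3", , drop = FALSE]
  counts <- table(g3$pedigree_id)
  n_g3 <- as.integer(counts[mutations$pedigree_id])
  n_g3[is.na(n_g3)] <- 0L
  mutations[n_g3 >= min_g3, , drop = FALSE]
}

#' Keep mutations in annotated-essential genes
#'
#' Retains mutations whose gene is annotated essential. Genes absent from
#' the annotation are treated as non-essential (annotation coverage is
#' partial) and a warning is logged with their count.
#'
#' @param mutations A `mutation_table`.
#' @param annotations An `essentiality_table` (see [read_essentiality()]).
#' @return The retained subset.
#' @export
filter_essential <- function(mutations, annotations) {
  if (nrow(mutations) == 0) return(mutations)
  ess_genes <- annotations$gene_id[annotations$essential]
  unannotated <- setdiff(unique(mutations$gene_id), annotations$gene_id)
  if (length(unannotated) > 0)
    log_msg(sprintf("%d gene(s) absent from essentiality annotation; treated as non-essential",
                    length(unannotated)), level = "WARN")
  mutations[mutations$gene_id %in% ess_genes, , drop = FALSE]
}

#' Homozygote proportion per mutation
#'
#' For each mutation, computes `p_hom`: the proportion of HOM G3 mice out
#' of all genotyped G3 mice in litters segregating the mutation. Since the
#' G1 sire is heterozygous by construction, a litter segregates the
#' mutation iff its G2 dam is HET for it; the denominator is therefore all
#' genotyped G3 offspring of HET dams, under which `p_hom` has Mendelian
#' expectation 0.25 in the absence of lethality. Mutations with no
#' informative offspring (no HET dam, or no genotyped pups) get
#' `p_hom = NA` and `informative = FALSE`; downstream estimators exclude
#' them.
#'
#' @param mutations A `mutation_table`.
#' @param genotypes A `genotype_table` with G2 dam and G3 calls.
#' @return The mutation table with columns `n_g3` (denominator), `n_hom`
#'   (HOM count), `p_hom`, `informative` appended; class
#'   `filtered_mutation_table`.
#' @export
compute_p_hom <- function(mutations, genotypes) {
  g <- as.data.frame(genotypes)
  # HET dams per mutation
  dams <- g[g$generation == "G2" & g$genotype == "HET",
            c("mouse_id", "mutation_id")]
  het_dam_key <- paste(dams$mutation_id, dams$mouse_id)
  g3 <- g[g$generation == "G3", , drop = FALSE]
  eligible <- g3[paste(g3$mutation_id, g3$dam_id) %in% het_dam_key, , drop = FALSE]
  n_g3 <- table(factor(eligible$mutation_id, levels = mutations$mutation_id))
  n_hom <- table(factor(eligible$mutation_id[eligible$genotype == "HOM"],
                        levels = mutations$mutation_id))
  out <- mutations
  out$n_g3 <- as.integer(n_g3)
  out$n_hom <- as.integer(n_hom)
  out$p_hom <- ifelse(out$n_g3 > 0, out$n_hom / out$n_g3, NA_real_)
  out$informative <- out$n_g3 > 0
  if (any(!out$informative))
    log_msg(sprintf("%d mutation(s) have no G3 offspring of HET dams; p_hom undefined",
                    sum(!out$informative)), level = "WARN")
  class(out) <- c("filtered_mutation_table", class(mutations))
  out
}

#' Phenotype-analysis mutation subset
#'
#' The stricter subset used for phenotype-linkage enrichment: isolated
#' mutations from pedigrees with at least `min_g3` G3 mice of any genotype
#' that reached homozygosity in at least `min_p_hom` of G3 mice (both
#' boundaries inclusive). `p_hom` must already be computed; uninformative
#' mutations are removed.
#'
#' @param mutations A `filtered_mutation_table` from [compute_p_hom()].
#' @param genotypes A `genotype_table`.
#' @param threshold_bp Isolation distance (default 100 Mb).
#' @param min_g3 Minimum G3 mice per pedigree (default 4).
#' @param min_p_hom Minimum homozygote proportion (default 0.25).
#' @return The retained subset.
#' @export
filter_for_phenotype <- function(mutations, genotypes, threshold_bp = 1e8,
                                 min_g3 = 4, min_p_hom = 0.25) {
  if (!"p_hom" %in% names(mutations))
    stop_fmt("filter_for_phenotype requires p_hom; call compute_p_hom() first")
  out <- filter_isolated(mutations, threshold_bp)
  out <- filter_min_g3(out, genotypes, min_g3 = min_g3)
  out[out$informative & out$p_hom >= min_p_hom, , drop = FALSE]
}
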