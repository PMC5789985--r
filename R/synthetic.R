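# Synthetic cohort generator. Emulates the statistical structure of a
# large ENU mutagenesis program: pedigrees founded by an exome-sequenced
# G1 male heterozygous for every pedigree mutation, G2 daughters
# backcrossed to the G1 sire (HET or REF per locus), about 30 weaned G3
# mice per pedigree each carrying about 34 mutations, a five-class
# mutation spectrum, latent essentiality (partial:total 39:100) and
# per-class truly-damaging fractions, with homozygous lethality applied
# before "weaning". Every latent label is recorded in a truth table so
# the whole inference stack can be validated against known ground truth.

#' Generator configuration
#'
#' @param n_pedigrees Number of pedigrees.
#' @param g3_mean Mean weaned-cohort target per pedigree before lethality
#'   (Poisson, truncated at 1; default 30).
#' @param mutations_mean Mean mutations per pedigree (Poisson, truncated
#'   at 1; default 55, which makes each G3 mouse carry about 34 mutations
#'   since a pup carries a locus with probability 3/4 under a HET dam and
#'   1/2 under a REF dam).
#' @param class_mix Named proportions over [mutation_classes()]; default:
#'   the empirical spectrum of a large mutagenesis cohort
#'   (26004 / 14412 / 32669 / 5170 / 2618 out of 80873 for benign /
#'   possibly / probably damaging / null I / null II). Must sum to 1
#'   within 1e-9.
#' @param true_damage_fractions Named per-class probabilities that a
#'   mutation truly damages the protein (default [default_damage_map()]).
#' @param essential_fraction Fraction of genes that are essential
#'   (default 0.34).
#' @param partial_ratio Partially:totally essential ratio (default 0.39).
#' @param theta Center of the surviving-homozygote proportion for
#'   damaging mutations in partially essential genes (default 0.125);
#'   the generator kills each such HOM pup with probability
#'   `1 - theta / 0.25` so the surviving proportion centers on `theta`.
#' @param n_dams Number of G2 dams per pedigree (default 2).
#' @param litter_mean Mean litter size used to assign litter ids
#'   (default 7).
#' @param chromosome_lengths Named lengths in bp (default
#'   [mouse_autosome_lengths()]).
#' @param gene_collision_rate Probability that a mutation hits an
#'   already-mutated gene, creating multi-allele genes and superpedigrees
#'   (default 0).
#' @param seed Integer master seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_pedigrees = 100, g3_mean = 30,
                             mutations_mean = 55,
                             class_mix = NULL,
                             true_damage_fractions = default_damage_map(),
                             essential_fraction = 0.34,
                             partial_ratio = 0.39, theta = 0.125,
                             n_dams = 2, litter_mean = 7,
                             chromosome_lengths = mouse_autosome_lengths(),
                             gene_collision_rate = 0, seed = 1L) {
  class_mix <- class_mix %||%
    stats::setNames(c(26004, 14412, 32669, 5170, 2618) / 80873,
                    mutation_classes())
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop_fmt("class_mix must sum to 1 (got %.12f)", sum(class_mix))
  missing <- setdiff(mutation_classes(), names(class_mix))
  if (length(missing) > 0)
    stop_fmt("class_mix is missing class(es): %s", paste(missing, collapse = ", "))
  stopifnot(essential_fraction >= 0, essential_fraction <= 1,
            theta > 0, theta < 0.25, gene_collision_rate >= 0,
            gene_collision_rate < 1, n_dams >= 1)
  structure(list(n_pedigrees = as.integer(n_pedigrees), g3_mean = g3_mean,
                 mutations_mean = mutations_mean,
                 class_mix = class_mix[mutation_classes()],
                 true_damage_fractions = validate_damage_map(true_damage_fractions),
                 essential_fraction = essential_fraction,
                 partial_ratio = partial_ratio, theta = theta,
                 n_dams = as.integer(n_dams), litter_mean = litter_mean,
                 chromosome_lengths = chromosome_lengths,
                 gene_collision_rate = gene_collision_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# score band per missense class; null classes carry no score
score_range <- function(cls) {
  switch(cls,
         probably_benign   = c(0, 0.45),
         possibly_damaging = c(0.45, 0.95),
         probably_damaging = c(0.95, 1),
         c(NA_real_, NA_real_))
}

rpois_min1 <- function(n, mean) pmax(1L, stats::rpois(n, mean))

#' Generate a synthetic mutagenesis dataset
#'
#' Draws pedigrees, mutations, parental genotypes and Mendelian G3
#' offspring per the configuration, applies pre-weaning lethality for
#' homozygous truly-damaging mutations in essential genes (deterministic
#' for totally essential genes; with probability `1 - theta/0.25` for
#' partially essential ones), and returns the surviving cohort together
#' with full ground truth. The same seed yields an identical dataset.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_dataset` with elements `mutations`
#'   (a `mutation_table`), `genotypes` (a `genotype_table` of G1/G2 mice
#'   and weaned G3 mice), `essentiality` (an `essentiality_table` over all
#'   genes), `truth` (per-mutation latent labels), `pedigrees` (born and
#'   weaned counts) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed)
  chr_names <- names(config$chromosome_lengths)
  chr_w <- config$chromosome_lengths / sum(config$chromosome_lengths)
  p_partial <- config$partial_ratio / (1 + config$partial_ratio)
  p_die_partial <- 1 - config$theta / 0.25

  mut_list <- list(); gen_list <- list(); ped_list <- list()
  gene_pool <- character(0)   # essential status assigned on first use
  gene_ess <- logical(0); gene_mode <- character(0)
  next_gene <- 1L

  for (p in seq_len(config$n_pedigrees)) {
    ped <- sprintf("P%04d", p)
    n_mut <- rpois_min1(1, config$mutations_mean)
    cls <- sample(names(config$class_mix), n_mut, replace = TRUE,
                  prob = config$class_mix)
    chrom <- sample(chr_names, n_mut, replace = TRUE, prob = chr_w)
    pos <- as.integer(floor(stats::runif(n_mut) *
                              config$chromosome_lengths[chrom]) + 1)
    score <- vapply(cls, function(cl) {
      r <- score_range(cl)
      if (anyNA(r)) NA_real_ else stats::runif(1, r[1], r[2])
    }, numeric(1))
    # gene assignment; collisions resample the pool as of pedigree start
    gene <- character(n_mut)
    collide <- length(gene_pool) > 0 &
      stats::runif(n_mut) < config$gene_collision_rate
    if (any(collide))
      gene[collide] <- sample(gene_pool, sum(collide), replace = TRUE)
    n_new <- sum(!collide)
    if (n_new > 0) {
      new_ids <- sprintf("gene%05d", next_gene + seq_len(n_new) - 1L)
      next_gene <- next_gene + n_new
      gene[!collide] <- new_ids
      is_ess <- stats::runif(n_new) < config$essential_fraction
      mode <- rep("unknown", n_new)
      mode[is_ess] <- ifelse(stats::runif(sum(is_ess)) < p_partial,
                             "partially", "totally")
      gene_pool <- c(gene_pool, new_ids)
      gene_ess <- c(gene_ess, is_ess)
      gene_mode <- c(gene_mode, mode)
    }
    damaging <- stats::runif(n_mut) < config$true_damage_fractions[cls]
    mut_id <- sprintf("%s_m%03d", ped, seq_len(n_mut))
    mut_list[[p]] <- data.frame(
      mutation_id = mut_id, pedigree_id = ped, gene_id = gene,
      chromosome = chrom, position = pos, mutation_class = cls,
      score = score, damaging = damaging, stringsAsFactors = FALSE)

    # parents: G1 sire HET everywhere; each dam HET or REF per locus
    dam_ids <- sprintf("%s_G2_%d", ped, seq_len(config$n_dams))
    dam_geno <- matrix(ifelse(stats::runif(config$n_dams * n_mut) < 0.5,
                              "HET", "REF"),
                       config$n_dams, n_mut)
    # offspring: target size split evenly over dams
    n_target <- rpois_min1(1, config$g3_mean)
    dam_of_pup <- sample(rep_len(seq_len(config$n_dams), n_target))
    J <- n_mut
    from_dam <- matrix(stats::rbinom(n_target * J, 1L,
                                     rep(TRANSMIT_PROB[t(dam_geno)[, dam_of_pup]],
                                         times = 1)),
                       nrow = J)
    from_sire <- matrix(stats::rbinom(n_target * J, 1L, 0.5), nrow = J)
    alleles <- from_dam + from_sire           # J x n_target
    # pre-weaning lethality
    ess_of <- gene_ess[match(gene, gene_pool)]
    mode_of <- gene_mode[match(gene, gene_pool)]
    lethal_total <- damaging & ess_of & mode_of == "totally"
    lethal_partial <- damaging & ess_of & mode_of == "partially"
    hom <- alleles == 2L
    dead <- colSums(hom[lethal_total, , drop = FALSE]) > 0
    ph <- hom[lethal_partial, , drop = FALSE]
    if (any(ph)) {
      coin <- matrix(FALSE, nrow(ph), ncol(ph))
      coin[ph] <- stats::runif(sum(ph)) < p_die_partial
      dead <- dead | colSums(coin) > 0
    }
    survivors <- which(!dead)
    # litter ids per dam (chunks of litter_mean pups, ordered by birth)
    litter_of_pup <- integer(n_target)
    for (d in seq_len(config$n_dams)) {
      pups <- which(dam_of_pup == d)
      litter_of_pup[pups] <- ceiling(seq_along(pups) / config$litter_mean)
    }
    glevels <- GENOTYPE_LEVELS
    g3_rows <- if (length(survivors) > 0) {
      data.frame(
        mouse_id = rep(sprintf("%s_G3_%03d", ped, survivors), each = J),
        pedigree_id = ped, generation = "G3",
        dam_id = rep(dam_ids[dam_of_pup[survivors]], each = J),
        litter_id = rep(sprintf("%s_L%d",
                                dam_ids[dam_of_pup[survivors]],
                                litter_of_pup[survivors]), each = J),
        mutation_id = rep(mut_id, times = length(survivors)),
        genotype = glevels[as.vector(alleles[, survivors, drop = FALSE]) + 1L],
        stringsAsFactors = FALSE)
    } else NULL
    parent_rows <- data.frame(
      mouse_id = c(rep(sprintf("%s_G1", ped), J),
                   rep(dam_ids, each = J)),
      pedigree_id = ped,
      generation = c(rep("G1", J), rep("G2", config$n_dams * J)),
      dam_id = NA_character_, litter_id = NA_character_,
      mutation_id = c(mut_id, rep(mut_id, config$n_dams)),
      genotype = c(rep("HET", J), as.vector(t(dam_geno))),
      stringsAsFactors = FALSE)
    gen_list[[p]] <- rbind(parent_rows, g3_rows)
    ped_list[[p]] <- data.frame(pedigree_id = ped, n_born = n_target,
                                n_weaned = length(survivors),
                                n_dams = config$n_dams,
                                n_litters = length(unique(paste(dam_of_pup,
                                                                litter_of_pup))),
                                stringsAsFactors = FALSE)
  }

  all_mut <- do.call(rbind, mut_list)
  truth <- data.frame(mutation_id = all_mut$mutation_id,
                      gene_id = all_mut$gene_id,
                      mutation_class = all_mut$mutation_class,
                      damaging = all_mut$damaging,
                      essential = gene_ess[match(all_mut$gene_id, gene_pool)],
                      lethality_mode = gene_mode[match(all_mut$gene_id, gene_pool)],
                      stringsAsFactors = FALSE)
  mutations <- validate_mutations(all_mut[c("mutation_id", "pedigree_id",
                                            "gene_id", "chromosome", "position",
                                            "mutation_class", "score")],
                                  where = "synthetic")
  genotypes <- do.call(rbind, gen_list)
  rownames(genotypes) <- NULL
  class(genotypes) <- c("genotype_table", "data.frame")
  essentiality <- data.frame(gene_id = gene_pool, essential = gene_ess,
                             lethality_mode = gene_mode,
                             stringsAsFactors = FALSE)
  class(essentiality) <- c("essentiality_table", "data.frame")
  structure(list(mutations = mutations, genotypes = genotypes,
                 essentiality = essentiality, truth = truth,
                 pedigrees = do.call(rbind, ped_list), config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d pedigree(s), %d mutation(s), %d weaned G3 mice\n",
              nrow(x$pedigrees), nrow(x$mutations), sum(x$pedigrees$n_weaned)))
  invisible(x)
}

#' Write a synthetic dataset to TSV files
#'
#' Emits `mutations.tsv`, `genotypes.tsv`, `essentiality.tsv` and
#' `truth.tsv` in the package's TSV dialect, plus `config.yaml` recording
#' the generator configuration (provenance).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(dataset$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(dataset$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(dataset$essentiality, file.path(dir, "essentiality.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  cfg <- dataset$config
  cfg$chromosome_lengths <- as.list(cfg$chromosome_lengths)
  cfg$class_mix <- as.list(cfg$class_mix)
  cfg$true_damage_fractions <- as.list(cfg$true_damage_fractions)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Generate a synthetic screen-linkage table
#'
#' Emits one record per (mutation, screen) combination. A combination is
#' significant with the rate of the mutation's gene set (essential vs
#' non-essential); significant records draw their Bonferroni-adjusted P
#' value uniformly below `p_threshold`, others uniformly in
#' `[p_threshold, 1]`. The transmission model is sampled uniformly.
#'
#' @param mutations A `mutation_table`.
#' @param annotations An `essentiality_table` (genes absent count as
#'   non-essential).
#' @param rates Named vector `c(essential = ..., non_essential = ...)` of
#'   per-combination significance rates.
#' @param n_screens Number of phenotypic screens (default 296).
#' @param p_threshold Significance boundary used for the draw (default
#'   1e-5).
#' @param seed Integer seed.
#' @return A `screen_linkage_table`.
#' @export
generate_screen_table <- function(mutations, annotations, rates,
                                  n_screens = 296, p_threshold = 1e-5,
                                  seed = NULL) {
  stopifnot(all(c("essential", "non_essential") %in% names(rates)),
            all(rates >= 0 & rates <= 1))
  local_seed(seed)
  ess_genes <- annotations$gene_id[annotations$essential]
  set <- ifelse(mutations$gene_id %in% ess_genes, "essential", "non_essential")
  n <- nrow(mutations) * n_screens
  rate <- rep(unname(rates[set]), each = n_screens)
  sig <- stats::runif(n) < rate
  p <- ifelse(sig, stats::runif(n) * p_threshold,
              p_threshold + stats::runif(n) * (1 - p_threshold))
  out <- data.frame(
    mutation_id = rep(mutations$mutation_id, each = n_screens),
    screen_id = rep(sprintf("screen%03d", seq_len(n_screens)),
                    times = nrow(mutations)),
    model = sample(c("recessive", "additive", "dominant"), n, replace = TRUE),
    p_value = p, stringsAsFactors = FALSE)
  class(out) <- c("screen_linkage_table", "data.frame")
  out
}

#' Draw homozygote proportions from the three-subgroup mixture
#'
#' Samples per-mutation homozygote proportions under the estimator's
#' generative model for one class whose total truly-damaging fraction is
#' `rho`. Damaging mutations split between totally and partially
#' essential genes at `partial_ratio` (100:39 by default), so the three
#' subgroup weights are `rho / (1 + partial_ratio)` (all homozygotes die:
#' 0 HOM out of the litter size), `rho * partial_ratio /
#' (1 + partial_ratio)` (HOM count binomial around `theta`) and `1 - rho`
#' (binomial around the Mendelian 0.25). Under these weights the
#' method-of-moments estimator is unbiased for `rho`. Litter sizes are
#' Poisson with mean `litter_mean` (truncated at `min_size`), mimicking
#' finite pedigrees.
#'
#' @param n Number of mutations.
#' @param rho Total truly-damaging fraction in \[0, 1\].
#' @param params An [mm_params()].
#' @param litter_mean Mean G3 count per mutation (default 30).
#' @param min_size Smallest G3 count (default 3, matching the pedigree
#'   filter).
#' @param seed Integer seed.
#' @return Numeric vector of `n` homozygote proportions.
#' @export
simulate_class_phom <- function(n, rho, params = mm_params(),
                                litter_mean = 30, min_size = 3, seed = NULL) {
  if (rho < 0 || rho > 1) stop_fmt("rho must lie in [0, 1]")
  local_seed(seed)
  sizes <- pmax(min_size, stats::rpois(n, litter_mean))
  w_total <- rho / (1 + params$partial_ratio)
  w_partial <- rho * params$partial_ratio / (1 + params$partial_ratio)
  u <- stats::runif(n)
  p_center <- ifelse(u < w_total, 0,
                     ifelse(u < w_total + w_partial,
                            params$theta, params$mendelian_rate))
  stats::rbinom(n, sizes, p_center) / sizes
}
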