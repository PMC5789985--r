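# In-silico breeding of virtual G3 mice and the essential-gene-fraction
# scan. The observed statistic is the number of genes carrying any
# mutation for which at least one homozygous G3 mouse survived to weaning;
# the scan simulates that statistic across a grid of assumed essential
# fractions and inverts the (linear) trend at the observed value.

#' Simulation scenario for the essentiality scan
#'
#' @param essential_fraction_grid Fractions of genes assumed essential, in
#'   \[0, 1\] (default `seq(0, 0.6, by = 0.02)`).
#' @param partial_ratio Ratio of partially to totally essential genes
#'   (default 0.39, i.e. 39:100); an essential gene is partially essential
#'   with probability `partial_ratio / (1 + partial_ratio)`.
#' @param partial_cull_rate Probability that a pup homozygous for a truly
#'   damaging mutation in a partially essential gene dies before weaning
#'   (default 0.5).
#' @param replicates Simulations per grid point (default 5).
#' @param damage_map Per-class probabilities that a mutation is truly
#'   damaging (default [default_damage_map()]).
#' @param seed Integer master seed for the scan.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(essential_fraction_grid = seq(0, 0.6, by = 0.02),
                         partial_ratio = 0.39, partial_cull_rate = 0.5,
                         replicates = 5, damage_map = default_damage_map(),
                         seed = NULL) {
  if (any(essential_fraction_grid < 0 | essential_fraction_grid > 1))
    stop_fmt("essential fractions must lie in [0, 1]")
  if (partial_cull_rate < 0 || partial_cull_rate > 1)
    stop_fmt("partial_cull_rate must lie in [0, 1]")
  structure(list(essential_fraction_grid = sort(unique(essential_fraction_grid)),
                 partial_ratio = partial_ratio,
                 partial_cull_rate = partial_cull_rate,
                 replicates = as.integer(replicates),
                 damage_map = validate_damage_map(damage_map),
                 seed = seed),
            class = "sim_scenario")
}

#' Pedigree-size regression for neutral litter sizes
#'
#' Fits an ordinary-least-squares model of observed G3 counts per pedigree
#' on pedigree covariates (pedigree type, number of litters, per-class
#' mutation counts carried by the G2 mothers). Setting the mutation-count
#' covariates to zero then predicts the pedigree size expected if every
#' mutation were neutral — the size at which virtual G3 cohorts are bred.
#'
#' @param ped_table Data frame, one row per pedigree, containing
#'   `size_col`, the covariates and the mutation-count columns.
#' @param size_col Name of the observed-size column (default "n_g3").
#' @param covariate_cols Names of non-mutation covariates (may be empty
#'   for an intercept-only model).
#' @param mutation_cols Names of the per-class mutation-count columns that
#'   are zeroed for the neutral prediction.
#' @return Object of class `pedigree_size_model` wrapping the [stats::lm]
#'   fit.
#' @export
fit_pedigree_size_model <- function(ped_table, size_col = "n_g3",
                                    covariate_cols = character(0),
                                    mutation_cols = character(0)) {
  cols <- c(size_col, covariate_cols, mutation_cols)
  missing <- setdiff(cols, names(ped_table))
  if (length(missing) > 0)
    stop_fmt("ped_table is missing column(s): %s", paste(missing, collapse = ", "))
  rhs <- c(covariate_cols, mutation_cols)
  fml <- stats::reformulate(if (length(rhs) > 0) rhs else "1",
                            response = size_col)
  fit <- stats::lm(fml, data = ped_table)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop_fmt("rank-deficient pedigree-size design; collinear term(s): %s",
             paste(bad, collapse = ", "))
  }
  structure(list(fit = fit, size_col = size_col,
                 covariate_cols = covariate_cols,
                 mutation_cols = mutation_cols),
            class = "pedigree_size_model")
}

#' @rdname fit_pedigree_size_model
#' @param model A fitted `pedigree_size_model`.
#' @param newdata Covariate rows to predict for (default: the training
#'   table).
#' @return Integer vector of neutral pedigree sizes (mutation counts
#'   zeroed, prediction rounded to the nearest nonnegative integer).
#' @export
predict_neutral_sizes <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "pedigree_size_model"))
  nd <- newdata %||% model$fit$model
  nd <- as.data.frame(nd)
  for (col in model$mutation_cols) nd[[col]] <- 0
  pred <- stats::predict(model$fit, newdata = nd)
  as.integer(pmax(0, round(pred)))
}

#' Breed virtual G3 mice for one mating
#'
#' Draws genotypes for `n_pups` virtual offspring of one G2 dam x G1 sire
#' mating. Per mutation, each pup receives one allele from each parent
#' independently (a HET parent transmits the variant with probability 1/2,
#' HOM with 1, REF with 0); loci are unlinked.
#'
#' @param dam_genotypes Named character vector (REF/HET/HOM) of the dam's
#'   genotypes, one per mutation.
#' @param sire_genotypes Same for the sire; default: HET at every locus
#'   (the G1 grandsire carries every pedigree mutation heterozygously).
#' @param n_pups Number of virtual pups.
#' @param seed Integer seed.
#' @return Character matrix `n_pups` x loci of REF/HET/HOM calls, columns
#'   named by mutation.
#' @export
breed_virtual_g3 <- function(dam_genotypes, sire_genotypes = NULL, n_pups,
                             seed = NULL) {
  loci <- names(dam_genotypes)
  if (is.null(loci)) stop_fmt("dam_genotypes must be named by mutation id")
  sire_genotypes <- sire_genotypes %||%
    stats::setNames(rep("HET", length(loci)), loci)
  if (!all(dam_genotypes %in% GENOTYPE_LEVELS) ||
      !all(sire_genotypes[loci] %in% GENOTYPE_LEVELS))
    stop_fmt("parental genotypes must be REF, HET or HOM")
  local_seed(seed)
  J <- length(loci)
  p_dam <- TRANSMIT_PROB[dam_genotypes]
  p_sire <- TRANSMIT_PROB[sire_genotypes[loci]]
  from_dam <- matrix(stats::rbinom(n_pups * J, 1L, rep(p_dam, each = n_pups)),
                     n_pups, J)
  from_sire <- matrix(stats::rbinom(n_pups * J, 1L, rep(p_sire, each = n_pups)),
                      n_pups, J)
  alleles <- from_dam + from_sire
  out <- matrix(GENOTYPE_LEVELS[alleles + 1L], n_pups, J,
                dimnames = list(NULL, loci))
  out
}

#' Assign essentiality and truly-damaging labels
#'
#' Marks a uniformly random fraction of genes essential; splits essential
#' genes into partially vs totally essential at the scenario's
#' `partial_ratio` (39:100 by default); and marks each mutation truly
#' damaging independently with its class probability from the scenario's
#' damage map.
#'
#' @param genes Character vector of gene ids.
#' @param mutations Data frame with `mutation_id`, `gene_id`,
#'   `mutation_class`.
#' @param essential_fraction Fraction of genes to mark essential.
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed.
#' @return List with `genes` (gene_id, essential, lethality_mode) and
#'   `mutations` (mutation_id, damaging).
#' @export
assign_essentiality_and_damage <- function(genes, mutations,
                                           essential_fraction, scenario,
                                           seed = NULL) {
  local_seed(seed)
  ess <- stats::runif(length(genes)) < essential_fraction
  p_partial <- scenario$partial_ratio / (1 + scenario$partial_ratio)
  mode <- rep("unknown", length(genes))
  mode[ess] <- ifelse(stats::runif(sum(ess)) < p_partial, "partially", "totally")
  damaging <- stats::runif(nrow(mutations)) <
    scenario$damage_map[mutations$mutation_class]
  list(genes = data.frame(gene_id = genes, essential = ess,
                          lethality_mode = mode, stringsAsFactors = FALSE),
       mutations = data.frame(mutation_id = mutations$mutation_id,
                              damaging = damaging, stringsAsFactors = FALSE))
}

#' Cull virtual pups by homozygous lethality
#'
#' A pup homozygous for a truly damaging mutation in a totally essential
#' gene is removed deterministically; a pup homozygous for a truly
#' damaging mutation in a partially essential gene is removed with
#' probability `partial_cull_rate` (independent coin per pup-mutation
#' pair). A pup qualifying under both rules is removed deterministically.
#'
#' @param genotypes Character matrix from [breed_virtual_g3()] (pups x
#'   mutations).
#' @param mutations Data frame with `mutation_id`, `gene_id`.
#' @param labels Output of [assign_essentiality_and_damage()].
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed for the partial-lethality coin flips.
#' @return Logical vector: TRUE for surviving pups.
#' @export
cull <- function(genotypes, mutations, labels, scenario, seed = NULL) {
  local_seed(seed)
  loci <- colnames(genotypes)
  info <- merge(merge(data.frame(mutation_id = loci, stringsAsFactors = FALSE),
                      mutations[c("mutation_id", "gene_id")], sort = FALSE),
                labels$mutations, sort = FALSE)
  info <- merge(info, labels$genes, by = "gene_id", sort = FALSE)
  info <- info[match(loci, info$mutation_id), , drop = FALSE]
  lethal_total <- info$damaging & info$essential & info$lethality_mode == "totally"
  lethal_partial <- info$damaging & info$essential & info$lethality_mode == "partially"
  hom <- genotypes == "HOM"
  dead <- rowSums(hom[, lethal_total, drop = FALSE]) > 0
  part_hom <- hom[, lethal_partial, drop = FALSE]
  if (any(part_hom)) {
    flips <- matrix(FALSE, nrow(part_hom), ncol(part_hom))
    flips[part_hom] <- stats::runif(sum(part_hom)) < scenario$partial_cull_rate
    dead <- dead | rowSums(flips) > 0
  }
  !dead
}

#' Bundle a dataset for the essentiality scan
#'
#' @param mutations A `mutation_table` (needs mutation_id, gene_id,
#'   mutation_class, pedigree_id).
#' @param dams Data frame of G2 dam genotypes: `dam_id`, `pedigree_id`,
#'   `mutation_id`, `genotype` (REF/HET/HOM), covering every pedigree
#'   mutation for every dam.
#' @param dam_sizes Data frame `dam_id`, `n_pups`: virtual litter size per
#'   dam under the all-neutral assumption (see
#'   [predict_neutral_sizes()]).
#' @return A list of class `sim_dataset`.
#' @export
sim_dataset <- function(mutations, dams, dam_sizes) {
  stopifnot(all(c("dam_id", "pedigree_id", "mutation_id", "genotype") %in% names(dams)),
            all(c("dam_id", "n_pups") %in% names(dam_sizes)))
  missing <- setdiff(dam_sizes$dam_id, dams$dam_id)
  if (length(missing) > 0)
    stop_fmt("no genotypes for dam(s): %s", paste(missing, collapse = ", "))
  structure(list(mutations = as.data.frame(mutations),
                 dams = as.data.frame(dams),
                 dam_sizes = as.data.frame(dam_sizes)),
            class = "sim_dataset")
}

# Flattened (pup, locus) cell structure for the whole virtual cohort.
# Only homozygosity matters downstream (culling and the gene statistic),
# and a pup is HOM iff both parents transmit the variant, so each cell is
# a Bernoulli draw with probability transmit(dam) * transmit(sire).
breed_cohort_cells <- function(dataset, seed = NULL) {
  local_seed(seed)
  dams <- dataset$dams
  sizes <- dataset$dam_sizes
  sizes <- sizes[sizes$n_pups > 0, , drop = FALSE]
  d <- dams[dams$dam_id %in% sizes$dam_id, , drop = FALSE]
  n_pups <- stats::setNames(as.integer(sizes$n_pups), sizes$dam_id)[d$dam_id]
  # one cell block per (dam, locus) row of d
  cell_locus <- rep(match(d$mutation_id, dataset$mutations$mutation_id), n_pups)
  pup_offset <- c(0L, cumsum(sizes$n_pups))
  names(pup_offset) <- c(sizes$dam_id, "")
  within <- sequence(n_pups)
  cell_pup <- rep(pup_offset[d$dam_id], n_pups) + within
  p_hom <- TRANSMIT_PROB[d$genotype] * 0.5   # G1 sire is HET throughout
  cell_hom <- stats::rbinom(length(cell_pup), 1L, rep(p_hom, n_pups)) == 1L
  list(cell_pup = as.integer(cell_pup), cell_locus = as.integer(cell_locus),
       cell_hom = cell_hom, n_pups_total = sum(sizes$n_pups))
}

# genes_with_hom for one essentiality assignment on a bred cohort
count_genes_with_hom <- function(cells, dataset, lethal_total, lethal_partial,
                                 cull_rate) {
  hom_idx <- which(cells$cell_hom)
  loci <- cells$cell_locus[hom_idx]
  dead_cell <- lethal_total[loci]
  part <- lethal_partial[loci]
  if (any(part))
    dead_cell[part] <- dead_cell[part] |
      (stats::runif(sum(part)) < cull_rate)
  dead_pup <- unique(cells$cell_pup[hom_idx[dead_cell]])
  alive_hom <- hom_idx[!(cells$cell_pup[hom_idx] %in% dead_pup)]
  loci_with_hom <- unique(cells$cell_locus[alive_hom])
  genes <- unique(dataset$mutations$gene_id[loci_with_hom])
  list(genes_with_hom = length(genes),
       survivors = cells$n_pups_total - length(dead_pup))
}

#' Simulate the homozygous-damage gene count
#'
#' Breeds one virtual G3 cohort under the all-neutral assumption, then for
#' every grid fraction and replicate assigns essentiality/damage labels,
#' culls, and records the number of genes with at least one surviving
#' homozygous G3 mouse.
#'
#' @param dataset A [sim_dataset()].
#' @param scenario A [sim_scenario()]; its `seed` drives breeding and all
#'   replicate streams.
#' @return Data frame with `essential_fraction`, `replicate`,
#'   `genes_with_hom`, `virtual_g3_count`.
#' @export
simulate_genes_with_hom <- function(dataset, scenario) {
  grid <- scenario$essential_fraction_grid
  reps <- scenario$replicates
  seeds <- derive_seeds(scenario$seed %||% 1L, 1L + length(grid) * reps)
  cells <- breed_cohort_cells(dataset, seed = seeds[1])
  muts <- dataset$mutations
  genes <- unique(muts$gene_id)
  p_damage <- unname(scenario$damage_map[muts$mutation_class])
  p_partial <- scenario$partial_ratio / (1 + scenario$partial_ratio)
  out <- vector("list", length(grid) * reps)
  k <- 0L
  for (i in seq_along(grid)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      res <- local({
        local_seed(seeds[1L + k])
        ess_gene <- stats::runif(length(genes)) < grid[i]
        partial_gene <- ess_gene & (stats::runif(length(genes)) < p_partial)
        g_idx <- match(muts$gene_id, genes)
        damaging <- stats::runif(nrow(muts)) < p_damage
        lethal_total <- damaging & ess_gene[g_idx] & !partial_gene[g_idx]
        lethal_partial <- damaging & partial_gene[g_idx]
        count_genes_with_hom(cells, dataset, lethal_total, lethal_partial,
                             scenario$partial_cull_rate)
      })
      out[[k]] <- data.frame(essential_fraction = grid[i], replicate = r,
                             genes_with_hom = res$genes_with_hom,
                             virtual_g3_count = res$survivors)
    }
  }
  do.call(rbind, out)
}

#' Estimate the essential-gene fraction
#'
#' Runs [simulate_genes_with_hom()] over the scenario grid, regresses the
#' simulated gene counts on the assumed essential fraction (all replicate
#' points jointly, one straight line), and solves the fitted line for the
#' fraction at which the prediction equals the observed statistic. The
#' statistic must decrease with essentiality, so a nonnegative fitted
#' slope is an error.
#'
#' @param dataset A [sim_dataset()].
#' @param scenario A [sim_scenario()] with at least two grid points.
#' @param observed_stat Observed number of genes carrying any mutation
#'   with at least one homozygous G3 mouse (see
#'   [observed_genes_with_hom()]).
#' @return List of class `essentiality_scan`: `estimate` (clipped to
#'   \[0, 1\]), `fit` (the lm), `results` (the simulation table).
#' @export
scan_essential_fraction <- function(dataset, scenario, observed_stat) {
  if (length(scenario$essential_fraction_grid) < 2)
    stop_fmt("the essential-fraction grid needs at least 2 points")
  results <- simulate_genes_with_hom(dataset, scenario)
  fit <- stats::lm(genes_with_hom ~ essential_fraction, data = results)
  slope <- stats::coef(fit)[["essential_fraction"]]
  if (!is.finite(slope) || slope >= 0)
    stop_fmt("fitted slope is %.3g (must be negative: genes_with_hom must decrease with essentiality)",
             slope)
  est <- (observed_stat - stats::coef(fit)[["(Intercept)"]]) / slope
  structure(list(estimate = min(1, max(0, est)), fit = fit,
                 results = results, observed_stat = observed_stat),
            class = "essentiality_scan")
}

#' @export
print.essentiality_scan <- function(x, ...) {
  cat(sprintf("<essentiality_scan> estimated essential-gene fraction: %.3f\n",
              x$estimate))
  cat(sprintf("  observed genes_with_hom: %d; grid points: %d x %d replicates\n",
              x$observed_stat,
              length(unique(x$results$essential_fraction)),
              max(x$results$replicate)))
  invisible(x)
}

#' Pedigree covariate table for the size regression
#'
#' Builds, from the mutation and genotype tables, the one-row-per-pedigree
#' covariate table consumed by [fit_pedigree_size_model()]: the observed
#' weaned G3 count (`n_g3`), the number of litters (`n_litters`) and the
#' number of mutations of each class carried heterozygously by the
#' pedigree's G2 mothers (`n_<class>`). The class-count columns are the
#' mutation covariates to zero for the neutral prediction.
#'
#' @param mutations A `mutation_table`.
#' @param genotypes A `genotype_table`.
#' @return Data frame, one row per pedigree; attribute `mutation_cols`
#'   names the per-class count columns.
#' @export
pedigree_covariates <- function(mutations, genotypes) {
  g <- as.data.frame(genotypes)
  mice <- mice_of(genotypes)
  peds <- sort(unique(mutations$pedigree_id))
  g3 <- mice[mice$generation == "G3", , drop = FALSE]
  n_g3 <- table(factor(g3$pedigree_id, levels = peds))
  n_litters <- tapply(g3$litter_id, factor(g3$pedigree_id, levels = peds),
                      function(x) length(unique(x)))
  n_litters[is.na(n_litters)] <- 0
  dam_het <- g[g$generation == "G2" & g$genotype == "HET", , drop = FALSE]
  cls <- mutations$mutation_class[match(dam_het$mutation_id,
                                        mutations$mutation_id)]
  out <- data.frame(pedigree_id = peds, n_g3 = as.integer(n_g3),
                    n_litters = as.integer(n_litters),
                    stringsAsFactors = FALSE)
  for (cl in mutation_classes()) {
    cnt <- table(factor(dam_het$pedigree_id[!is.na(cls) & cls == cl],
                        levels = peds))
    out[[paste0("n_", cl)]] <- as.integer(cnt)
  }
  attr(out, "mutation_cols") <- paste0("n_", mutation_classes())
  out
}

#' Assemble a scan dataset from mutation and genotype tables
#'
#' Pairs each pedigree's G2 dam genotypes with a neutral pedigree size
#' (typically from [predict_neutral_sizes()]), splitting the size evenly
#' across the pedigree's dams (remainders go to the first dams).
#'
#' @param mutations A `mutation_table`.
#' @param genotypes A `genotype_table` containing the G2 dam calls.
#' @param neutral_sizes Named integer vector of virtual G3 counts per
#'   pedigree (names are pedigree ids).
#' @return A [sim_dataset()].
#' @export
sim_dataset_from_tables <- function(mutations, genotypes, neutral_sizes) {
  g <- as.data.frame(genotypes)
  dams <- g[g$generation == "G2", c("mouse_id", "pedigree_id", "mutation_id",
                                    "genotype")]
  names(dams)[1] <- "dam_id"
  ped_dams <- unique(dams[c("dam_id", "pedigree_id")])
  missing <- setdiff(names(neutral_sizes), ped_dams$pedigree_id)
  if (length(missing) > 0)
    stop_fmt("no G2 dams for pedigree(s): %s", paste(missing, collapse = ", "))
  sizes <- do.call(rbind, lapply(names(neutral_sizes), function(ped) {
    ids <- ped_dams$dam_id[ped_dams$pedigree_id == ped]
    tot <- as.integer(neutral_sizes[[ped]])
    base <- tot %/% length(ids)
    extra <- tot %% length(ids)
    data.frame(dam_id = ids,
               n_pups = base + as.integer(seq_along(ids) <= extra),
               stringsAsFactors = FALSE)
  }))
  sim_dataset(mutations, dams, sizes)
}

#' Observed homozygous-damage gene count
#'
#' The number of genes carrying any mutation for which at least one G3
#' mouse in the genotype table is HOM — the statistic matched by the
#' essentiality scan.
#'
#' @param mutations A `mutation_table`.
#' @param genotypes A `genotype_table` of surviving (weaned) mice.
#' @return Integer count.
#' @export
observed_genes_with_hom <- function(mutations, genotypes) {
  g <- as.data.frame(genotypes)
  hom <- g[g$generation == "G3" & g$genotype == "HOM", "mutation_id"]
  length(unique(mutations$gene_id[mutations$mutation_id %in% unique(hom)]))
}
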