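# Fixture builders and independent oracles used across the suite.
options(enudamage.quiet = TRUE)

# quick mutation table; scores auto-filled for missense classes
make_mutations <- function(ids, pedigree = "P1", gene = NULL, chrom = "chr1",
                           pos = NULL, class = "probably_benign",
                           score = NULL) {
  n <- length(ids)
  class <- rep_len(class, n)
  default_score <- c(probably_benign = 0.1, possibly_damaging = 0.6,
                     probably_damaging = 0.97)[class]
  validate_mutations(data.frame(
    mutation_id = ids,
    pedigree_id = rep_len(pedigree, n),
    gene_id = gene %||% paste0("g_", ids),
    chromosome = rep_len(chrom, n),
    position = pos %||% (1e6 + (seq_len(n) - 1) %% 9 * 1.5e8 +
                           (seq_len(n) - 1) %/% 9),
    mutation_class = class,
    score = score %||% unname(default_score),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long genotype table from a compact spec: list of mice, each
# list(id, gen, dam, litter, geno = named genotype vector)
make_genotypes <- function(mice, pedigree = "P1") {
  rows <- lapply(mice, function(m) {
    data.frame(mouse_id = m$id, pedigree_id = pedigree,
               generation = m$gen,
               dam_id = m$dam %||% NA_character_,
               litter_id = m$litter %||% NA_character_,
               mutation_id = names(m$geno), genotype = unname(m$geno),
               stringsAsFactors = FALSE)
  })
  validate_genotypes(do.call(rbind, rows))
}

# a HET-dam x HET-sire pedigree with explicit G3 genotypes at one locus
het_pedigree <- function(g3_genos, mut = "m1", pedigree = "P1",
                         dam_geno = "HET") {
  mice <- c(
    list(list(id = paste0(pedigree, "_G1"), gen = "G1",
              geno = stats::setNames("HET", mut)),
         list(id = paste0(pedigree, "_D1"), gen = "G2",
              geno = stats::setNames(dam_geno, mut))),
    lapply(seq_along(g3_genos), function(i)
      list(id = sprintf("%s_K%02d", pedigree, i), gen = "G3",
           dam = paste0(pedigree, "_D1"), litter = "L1",
           geno = stats::setNames(g3_genos[i], mut))))
  make_genotypes(mice, pedigree = pedigree)
}

# Independent brute-force oracle for the gene damage probability: loops
# over all damaging-status assignments via expand.grid and counts mice by
# explicit iteration (no linear algebra shared with the implementation).
oracle_damage_prob <- function(m, probs, n) {
  J <- nrow(m); K <- ncol(m)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), J))
  total <- 0
  for (row in seq_len(nrow(grid))) {
    damaging <- unlist(grid[row, ])
    w <- 1
    for (j in seq_len(J)) w <- w * if (damaging[j]) probs[j] else 1 - probs[j]
    c_mice <- 0
    for (k in seq_len(K)) {
      hit <- FALSE
      for (j in seq_len(J)) if (damaging[j] && m[j, k] == 1) hit <- TRUE
      if (hit) c_mice <- c_mice + 1
    }
    if (c_mice >= n) total <- total + w
  }
  total
}

# Clopper-Pearson interval via beta quantiles (independent of binom.test)
oracle_clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

# random small homozygosity matrix fixture
random_hom_matrix <- function(max_j = 6, max_k = 8) {
  J <- sample(1:max_j, 1)
  K <- sample(1:max_k, 1)
  m <- matrix(stats::rbinom(J * K, 1, 0.4), J, K)
  gene <- sprintf("g%04d", sample.int(9999, 1))
  rownames(m) <- sprintf("%s_m%d", gene, seq_len(J))
  hom_matrix(gene, m, stats::runif(J))
}
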