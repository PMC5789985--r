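# Gene damage probability (exact and Monte Carlo) and saturation curves.

test_that("superpedigrees pool mutations and mice across pedigrees", {
  m <- validate_mutations(data.frame(
    mutation_id = c("m1", "m2", "m3"),
    pedigree_id = c("P1", "P2", "P2"),
    gene_id = c("gA", "gA", "gB"),
    chromosome = "chr1", position = c(1e6, 2e6, 150e6),
    mutation_class = c("probably_damaging", "null_class_I", "probably_benign"),
    score = c(0.97, NA, 0.1)))
  g <- make_genotypes(list(
    list(id = "k1", gen = "G3", dam = "d1", litter = "L1",
         geno = c(m1 = "HOM")),
    list(id = "k2", gen = "G3", dam = "d1", litter = "L1",
         geno = c(m1 = "HOM", m3 = "HET")),
    list(id = "k3", gen = "G3", dam = "d2", litter = "L2",
         geno = c(m2 = "HOM", m3 = "HOM"))))
  sp <- build_superpedigrees(m, g)
  expect_setequal(names(sp), c("gA", "gB"))
  # gA spans both pedigrees: mutations m1 (2 HOM mice) and m2 (1 HOM mouse)
  expect_equal(dim(sp$gA$m), c(2L, 3L))
  expect_equal(sum(sp$gA$m), 3)
  expect_equal(sort(sp$gA$probs),
               sort(unname(default_damage_map()[c("probably_damaging",
                                                  "null_class_I")])))
  # a damage map that does not cover the class set errors
  expect_error(build_superpedigrees(m, g, damage_map = c(probably_benign = 0.1)),
               "missing class")
})

test_that("a mouse homozygous for two mutations of one gene fills one column twice", {
  m <- make_mutations(c("m1", "m2"), gene = c("gA", "gA"),
                      class = "probably_damaging")
  g <- make_genotypes(list(
    list(id = "k1", gen = "G3", dam = "d1", litter = "L1",
         geno = c(m1 = "HOM", m2 = "HOM"))))
  sp <- build_superpedigrees(m, g)
  expect_equal(colSums(sp$gA$m), c(k1 = 2))
})

test_that("exact damage probability matches hand-checkable cases", {
  # J = 1, probability 0: impossible damage
  hm0 <- hom_matrix("g", matrix(1, 1, 1), 0)
  expect_equal(damage_prob_exact(hm0, 1), 0)
  # J = 1, p = 0.594, HOM in 3 of 5 mice
  hm1 <- hom_matrix("g", matrix(c(1, 1, 1, 0, 0), 1, 5), 0.594)
  expect_equal(damage_prob_exact(hm1, 3), 0.594)
  expect_equal(damage_prob_exact(hm1, 4), 0)
  # J = 2, distinct mice
  hm2 <- hom_matrix("g", rbind(c(1, 0), c(0, 1)), c(0.167, 0.045))
  expect_equal(damage_prob_exact(hm2, 1), 1 - 0.833 * 0.955, tolerance = 1e-12)
  expect_equal(damage_prob_exact(hm2, 1), 0.204485, tolerance = 1e-9)
  expect_equal(damage_prob_exact(hm2, 2), 0.167 * 0.045, tolerance = 1e-12)
  # n = 0 is certain; J above the limit redirects to Monte Carlo
  expect_equal(damage_prob_exact(hm2, 0), 1)
  big <- hom_matrix("g", matrix(1, 12, 2), rep(0.5, 12))
  expect_error(damage_prob_exact(big, 1), "damage_prob_mc")
})

test_that("exact enumeration equals the independent brute-force oracle", {
  set.seed(42)
  for (i in 1:25) {
    hm <- random_hom_matrix(max_j = 5, max_k = 6)
    for (n in 1:3)
      expect_equal(damage_prob_exact(hm, n),
                   oracle_damage_prob(hm$m, hm$probs, n), tolerance = 1e-12)
  }
})

test_that("Monte Carlo path is degenerate at probability 0 and 1 and agrees with exact", {
  hm <- hom_matrix("g", rbind(c(1, 1, 0), c(0, 1, 1)), c(1, 1))
  expect_equal(damage_prob_mc(hm, 3, sims = 50, seed = 1), 1)
  expect_equal(damage_prob_mc(hm, 4, sims = 50, seed = 1), 0)
  hm0 <- hom_matrix("g", matrix(1, 2, 2), c(0, 0))
  expect_equal(damage_prob_mc(hm0, 1, sims = 50, seed = 1), 0)

  hm2 <- hom_matrix("g", rbind(c(1, 0), c(0, 1)), c(0.167, 0.045))
  exact <- damage_prob_exact(hm2, 1)
  mc <- damage_prob_mc(hm2, 1, sims = 1e5, seed = 7)
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(mc - exact), 3 * se)
})

test_that("P_g(n) is nonincreasing in n and bounded by the union probability", {
  set.seed(9)
  for (i in 1:10) {
    hm <- random_hom_matrix(max_j = 5, max_k = 6)
    rep <- gene_damage_report(hm, max_n = ncol(hm$m) + 1)
    expect_true(all(diff(rep$p_damage) <= 1e-12))
    union_bound <- 1 - prod(1 - hm$probs)
    expect_lte(rep$p_damage[1], union_bound + 1e-12)
    if (all(rowSums(hm$m) >= 1))
      expect_equal(rep$p_damage[1], union_bound, tolerance = 1e-12)
  }
})

test_that("gene report follows the single-mutation closed form", {
  hm <- hom_matrix("g", matrix(c(1, 1, 1, 0), 1, 4), 0.7)
  rep <- gene_damage_report(hm, max_n = 4)
  expect_equal(rep$p_damage, c(0.7, 0.7, 0.7, 0))
  # no HOM mice anywhere: all zero
  hm_none <- hom_matrix("g", matrix(0, 2, 3), c(0.5, 0.5))
  expect_equal(gene_damage_report(hm_none, 3)$p_damage, rep(0, 3))
})

test_that("saturation adds per-gene probabilities and accumulates along the chronology", {
  m <- validate_mutations(data.frame(
    mutation_id = c("m1", "m2"), pedigree_id = c("P1", "P2"),
    gene_id = c("gA", "gB"), chromosome = "chr1", position = c(1e6, 2e6),
    mutation_class = "probably_damaging", score = 0.99))
  m$damage_prob <- c(0.2, 0.5)
  g <- make_genotypes(list(
    list(id = "k1", gen = "G3", dam = "d1", litter = "L1", geno = c(m1 = "HOM")),
    list(id = "k2", gen = "G3", dam = "d2", litter = "L2", geno = c(m2 = "HOM"))))
  sp <- build_superpedigrees(m, g)
  curve <- genome_saturation(sp, n = 1, order = c("m1", "m2"),
                             genome_size = 10)
  expect_equal(curve$s_expected_genes, c(0.2, 0.7))
  expect_equal(curve$saturation_pct, c(2, 7))
})

test_that("saturation curves are nondecreasing in prefix length and in decreasing n", {
  set.seed(15)
  n_genes <- 30
  df <- data.frame(
    mutation_id = sprintf("m%03d", 1:n_genes),
    pedigree_id = sprintf("P%02d", rep(1:5, 6)),
    gene_id = sprintf("g%03d", 1:n_genes),
    chromosome = "chr1", position = seq(1e6, by = 1e6, length.out = n_genes),
    mutation_class = sample(mutation_classes(), n_genes, TRUE),
    score = NA_real_, stringsAsFactors = FALSE)
  df$score[df$mutation_class %in% missense_classes()] <- 0.5
  m <- validate_mutations(df)
  g <- make_genotypes(lapply(1:60, function(i) {
    list(id = sprintf("k%03d", i), gen = "G3", dam = "d1", litter = "L1",
         geno = stats::setNames(sample(c("HOM", "HET", "REF"), 1),
                                sprintf("m%03d", sample.int(n_genes, 1))))
  }))
  sp <- build_superpedigrees(m, g)
  n_present <- sum(m$mutation_id %in%
                     unlist(lapply(sp, `[[`, "mutation_ids")))
  at <- unique(round(seq(2, n_present, length.out = 4)))
  c1 <- genome_saturation(sp, n = 1, order = m$mutation_id, at = at)
  c2 <- genome_saturation(sp, n = 2, order = m$mutation_id, at = at)
  expect_true(all(diff(c1$s_expected_genes) >= -1e-12))
  expect_true(all(diff(c2$s_expected_genes) >= -1e-12))
  expect_true(all(c2$s_expected_genes <= c1$s_expected_genes + 1e-12))
})

test_that("saturation is additive over gene partitions", {
  set.seed(21)
  mats <- replicate(6, random_hom_matrix(max_j = 4, max_k = 5),
                    simplify = FALSE)
  names(mats) <- sprintf("g%d", 1:6)
  full <- genome_saturation(mats, n = 1)
  parts <- sum(vapply(mats, function(h) damage_prob_exact(h, 1), numeric(1)))
  expect_equal(full$s_expected_genes[nrow(full)], parts, tolerance = 1e-12)
})
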