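# Filtering cascade and homozygote-proportion computation.

test_that("isolation filter applies the strict <100 Mb rule within pedigree and chromosome", {
  two <- function(pos, ped = c("P1", "P1"), chrom = c("chr1", "chr1"))
    validate_mutations(data.frame(
      mutation_id = c("a", "b"), pedigree_id = ped, gene_id = c("g1", "g2"),
      chromosome = chrom, position = pos,
      mutation_class = "probably_benign", score = 0.1))
  # 110 Mb apart: both kept
  expect_equal(nrow(filter_isolated(two(c(10e6, 120e6)))), 2)
  # 40 Mb apart: both removed
  expect_equal(nrow(filter_isolated(two(c(10e6, 50e6)))), 0)
  # exactly 100 Mb apart: retained (strict inequality)
  expect_equal(nrow(filter_isolated(two(c(10e6, 110e6)))), 2)
  # same positions, different pedigrees or chromosomes: never exclude
  expect_equal(nrow(filter_isolated(two(c(10e6, 50e6), ped = c("P1", "P2")))), 2)
  expect_equal(nrow(filter_isolated(two(c(10e6, 50e6),
                                        chrom = c("chr1", "chr2")))), 2)
  # empty input passes through
  expect_equal(nrow(filter_isolated(two(c(1e6, 2e6))[0, ])), 0)
})

test_that("isolation threshold 0 retains everything; a crowded middle removes its flanks", {
  m <- make_mutations(c("a", "b", "c"), pos = c(1e6, 60e6, 130e6))
  expect_equal(nrow(filter_isolated(m, threshold_bp = 0)), 3)
  # b is <100 Mb from both a and c; a and c are 129 Mb apart but each
  # within 100 Mb of b, so all three fall
  expect_equal(nrow(filter_isolated(m)), 0)
})

test_that("minimum-G3 filter is inclusive at the boundary", {
  g2 <- het_pedigree(c("REF", "HET"), pedigree = "P1")        # 2 G3 mice
  g3 <- het_pedigree(c("REF", "HET", "HOM"), pedigree = "P2") # 3 G3 mice
  m <- rbind(make_mutations("m1", pedigree = "P1"),
             make_mutations("m1", pedigree = "P2"))
  m$mutation_id <- c("m1", "m1b")  # keep ids unique across pedigrees
  geno <- validate_genotypes(rbind(as.data.frame(g2), as.data.frame(g3)))
  kept <- filter_min_g3(m, geno, min_g3 = 3)
  expect_equal(kept$pedigree_id, "P2")
  expect_error(filter_min_g3(make_mutations("x", pedigree = "P9"), geno),
               "P9")
})

test_that("essential filter keeps annotated-essential genes and drops the rest", {
  m <- make_mutations(c("m1", "m2", "m3"), gene = c("gA", "gB", "gC"))
  ann <- data.frame(gene_id = c("gA", "gB"), essential = c(TRUE, FALSE),
                    lethality_mode = c("totally", "unknown"))
  kept <- filter_essential(m, ann)
  expect_equal(kept$gene_id, "gA")  # gB non-essential, gC unannotated
})

test_that("p_hom counts HOM G3 offspring of HET dams against a hand enumeration", {
  # 8 pups of a HET dam, 2 HOM
  g <- het_pedigree(c("HOM", "HOM", "HET", "HET", "REF", "REF", "HET", "REF"))
  m <- make_mutations("m1")
  fm <- compute_p_hom(m, g)
  expect_equal(fm$n_g3, 8L)
  expect_equal(fm$n_hom, 2L)
  expect_equal(fm$p_hom, 0.25)
  expect_true(fm$informative)

  # zero HOM pups
  fm0 <- compute_p_hom(m, het_pedigree(rep("HET", 8)))
  expect_equal(fm0$p_hom, 0)

  # all pups from a REF dam: denominator empty, flagged uninformative
  fm_ref <- compute_p_hom(m, het_pedigree(c("HET", "REF"), dam_geno = "REF"))
  expect_false(fm_ref$informative)
  expect_true(is.na(fm_ref$p_hom))
})

test_that("p_hom pools litters of several HET dams but ignores REF-dam litters", {
  mk <- function(id, dam, geno) list(id = id, gen = "G3", dam = dam,
                                     litter = paste0(dam, "_L1"),
                                     geno = c(m1 = geno))
  g <- make_genotypes(c(
    list(list(id = "sire", gen = "G1", geno = c(m1 = "HET")),
         list(id = "damA", gen = "G2", geno = c(m1 = "HET")),
         list(id = "damB", gen = "G2", geno = c(m1 = "REF"))),
    list(mk("k1", "damA", "HOM"), mk("k2", "damA", "REF"),
         mk("k3", "damB", "HET"), mk("k4", "damB", "REF"))))
  fm <- compute_p_hom(make_mutations("m1"), g)
  # only damA's two pups count; one is HOM
  expect_equal(fm$n_g3, 2L)
  expect_equal(fm$p_hom, 0.5)
})

test_that("filters commute and the cascade equals the intersection", {
  set.seed(11)
  n <- 40
  m <- validate_mutations(data.frame(
    mutation_id = sprintf("m%02d", 1:n),
    pedigree_id = sample(c("P1", "P2", "P3"), n, TRUE),
    gene_id = sprintf("g%02d", 1:n),
    chromosome = sample(c("chr1", "chr2"), n, TRUE),
    position = sample.int(2e8, n),
    mutation_class = "probably_benign", score = 0.2))
  ann <- data.frame(gene_id = m$gene_id,
                    essential = rep(c(TRUE, FALSE), length.out = n),
                    lethality_mode = ifelse(rep(c(TRUE, FALSE), length.out = n),
                                            "totally", "unknown"))
  sizes <- c(P1 = 4, P2 = 2, P3 = 5)  # P2 fails the min-G3 filter
  g <- do.call(rbind, lapply(names(sizes), function(p)
    as.data.frame(het_pedigree(rep("HET", sizes[[p]]), mut = paste0("mx_", p),
                               pedigree = p))))
  g <- validate_genotypes(g)
  # row-local filters (pedigree size, essentiality) commute freely;
  # isolation is judged against the full mutation set, so it runs first
  a <- filter_essential(filter_min_g3(filter_isolated(m), g, 3), ann)
  b <- filter_min_g3(filter_essential(filter_isolated(m), ann), g, 3)
  expect_setequal(a$mutation_id, b$mutation_id)
  inter <- Reduce(intersect, list(filter_isolated(m)$mutation_id,
                                  filter_min_g3(m, g, 3)$mutation_id,
                                  filter_essential(m, ann)$mutation_id))
  expect_setequal(a$mutation_id, inter)
})

test_that("phenotype subset enforces >=4 G3 mice and p_hom >= 0.25 inclusively", {
  m4 <- make_mutations("m1")
  g_boundary <- het_pedigree(c("HOM", "HET", "REF", "REF"))  # p_hom 0.25, 4 G3
  fm <- compute_p_hom(m4, g_boundary)
  expect_equal(nrow(filter_for_phenotype(fm, g_boundary)), 1)

  g_low <- het_pedigree(c("HOM", "HET", "REF", "REF", "REF"))  # p_hom 0.20
  fm_low <- compute_p_hom(m4, g_low)
  expect_equal(nrow(filter_for_phenotype(fm_low, g_low)), 0)

  g_small <- het_pedigree(c("HOM", "HET", "REF"))  # only 3 G3 mice
  fm_small <- compute_p_hom(m4, g_small)
  expect_equal(nrow(filter_for_phenotype(fm_small, g_small)), 0)
  expect_error(filter_for_phenotype(m4, g_small), "compute_p_hom")
})
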