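# Pedigree-size regression, virtual breeding, culling and the
# essential-fraction scan.

test_that("intercept-only size model predicts the mean observed size", {
  tab <- data.frame(n_g3 = c(10, 20, 30, 40))
  mdl <- fit_pedigree_size_model(tab)
  expect_equal(predict_neutral_sizes(mdl), rep(25L, 4))
})

test_that("size regression recovers known coefficients and the neutral prediction zeroes mutations", {
  set.seed(8)
  n <- 400
  tab <- data.frame(n_litters = rpois(n, 3),
                    n_damaging = rpois(n, 5))
  tab$n_g3 <- round(10 + 4 * tab$n_litters - 1.5 * tab$n_damaging +
                      rnorm(n, sd = 2))
  mdl <- fit_pedigree_size_model(tab, covariate_cols = "n_litters",
                                 mutation_cols = "n_damaging")
  cf <- coef(mdl$fit)
  expect_equal(unname(cf["n_litters"]), 4, tolerance = 0.1)
  expect_equal(unname(cf["n_damaging"]), -1.5, tolerance = 0.1)
  # zeroing a negative mutation coefficient raises the prediction
  expect_true(all(predict_neutral_sizes(mdl) >=
                    as.integer(round(fitted(mdl$fit))) - 1L))
  # collinear design errors with the offending column named
  tab$dup <- tab$n_litters
  expect_error(fit_pedigree_size_model(tab, covariate_cols = c("n_litters", "dup")),
               "collinear.*dup")
  expect_error(fit_pedigree_size_model(tab, covariate_cols = "absent"),
               "absent")
})

test_that("virtual breeding follows Mendelian transmission", {
  # REF dam x HET sire: variant cannot reach homozygosity
  pups <- breed_virtual_g3(c(m1 = "REF"), n_pups = 500, seed = 2)
  expect_false(any(pups == "HOM"))
  # HOM dam x HET sire: pup is HOM with probability 1/2
  pups2 <- breed_virtual_g3(c(m1 = "HOM"), n_pups = 8000, seed = 3)
  frac <- mean(pups2 == "HOM")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 8000))
  # explicit sire genotypes and unknown values
  pups3 <- breed_virtual_g3(c(m1 = "HET"), c(m1 = "REF"), n_pups = 200, seed = 4)
  expect_false(any(pups3 == "HOM"))
  expect_error(breed_virtual_g3(c(m1 = "het"), n_pups = 10), "REF, HET or HOM")
})

test_that("essentiality assignment hits the requested fractions", {
  genes <- sprintf("g%05d", 1:10000)
  muts <- data.frame(mutation_id = paste0("m", 1:5000),
                     gene_id = sample(genes, 5000),
                     mutation_class = "probably_damaging")
  sc <- sim_scenario(seed = 1)
  lab <- assign_essentiality_and_damage(genes, muts, 0.34, sc, seed = 9)
  n_ess <- sum(lab$genes$essential)
  expect_lt(abs(n_ess - 3400), 3 * sqrt(10000 * 0.34 * 0.66))
  # partial share among essential genes is 39/139
  frac_partial <- mean(lab$genes$lethality_mode[lab$genes$essential] == "partially")
  expect_lt(abs(frac_partial - 0.39 / 1.39), 3 * sqrt(0.28 * 0.72 / n_ess))
  # damaging fraction follows the class probability
  expect_lt(abs(mean(lab$mutations$damaging) - 0.167),
            3 * sqrt(0.167 * 0.833 / 5000))
  # fraction 0: nothing essential
  lab0 <- assign_essentiality_and_damage(genes, muts, 0, sc, seed = 9)
  expect_false(any(lab0$genes$essential))
})

test_that("culling removes homozygotes per the lethality rules", {
  muts <- data.frame(mutation_id = c("mT", "mP", "mN"),
                     gene_id = c("gT", "gP", "gN"),
                     mutation_class = "probably_damaging")
  labels <- list(
    genes = data.frame(gene_id = c("gT", "gP", "gN"),
                       essential = c(TRUE, TRUE, FALSE),
                       lethality_mode = c("totally", "partially", "unknown")),
    mutations = data.frame(mutation_id = c("mT", "mP", "mN"),
                           damaging = c(TRUE, TRUE, TRUE)))
  sc <- sim_scenario(seed = 1)
  geno <- rbind(c("HOM", "REF", "REF"),   # dies: damaging HOM, totally essential
                c("HET", "REF", "HOM"),   # survives: HOM only in non-essential
                c("REF", "REF", "REF"))   # survives
  colnames(geno) <- muts$mutation_id
  alive <- cull(geno, muts, labels, sc, seed = 5)
  expect_identical(alive, c(FALSE, TRUE, TRUE))
  # partial culling at about 50%
  big <- matrix("REF", 10000, 3, dimnames = list(NULL, muts$mutation_id))
  big[, "mP"] <- "HOM"
  alive_big <- cull(big, muts, labels, sc, seed = 6)
  expect_lt(abs(sum(alive_big) - 5000), 3 * sqrt(10000 * 0.25))
  # a pup HOM for both a total and a partial lethal dies deterministically
  both <- matrix(c("HOM", "HOM", "REF"), 1, 3,
                 dimnames = list(NULL, muts$mutation_id))
  expect_false(any(replicate(20, cull(both, muts, labels, sc))))
})

test_that("simulated gene statistic decreases with the essential fraction", {
  ds <- generate_dataset(generator_config(n_pedigrees = 25, seed = 77,
                                          essential_fraction = 0))
  sdat <- sim_dataset_from_tables(
    ds$mutations, ds$genotypes,
    stats::setNames(ds$pedigrees$n_born, ds$pedigrees$pedigree_id))
  sc <- sim_scenario(essential_fraction_grid = seq(0, 0.6, 0.1),
                     replicates = 3, seed = 123)
  res <- simulate_genes_with_hom(sdat, sc)
  fit <- lm(genes_with_hom ~ essential_fraction, data = res)
  expect_lt(coef(fit)["essential_fraction"], 0)
  # with fraction 0 no pup is ever culled
  zero <- res[res$essential_fraction == 0, ]
  expect_true(all(zero$virtual_g3_count == sum(sdat$dam_sizes$n_pups)))
})

test_that("scan inverts the fitted line at the observed statistic", {
  ds <- generate_dataset(generator_config(n_pedigrees = 25, seed = 78))
  obs <- observed_genes_with_hom(ds$mutations, ds$genotypes)
  sdat <- sim_dataset_from_tables(
    ds$mutations, ds$genotypes,
    stats::setNames(ds$pedigrees$n_born, ds$pedigrees$pedigree_id))
  sc <- sim_scenario(essential_fraction_grid = seq(0, 0.6, 0.05),
                     replicates = 3, seed = 11)
  scan <- scan_essential_fraction(sdat, sc, obs)
  expect_gte(scan$estimate, 0)
  expect_lte(scan$estimate, 1)
  # solving the line at the fitted value of the estimate returns obs
  pred <- predict(scan$fit,
                  newdata = data.frame(essential_fraction = scan$estimate))
  expect_equal(unname(pred), obs, tolerance = 1e-6)
  # observing the zero-essential mean recovers a fraction near 0
  mean0 <- mean(scan$results$genes_with_hom[
    scan$results$essential_fraction == 0])
  scan0 <- scan_essential_fraction(sdat, sc, round(mean0))
  expect_lt(scan0$estimate, 0.06)
  # degenerate grid errors
  expect_error(
    scan_essential_fraction(sdat,
                            sim_scenario(essential_fraction_grid = 0.3,
                                         replicates = 2, seed = 1), obs),
    "at least 2")
})

test_that("seeded scans reproduce exactly", {
  ds <- generate_dataset(generator_config(n_pedigrees = 10, seed = 5))
  sdat <- sim_dataset_from_tables(
    ds$mutations, ds$genotypes,
    stats::setNames(ds$pedigrees$n_born, ds$pedigrees$pedigree_id))
  sc <- sim_scenario(essential_fraction_grid = c(0, 0.3, 0.6),
                     replicates = 2, seed = 99)
  r1 <- simulate_genes_with_hom(sdat, sc)
  r2 <- simulate_genes_with_hom(sdat, sc)
  expect_identical(r1, r2)
})
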