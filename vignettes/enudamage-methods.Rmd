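---
title: "Methods: damage probability, saturation and essentiality inference for ENU pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: damage probability, saturation and essentiality inference for ENU pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enudamage)
options(enudamage.quiet = TRUE)
```

# The experimental design being modelled

A germline mutagenesis program treats G0 males with ENU, sequences the
exomes of their G1 sons, and backcrosses G2 daughters to the G1 sire so
that each induced mutation can reach homozygosity in the G3 generation.
Every G1 is heterozygous for each of his pedigree's mutations; each G2
dam is HET or REF per locus with probability 1/2; a G3 pup of a HET dam
is HOM with Mendelian probability 1/4. Prediction tools such as
PolyPhen-2 score missense mutations, and non-missense coding/splice
mutations ("putative null": class I for nonsense/makesense/start-loss,
class II for indels and splice defects) are treated as likely knockouts —
but scores are ordinal severity, not a probability of functional damage.
This package infers that probability from segregation data, and
propagates it into genome-saturation and essential-gene-fraction
estimates.

# Filtering

Analysis starts from a mutation table and a per-mouse genotype table
(REF/HET/HOM). Three filters precede estimation:

* **Isolation** (`filter_isolated()`): a mutation is kept only if every
  other mutation of the same pedigree on the same chromosome is at least
  100 Mb away (strictly closer excludes; exactly 100 Mb is retained, and
  1 Mb is exactly 1e6 bp). This makes phenotypes attributable to single
  loci. Isolation is judged against the *full* mutation set supplied:
  neighbours excluded by other filters still count as neighbours, so this
  filter runs first in the cascade. The later filters are row-local
  predicates and commute freely.
* **Pedigree size** (`filter_min_g3()`): pedigrees need at least 3
  genotyped G3 mice of any genotype (boundary inclusive).
* **Essentiality** (`filter_essential()`): the mixture estimator is
  identified only within genes known to be essential (homozygous
  disruption is pre-weaning lethal), so estimation is restricted to
  annotated-essential genes. Genes missing from the annotation are
  treated as non-essential and logged, since annotation coverage is
  partial.

`compute_p_hom()` then computes, per mutation, the homozygote proportion
`p_hom`: HOM G3 mice over all genotyped G3 offspring of HET dams. The
denominator is restricted to HET-dam litters because the G1 sire is HET
by construction and a REF-dam litter cannot produce HOM pups — including
such litters would dilute `p_hom` below its Mendelian null of 0.25.
Mutations with no informative offspring are flagged and excluded
downstream. Only successfully genotyped mice count.

# The three-subgroup mixture estimator

Within essential genes, a mutation class is modelled as a mixture of
three kinds of mutations, distinguished by the homozygote proportion
they produce among weaned G3 mice:

1. damaging mutations in **totally** essential genes: no homozygote
   survives, `p = 0`;
2. damaging mutations in **partially** essential genes: `p` scattered
   around a center `theta` with `0 < theta < 0.25`;
3. non-damaging mutations: `p` scattered around the Mendelian 0.25.

Writing `q` for the weight of subgroup 1, subgroup 2 has weight `r * q`
where `r` is the ratio of partially to totally essential genes, and the
quantity of interest is the total truly-damaging fraction
`rho = (1 + r) q`. Equating the first moment of `p` with the sample mean
gives the closed-form estimator implemented in `mm_estimate()`:

```
rho = (1 + r) * (1/4 - mean(p)) / (1/4 * (1 + r) - theta * r)
```

At the defaults `r = 0.39` and `theta = 0.125` the numerator factor is
1.39 and the denominator 0.29875. The estimator is affine and strictly
decreasing in `mean(p)`, exactly 0 at the Mendelian mean, and unbiased
for `rho` under the mixture weights `(rho/(1+r), r*rho/(1+r), 1-rho)`.

Parameter choices and their provenance:

* `partial_ratio = 0.39` comes from knockout-viability annotation: among
  885 essential genes with a lethality mode, 250 are partially and 635
  totally lethal (shipped in `essential_lethality_counts()`;
  250/635 = 39%).
* `theta = 0.125` is the midpoint of (0, 0.25). The first moment alone
  cannot identify `theta`, so it is a fixed modelling choice, exposed as
  a parameter of `mm_params()`.
* `mendelian_rate = 0.25` is the intercross expectation and is only a
  parameter so that the algebra is visible; there is no scientific
  reason to change it.

Because it is a moment estimator applied to noisy finite samples, the
raw estimate can leave [0, 1] (an all-lethal sample gives about 1.163 at
the defaults). Both the raw and the clamped value are reported; clamped
values feed all downstream calculations.

**Uncertainty** is by percentile bootstrap (`bootstrap_ci()`, default
5,000 replicates): the mutation, with its `p_i`, is the resampling unit,
since the estimator is a functional of the `p_i` sample, and each
replicate is clamped exactly like the point estimate. The interval
therefore brackets the clamped estimate up to resampling granularity.
The percentile method was chosen as the least-assumption default for a
bounded, possibly boundary-clamped statistic.

`estimate_by_score_window()` re-estimates within user-supplied score
windows instead of the three coarse missense bands. Windows are
half-open `(low, high]`; a score on a shared boundary belongs to the
window it closes. Window lists are user input — no canonical boundaries
are hard-coded.

`weighted_average_damage()` combines per-class probabilities with class
abundances; with the shipped defaults and the full-cohort class counts
(`published_class_counts()`) it gives 0.158, i.e. a random
coding/splicing ENU mutation carries a 16% probability of
phenotypically detectable damage.

# Gene damage probability and genome saturation

For one gene, all its mutations across all pedigrees are pooled into a
"superpedigree": a binary matrix `M` (J mutations x K G3 mice,
`M[j,k] = 1` iff mouse `k` is HOM for mutation `j`) plus per-mutation
damage probabilities `P(m_j)`, by default the class-level estimates in
`default_damage_map()` and overridable per mutation. The same mouse may
be HOM for several mutations of the gene.

`P_g(n)` is the probability that at least `n` mice carry at least one
truly damaging homozygous mutation of gene `g`, marginalised over the
`2^J` damaging-status assignments with independent `P(m_j)`:

* `damage_prob_exact()` enumerates all assignments when `J <= 10`
  (configurable `enum_limit`);
* `damage_prob_mc()` samples assignments (default 1,000 simulations,
  raised freely by callers needing tighter error).

Both use the inclusive threshold `c >= n`. (The Monte Carlo estimator
could equally be written with a strict inequality; the exact-enumeration
definition is taken as authoritative and the MC path matches it, so the
two paths estimate the same quantity.) `P_g(0)` is defined as 1.
Exactness is verified in the test suite against an independent
brute-force enumeration, and the MC path against the exact one at
200,000 simulations.

Genome saturation is the expected number of genes damaged homozygously
in at least `n` mice, `S = sum_g P_g(n)`, accumulated along a mutation
chronology (`genome_saturation()`). The chronology is an explicit input
(database accrual order in the motivating use; record order as
fallback), and the gene count `G` used to express `S` as a percentage is
a required user input — no genome-wide gene count is hard-coded.

# The essentiality simulation

The fraction of essential genes is estimated by matching a simulated to
an observed statistic: the number of genes carrying any mutation for
which at least one homozygous G3 mouse survived to weaning
(`observed_genes_with_hom()`). The simulation:

1. predicts each pedigree's **neutral size** — the G3 cohort expected if
   every mutation were neutral — by ordinary least squares of observed
   pedigree sizes on covariates, zeroing the per-class mutation-count
   covariates for prediction (`fit_pedigree_size_model()`,
   `predict_neutral_sizes()`; predictions are rounded to nonnegative
   integers);
2. breeds virtual G3 pups by Mendelian transmission from the real G2 dam
   and G1 sire genotypes (`breed_virtual_g3()`); loci are transmitted
   independently, with no recombination model, because analysed
   mutations are pre-filtered to be at least 100 Mb apart;
3. assigns an essential label to a uniformly random fraction `f` of
   genes, splits essential genes partially:totally at 39:100, and marks
   each mutation truly damaging with its class probability
   (`assign_essentiality_and_damage()`);
4. culls pups homozygous for a damaging mutation in a totally essential
   gene deterministically, and in a partially essential gene with
   probability 0.5; a pup qualifying under both rules dies
   (`cull()`). Culling happens at "birth": culled pups never enter the
   weaned statistics, and they are not replaced;
5. repeats (3)-(4) five times per grid value of `f` over a fixed grid
   (default 0 to 0.6 in steps of 0.02), regresses the simulated counts
   on `f` over **all replicate points jointly** (one straight line, not
   per-point means), and solves the fitted line at the observed
   statistic (`scan_essential_fraction()`). The virtual cohort is bred
   once per scan, under the all-neutral assumption, and only the labels
   and culling are resampled per replicate, mirroring step order in the
   motivating design. A nonnegative fitted slope is an error: the
   statistic must decrease with essentiality.

Seeding: the scenario carries one master seed; breeding and every
(grid point, replicate) stream derive deterministic child seeds from it,
so scans reproduce exactly and replicates are mutually independent.

Two modelling notes that matter in practice:

* The survival of a pedigree is *multiplicative* in its lethal loci,
  while the size regression is linear; extrapolating to zero mutation
  counts therefore carries a small downward bias in the neutral sizes
  that grows with the essential fraction. In validation at 100
  pedigrees this leaves the recovered fraction a few percentage points
  low at `f = 0.34` while staying within the +-0.05 band over 20
  generated datasets.
* A covariate is only usable if it is exogenous to lethality. In the
  synthetic cohort below, litter count is derived from the weaned pup
  count, so including it would absorb the culling signal and corrupt
  the neutral prediction; the validation scans use intercept +
  mutation counts only. With real breeding records, litters produced is
  an independently recorded fact and belongs in the model.

# Phenotype-linkage enrichment

`significant_fraction()` computes the proportion of screen/mutation
combinations with Bonferroni-adjusted linkage P strictly below 1e-5
(strict, matching the inequality as printed in the motivating analysis),
with an exact Clopper-Pearson interval — the natural reading of a CI
"calculated from binomial distribution" when no method is named; users
can compare alternatives since the counts are returned. Records of the
same (mutation, screen) pair under recessive/additive/dominant models
are collapsed to one combination by minimum P by default
(`collapse_models = "min"`); whether the motivating denominator counted
model variants separately is not recoverable, so `"none"` is available
and the choice is explicit in every call. `compare_gene_sets()` splits
combinations by gene essentiality and additionally reports each set's
class composition (fractions probably-damaging and putative-null) — the
enrichment comparison is only meaningful if both sets carry similar
mutation spectra.

# The synthetic cohort generator

`generate_dataset()` emulates the statistical structure of a large
mutagenesis cohort with full ground truth, so that every stage of the
stack can be validated against known latent labels. Defaults, and what
they emulate:

* about 30 weaned G3 mice per pedigree (Poisson, truncated at 1), the
  cohort-wide average of the motivating program; 2 G2 dams per pedigree
  with litter ids assigned in chunks of ~7 pups;
* Poisson mutations per pedigree with mean 55, which makes each G3 mouse
  carry about 34 coding/splicing mutations (a pup carries a locus with
  probability 3/4 under a HET dam, 1/2 under a REF dam, and dams are HET
  at half the loci);
* class proportions matching the full-cohort spectrum (32% benign, 18%
  possibly, 40% probably damaging, 6.4% null I, 3.2% null II);
* per-class true-damage fractions defaulting to `default_damage_map()`;
* 34% of genes essential, split partially:totally at 39:100;
* uniform positions on chromosomes with approximate mouse autosome
  lengths, so the 100-Mb isolation filter has realistic bite;
* one gene per mutation by default; `gene_collision_rate` creates
  multi-allele genes to exercise superpedigrees.

Lethality at "weaning": a pup HOM for a damaging mutation in a totally
essential gene dies; in a partially essential gene it dies with
probability `1 - theta/0.25` (0.5 at the default), chosen so that the
*expected number* of surviving homozygotes corresponds to a rate of
`theta`. Note the induced homozygote *share among weaned pups* centers
slightly higher, at `theta / (0.75 + theta)` (1/7 at the default),
because deaths also shrink the denominator; the estimator tests account
for this. Truth tables record every latent label (class, damaging,
essential, lethality mode, born and weaned counts), and the same seed
reproduces a dataset byte-identically.

What the generator does **not** emulate: within-chromosome linkage and
recombination, genotype failure/missingness, sequencing error, X-linked
loci, litter-level environmental effects, and the empirical joint
distribution of pedigree size and mutation count (only its scale).
Passing validation on synthetic data therefore demonstrates correctness
of the inference machinery under the stated model, not robustness to
those real-data complications.

`generate_screen_table()` adds a screen-linkage table (default 296
screens) with set-specific significance rates for enrichment round
trips.

# Numerical and degenerate-input choices

* Distances: strict `< threshold` excludes; like-named chromosomes only.
* Score windows: half-open `(low, high]`; overlapping windows error.
* `p_hom` with an empty denominator is NA + flagged, never 0.
* Bootstrap of a constant or singleton sample returns a width-0
  interval rather than erroring.
* Enumeration limit `J <= 10` and 1,000 MC simulations are defaults,
  both configurable; tests raise the simulation count instead of
  loosening tolerances.
* All randomised operations take explicit integer seeds; derived child
  seeds stay below 2^31.
* Conflicting essentiality annotations (a gene both essential and not)
  are discarded with a logged count; consistent duplicates collapse.

# Validation scale

The shipped validation uses problem sizes chosen to exercise the
asymptotics that matter while staying desk-runnable: estimator recovery
at the real filtered-cohort class sizes (477/281/690/78/60) over 20
seeds with 5,000-replicate bootstraps; saturation oracle equivalence on
200 random matrices with 200,000-simulation MC checks; essentiality-scan
recovery on 100-pedigree cohorts (about 5,400 mutations, 3,000 G3 mice)
at generating fractions 0.2, 0.34 and 0.5 over 20 seeds each. The
published headline estimates that depend on the full proprietary cohort
(the per-class damage probabilities themselves, the 34% essential
fraction on real breeding records, genome-wide saturation percentages,
and the enrichment rates) are treated as *inputs* (`default_damage_map()`,
shipped summary tables) or as recovery targets for the synthetic
validation, not as quantities this package can recompute from raw data.

# Known limitations

* `theta` is unidentified from first moments; estimates shift if the
  true partial-lethality center differs from 0.125 (the package exposes
  it, so sensitivity analyses are one argument away).
* The estimator ignores per-mutation denominators (it is a plain moment
  estimator over `p_i`), so finite-litter noise propagates into the
  bootstrap rather than being modelled.
* The essentiality scan inherits the linear-extrapolation bias of the
  neutral-size regression discussed above.
* Culling removes whole pups, so a heavily mutated virtual pup can die
  of one gene and silence another gene's homozygosity — an interaction
  the gene-level statistic inherits by design.
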