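# Gene-level damage probability and genome saturation.
#
# For one gene, pool all its mutations (rows) and all G3 mice genotyped
# for them (columns) across pedigrees into a binary homozygosity matrix M
# (M[j,k] = 1 iff mouse k is HOM for mutation j), with a per-mutation
# probability P(m_j) of being truly damaging. P_g(n) is the probability
# that at least n mice carry a truly damaging homozygous mutation of the
# gene, marginalised over the 2^J damaging-status assignments (exact for
# small J, Monte Carlo otherwise).

#' Construct a homozygosity matrix
#'
#' @param gene_id Gene identifier.
#' @param m Binary matrix, mutations x mice; dimnames give mutation and
#'   mouse ids (generated if absent).
#' @param probs Numeric vector, length `nrow(m)`, per-mutation damage
#'   probability in \[0, 1\].
#' @return Object of class `hom_matrix`.
#' @export
hom_matrix <- function(gene_id, m, probs) {
  m <- as.matrix(m)
  if (nrow(m) < 1 || ncol(m) < 1) stop_fmt("hom matrix needs >= 1 mutation and >= 1 mouse")
  if (!all(m %in% c(0, 1))) stop_fmt("hom matrix entries must be 0/1")
  if (length(probs) != nrow(m)) stop_fmt("probs must have one entry per mutation")
  if (any(!is.finite(probs) | probs < 0 | probs > 1))
    stop_fmt("probs must lie in [0, 1]")
  if (is.null(rownames(m))) rownames(m) <- paste0("mut", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("mouse", seq_len(ncol(m)))
  structure(list(gene_id = as.character(gene_id), m = m,
                 mutation_ids = rownames(m), mouse_ids = colnames(m),
                 probs = as.numeric(probs)),
            class = "hom_matrix")
}

#' @export
print.hom_matrix <- function(x, ...) {
  cat(sprintf("<hom_matrix> gene %s: %d mutation(s) x %d mouse/mice, %d HOM call(s)\n",
              x$gene_id, nrow(x$m), ncol(x$m), sum(x$m)))
  invisible(x)
}

#' Build per-gene superpedigree homozygosity matrices
#'
#' For each gene, pools all of its mutations across all pedigrees and all
#' G3 mice genotyped for any of them (a "superpedigree"). The same mouse
#' can be HOM for several mutations of the gene; the same gene can be
#' mutated in several pedigrees.
#'
#' @param mutations A `mutation_table`.
#' @param genotypes A `genotype_table` with G3 calls for those mutations.
#' @param damage_map Named per-class damage probabilities (default
#'   [default_damage_map()]); may be overridden per mutation via a
#'   `damage_prob` column on `mutations`.
#' @return Named list of `hom_matrix`, one per gene with at least one
#'   genotyped G3 mouse.
#' @export
build_superpedigrees <- function(mutations, genotypes,
                                 damage_map = default_damage_map()) {
  damage_map <- validate_damage_map(damage_map)
  probs <- if ("damage_prob" %in% names(mutations)) {
    ifelse(is.na(mutations$damage_prob),
           damage_map[mutations$mutation_class], mutations$damage_prob)
  } else {
    unname(damage_map[mutations$mutation_class])
  }
  if (anyNA(probs))
    stop_fmt("damage probability unavailable for class(es): %s",
             paste(unique(mutations$mutation_class[is.na(probs)]), collapse = ", "))
  g <- as.data.frame(genotypes)
  g3 <- g[g$generation == "G3" & g$mutation_id %in% mutations$mutation_id, ,
          drop = FALSE]
  mut_idx <- match(g3$mutation_id, mutations$mutation_id)
  g3$gene_id <- mutations$gene_id[mut_idx]
  out <- lapply(split(seq_len(nrow(g3)), g3$gene_id), function(rows) {
    sub <- g3[rows, , drop = FALSE]
    muts <- unique(sub$mutation_id)
    mice <- unique(sub$mouse_id)
    m <- matrix(0L, length(muts), length(mice), dimnames = list(muts, mice))
    hom <- sub[sub$genotype == "HOM", , drop = FALSE]
    m[cbind(match(hom$mutation_id, muts), match(hom$mouse_id, mice))] <- 1L
    hom_matrix(sub$gene_id[1], m,
               probs[match(muts, mutations$mutation_id)])
  })
  out[order(names(out))]
}

#' Exact gene damage probability
#'
#' Enumerates all 2^J truly-damaging/neutral assignments of the gene's J
#' mutations; for each assignment counts the mice HOM for at least one
#' truly damaging mutation (c) and accumulates the product-weighted
#' indicator of `c >= n`.
#'
#' @param hm A [hom_matrix()].
#' @param n Minimum number of homozygously damaged mice.
#' @param enum_limit Largest J enumerated exactly (default 10); above it
#'   an error directs the caller to [damage_prob_mc()].
#' @return P_g(n), a probability.
#' @export
#' @examples
#' hm <- hom_matrix("g", matrix(c(1, 0, 0, 1), 2, 2), c(0.167, 0.045))
#' damage_prob_exact(hm, 1)  # 1 - 0.833 * 0.955
damage_prob_exact <- function(hm, n, enum_limit = 10) {
  J <- nrow(hm$m)
  if (J > enum_limit)
    stop_fmt("J = %d exceeds the enumeration limit (%d); use damage_prob_mc()",
             J, enum_limit)
  if (n < 1) return(1)
  # assignments as rows of a 2^J x J binary matrix
  B <- as.matrix(expand.grid(rep(list(c(0L, 1L)), J)))
  counts <- B %*% hm$m                # assignment x mouse: damaging HOM muts
  c_vec <- rowSums(counts > 0)
  w <- rep(1, nrow(B))
  for (j in seq_len(J))
    w <- w * ifelse(B[, j] == 1L, hm$probs[j], 1 - hm$probs[j])
  sum(w[c_vec >= n])
}

#' Monte Carlo gene damage probability
#'
#' Per simulation, draws each mutation's damaging status independently
#' with its probability, counts mice with at least one damaging HOM
#' mutation, and returns the fraction of simulations reaching `n`
#' (inclusive: `c >= n`, matching the exact enumeration).
#'
#' @inheritParams damage_prob_exact
#' @param sims Number of simulations (default 1000).
#' @param seed Integer seed.
#' @return Monte Carlo estimate of P_g(n).
#' @export
damage_prob_mc <- function(hm, n, sims = 1000, seed = NULL) {
  if (sims < 1) stop_fmt("sims must be >= 1")
  if (n < 1) return(1)
  local_seed(seed)
  J <- nrow(hm$m)
  D <- matrix(stats::rbinom(sims * J, 1L, rep(hm$probs, each = sims)),
              nrow = sims, ncol = J)
  counts <- D %*% hm$m
  mean(rowSums(counts > 0) >= n)
}

#' Per-gene damage report over mouse cutoffs
#'
#' P_g(n) for n = 1..`max_n`, using exact enumeration when the gene has at
#' most `enum_limit` mutations and Monte Carlo otherwise.
#'
#' @inheritParams damage_prob_exact
#' @param max_n Largest cutoff to report.
#' @param sims,seed Monte Carlo controls (used only when J > `enum_limit`).
#' @return Data frame with columns `n`, `p_damage` (nonincreasing in `n`).
#' @export
gene_damage_report <- function(hm, max_n, enum_limit = 10, sims = 1000,
                               seed = NULL) {
  J <- nrow(hm$m)
  p <- if (J <= enum_limit) {
    vapply(seq_len(max_n), function(n) damage_prob_exact(hm, n, enum_limit),
           numeric(1))
  } else {
    f <- function() {
      local_seed(seed)
      D <- matrix(stats::rbinom(sims * J, 1L, rep(hm$probs, each = sims)),
                  nrow = sims, ncol = J)
      c_s <- rowSums((D %*% hm$m) > 0)
      # share one set of simulations across cutoffs for coherence
      vapply(seq_len(max_n), function(n) mean(c_s >= n), numeric(1))
    }
    f()
  }
  data.frame(n = seq_len(max_n), p_damage = p)
}

#' Cumulative genome saturation curve
#'
#' The expected number of genes functionally damaged homozygously in at
#' least `n` mice, S = sum over genes of P_g(n), evaluated cumulatively
#' along a mutation chronology: at each evaluation point only the mutation
#' prefix discovered so far contributes. When `genome_size` is given, the
#' percentage S / G * 100 is reported as well.
#'
#' @param matrices Named list of `hom_matrix` as from
#'   [build_superpedigrees()].
#' @param n Mouse cutoff.
#' @param order Character vector of mutation ids in chronological order
#'   (e.g. database accrual order). Mutations of `matrices` absent from
#'   `order` are appended at the end in matrix order.
#' @param at Integer prefix lengths at which to evaluate the curve;
#'   default: after every mutation.
#' @param genome_size Total gene count G for the percentage scale; `NULL`
#'   (default) reports S only.
#' @param enum_limit,sims,seed Passed to the per-gene calculators.
#' @return Data frame of class `saturation_curve` with columns
#'   `n_mutations`, `s_expected_genes` and, when `genome_size` is given,
#'   `saturation_pct`. S is nondecreasing along the curve.
#' @export
genome_saturation <- function(matrices, n, order = NULL, at = NULL,
                              genome_size = NULL, enum_limit = 10,
                              sims = 1000, seed = NULL) {
  all_muts <- unlist(lapply(matrices, `[[`, "mutation_ids"), use.names = FALSE)
  order <- c(order %||% character(0), setdiff(all_muts, order))
  order <- order[order %in% all_muts]
  at <- sort(unique(as.integer(at %||% seq_along(order))))
  if (any(at < 1 | at > length(order)))
    stop_fmt("evaluation points must lie in 1..%d", length(order))
  seeds <- if (is.null(seed)) rep(list(NULL), length(matrices))
           else as.list(derive_seeds(seed, length(matrices)))
  names(seeds) <- names(matrices)
  s <- vapply(at, function(k) {
    prefix <- order[seq_len(k)]
    total <- 0
    for (gname in names(matrices)) {
      hm <- matrices[[gname]]
      keep <- hm$mutation_ids %in% prefix
      if (!any(keep)) next
      sub <- hom_matrix(hm$gene_id,
                        hm$m[keep, , drop = FALSE],
                        hm$probs[keep])
      total <- total + if (sum(keep) <= enum_limit) {
        damage_prob_exact(sub, n, enum_limit)
      } else {
        damage_prob_mc(sub, n, sims = sims, seed = seeds[[gname]])
      }
    }
    total
  }, numeric(1))
  out <- data.frame(n_mutations = at, s_expected_genes = s)
  if (!is.null(genome_size)) {
    stopifnot(genome_size >= 1)
    out$saturation_pct <- 100 * s / genome_size
  }
  class(out) <- c("saturation_curve", "data.frame")
  out
}
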