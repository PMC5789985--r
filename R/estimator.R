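# Method-of-moments mixture estimator of the truly-damaging fraction of a
# mutation class, from the per-mutation homozygote proportions p_i of
# mutations in essential genes.
#
# Model: a class is a three-subgroup mixture. Writing q for the fraction
# of mutations that damage totally essential genes (p_i = 0), a fraction
# partial_ratio * q damages partially essential genes (p_i scattered
# around theta, 0 < theta < 0.25) and the rest are non-damaging (p_i
# around the Mendelian 0.25). The quantity of interest is the TOTAL
# truly-damaging fraction rho = (1 + partial_ratio) * q; matching first
# moments gives the estimator
#
#   rho = (1 + r) * (0.25 - mean(p)) / (0.25 * (1 + r) - theta * r)
#
# with r = partial_ratio. At the defaults r = 0.39, theta = 0.125 this is
# 1.39 * (0.25 - mean(p)) / 0.29875, which is unbiased for rho under the
# mixture weights (rho/(1+r), r*rho/(1+r), 1-rho).

#' Mixture-model parameters
#'
#' @param theta Center of the homozygote proportion for damaging mutations
#'   in partially essential genes; must lie strictly between 0 and the
#'   Mendelian rate. The true value is unidentifiable from first moments
#'   alone; 0.125 (the midpoint) is the shipped default.
#' @param partial_ratio Ratio of partially to totally essential damaging
#'   mutations (default 0.39, i.e. 39 partially essential genes per 100
#'   totally essential ones, from large-scale viability annotation).
#' @param mendelian_rate Expected homozygote proportion without lethality;
#'   0.25 for an intercross of heterozygotes.
#' @return A list of class `mm_params`.
#' @export
#' @examples
#' mm_params()            # defaults
#' mm_params(theta = 0.1)
mm_params <- function(theta = 0.125, partial_ratio = 0.39,
                      mendelian_rate = 0.25) {
  if (!is.numeric(theta) || length(theta) != 1 ||
      theta <= 0 || theta >= mendelian_rate)
    stop_fmt("theta must lie strictly between 0 and %g", mendelian_rate)
  if (partial_ratio < 0) stop_fmt("partial_ratio must be >= 0")
  structure(list(theta = theta, partial_ratio = partial_ratio,
                 mendelian_rate = mendelian_rate), class = "mm_params")
}

mm_denominator <- function(params) {
  params$mendelian_rate * (1 + params$partial_ratio) -
    params$theta * params$partial_ratio
}

#' Method-of-moments damage-fraction estimate
#'
#' Point estimate of the fraction of truly damaging mutations from a
#' sample of homozygote proportions. The raw estimate is affine and
#' strictly decreasing in `mean(p_list)`; it is 0 when the sample mean
#' equals the Mendelian rate and can exceed \[0, 1\] under sampling noise
#' (an all-lethal sample gives about 1.163 at the defaults), so the
#' clamped value `rho` is reported alongside the raw one.
#'
#' @param p_list Numeric vector of per-mutation homozygote proportions in
#'   \[0, 1\]; must be non-empty.
#' @param params An [mm_params()] object.
#' @return List with `rho_raw` (unclamped) and `rho` (clamped to \[0, 1\]).
#' @export
#' @examples
#' mm_estimate(c(0, 0.25))$rho_raw  # about 0.5816
mm_estimate <- function(p_list, params = mm_params()) {
  if (length(p_list) == 0) stop_fmt("p_list must be non-empty")
  if (anyNA(p_list)) stop_fmt("p_list contains NA; drop uninformative mutations first")
  if (any(p_list < 0 | p_list > 1)) stop_fmt("p_list values must lie in [0, 1]")
  raw <- (1 + params$partial_ratio) *
    (params$mendelian_rate - mean(p_list)) / mm_denominator(params)
  list(rho_raw = raw, rho = min(1, max(0, raw)))
}

#' Percentile bootstrap confidence interval for the damage fraction
#'
#' Resamples the homozygote proportions with replacement (the mutation is
#' the resampling unit), re-computes the clamped estimate for each
#' replicate, and returns the percentile interval.
#'
#' @inheritParams mm_estimate
#' @param reps Number of bootstrap replicates (default 5000).
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed; required for reproducibility.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(p_list, params = mm_params(), reps = 5000,
                         level = 0.95, seed = NULL) {
  if (reps < 1) stop_fmt("reps must be >= 1")
  if (length(p_list) == 0) stop_fmt("p_list must be non-empty")
  local_seed(seed)
  n <- length(p_list)
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
  means <- colMeans(matrix(p_list[idx], nrow = n))
  raw <- (1 + params$partial_ratio) * (params$mendelian_rate - means) /
    mm_denominator(params)
  rho <- pmin(1, pmax(0, raw))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(rho, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(ci_low = ci[1], ci_high = ci[2])
}

estimate_one_group <- function(p, label, params, reps, level, seed) {
  est <- mm_estimate(p, params)
  ci <- bootstrap_ci(p, params, reps = reps, level = level, seed = seed)
  # the point estimate is clamped identically to the replicates, so the
  # percentile interval brackets it up to resampling granularity
  data.frame(group = label, n = length(p),
             rho_raw = est$rho_raw, rho = est$rho,
             ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             bootstrap_reps = reps, stringsAsFactors = FALSE)
}

#' Per-class damage probability estimates
#'
#' Applies the method-of-moments estimator with bootstrap confidence
#' intervals to each mutation class present in a filtered mutation table.
#' Mutations with undefined `p_hom` are excluded; classes with no
#' informative mutations are omitted with a log entry.
#'
#' @param filtered A `filtered_mutation_table` (see [compute_p_hom()]),
#'   normally already restricted to essential genes.
#' @param params An [mm_params()] object.
#' @param reps Bootstrap replicates (default 5000).
#' @param level CI coverage (default 0.95).
#' @param seed Integer master seed; per-class streams are derived from it.
#' @return Data frame with one row per class: `group`, `n`, `rho_raw`,
#'   `rho`, `ci_low`, `ci_high`, `bootstrap_reps`.
#' @export
estimate_by_class <- function(filtered, params = mm_params(), reps = 5000,
                              level = 0.95, seed = NULL) {
  stopifnot("p_hom" %in% names(filtered))
  keep <- filtered$informative %||% !is.na(filtered$p_hom)
  dropped <- sum(!keep)
  if (dropped > 0)
    log_msg(sprintf("excluding %d mutation(s) with undefined p_hom", dropped))
  f <- filtered[keep, , drop = FALSE]
  classes <- intersect(mutation_classes(), unique(f$mutation_class))
  absent <- setdiff(unique(filtered$mutation_class), classes)
  if (length(absent) > 0)
    log_msg(sprintf("class(es) with no informative mutations omitted: %s",
                    paste(absent, collapse = ", ")))
  seeds <- if (is.null(seed)) rep(list(NULL), length(classes))
           else as.list(derive_seeds(seed, length(classes)))
  rows <- lapply(seq_along(classes), function(i) {
    p <- f$p_hom[f$mutation_class == classes[i]]
    estimate_one_group(p, classes[i], params, reps, level, seeds[[i]])
  })
  do.call(rbind, rows)
}

#' Damage estimates across prediction-score windows
#'
#' Re-estimates the damage fraction within user-supplied score windows
#' rather than the three coarse missense classes, to probe how damage
#' probability tracks the continuous prediction score. Windows are
#' half-open intervals (low, high\]: a score on a shared boundary belongs
#' to the window whose upper bound it equals. Only missense mutations
#' (which carry scores) participate; scores outside every window are
#' dropped with a log entry.
#'
#' @param filtered A `filtered_mutation_table`.
#' @param windows List of 2-vectors `c(low, high)`, disjoint and
#'   increasing.
#' @inheritParams estimate_by_class
#' @return Data frame as in [estimate_by_class()], one row per non-empty
#'   window, labelled "(low,high]".
#' @export
estimate_by_score_window <- function(filtered, windows, params = mm_params(),
                                     reps = 5000, level = 0.95, seed = NULL) {
  stopifnot("p_hom" %in% names(filtered))
  if (length(windows) == 0) stop_fmt("windows must be non-empty")
  w <- do.call(rbind, lapply(windows, function(x) {
    if (length(x) != 2 || x[1] >= x[2])
      stop_fmt("each window must be c(low, high) with low < high")
    as.numeric(x)
  }))
  w <- w[order(w[, 1]), , drop = FALSE]
  if (nrow(w) > 1 && any(w[-1, 1] < w[-nrow(w), 2]))
    stop_fmt("score windows overlap")
  keep <- (filtered$informative %||% !is.na(filtered$p_hom)) &
    filtered$mutation_class %in% missense_classes()
  f <- filtered[keep, , drop = FALSE]
  labels <- sprintf("(%g,%g]", w[, 1], w[, 2])
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(w))
           else as.list(derive_seeds(seed, nrow(w)))
  rows <- list()
  assigned <- rep(FALSE, nrow(f))
  for (i in seq_len(nrow(w))) {
    in_w <- f$score > w[i, 1] & f$score <= w[i, 2]
    assigned <- assigned | in_w
    if (!any(in_w)) next
    rows[[length(rows) + 1]] <-
      estimate_one_group(f$p_hom[in_w], labels[i], params, reps, level,
                         seeds[[i]])
  }
  if (any(!assigned))
    log_msg(sprintf("%d missense mutation(s) fall outside all score windows",
                    sum(!assigned)))
  if (length(rows) == 0) stop_fmt("no mutations fall inside any window")
  do.call(rbind, rows)
}

#' Count-weighted average damage probability
#'
#' The overall probability that a mutation (of any class) is truly
#' damaging: the class damage probabilities averaged with class abundances
#' as weights, `sum(count_c * rho_c) / sum(count_c)`.
#'
#' @param estimates Data frame from [estimate_by_class()] (needs columns
#'   `group` and `rho`), or a named numeric vector of per-class
#'   probabilities.
#' @param counts Named integer vector of class abundances; every name must
#'   have a matching estimate.
#' @return The weighted average, a single number in \[0, 1\].
#' @export
#' @examples
#' weighted_average_damage(default_damage_map(),
#'   c(probably_benign = 26004, possibly_damaging = 14412,
#'     probably_damaging = 32669, null_class_I = 5170, null_class_II = 2618))
weighted_average_damage <- function(estimates, counts) {
  if (is.data.frame(estimates)) {
    rho <- stats::setNames(estimates$rho, estimates$group)
  } else {
    rho <- estimates
  }
  missing <- setdiff(names(counts), names(rho))
  if (length(missing) > 0)
    stop_fmt("no estimate for class(es): %s", paste(missing, collapse = ", "))
  if (length(counts) == 0 || sum(counts) <= 0)
    stop_fmt("counts must be non-empty with positive total")
  sum(counts * rho[names(counts)]) / sum(counts)
}
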