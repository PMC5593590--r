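#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Conditional on the observed allele counts, every genotype configuration
#' with a heterozygote count of matching parity is enumerated; configuration
#' probabilities are proportional to
#' `n! / (n_II! n_ID! n_DD!) * 2^n_ID`. The two-sided p-value is the total
#' probability of configurations no more probable than the observed one
#' (probability-ordering rule).
#'
#' @param n_II,n_ID,n_DD observed genotype counts.
#' @return The exact p-value in `(0, 1]`; exactly 1 when only one
#'   configuration is compatible with the allele counts (e.g. a monomorphic
#'   locus).
#' @examples
#' hwe_exact_test(1, 0, 4)   # 1/9
#' @export
hwe_exact_test <- function(n_II, n_ID, n_DD) {
  n <- check_counts(n_II, n_ID, n_DD)
  tab <- hwe_config_probs(2 * n_II + n_ID, n)
  p_obs <- tab$prob[match(n_ID, tab$n_ID)]
  if (is.na(p_obs)) stop("internal error: observed configuration not enumerated")
  # tolerance guards ties against floating-point jitter
  min(1, sum(tab$prob[tab$prob <= p_obs * (1 + 1e-12)]))
}

# all heterozygote counts compatible with n_ins insertion alleles among
# 2n alleles, with their conditional probabilities
hwe_config_probs <- function(n_ins, n) {
  n_del <- 2 * n - n_ins
  m <- min(n_ins, n_del)
  h <- seq.int(m %% 2L, m, by = 2L)
  logw <- lgamma(n + 1) - lgamma((n_ins - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_del - h) / 2 + 1) + h * log(2)
  w <- exp(logw - max(logw))
  data.frame(n_ID = h, prob = w / sum(w))
}

#' Chi-square Hardy-Weinberg test for a biallelic locus
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against their Hardy-Weinberg expectations, without continuity
#' correction. Provided as a large-sample cross-check for
#' [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return A list with `statistic` and `p_value`.
#' @export
hwe_chi2_test <- function(n_II, n_ID, n_DD) {
  n <- check_counts(n_II, n_ID, n_DD)
  p <- (2 * n_II + n_ID) / (2 * n)
  if (p == 0 || p == 1)
    stop("chi-square HWE test is undefined at a monomorphic locus")
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_II, n_ID, n_DD) - expd)^2 / expd)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Bonferroni-corrected significance level
#'
#' @param alpha family-wise level in `(0, 1)`.
#' @param m number of tests.
#' @param digits if non-`NULL`, round the level half-up to this many
#'   decimals for reporting (the usual published convention; 0.05/30 is
#'   reported as 0.0017).
#' @return `alpha / m`, optionally rounded.
#' @export
bonferroni_threshold <- function(alpha, m, digits = NULL) {
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  if (length(m) != 1L || m < 1) stop("m must be a positive count")
  out <- alpha / m
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Hardy-Weinberg screen of every locus in a population
#'
#' Runs the exact test (and, where defined, the chi-square test) at each
#' locus and flags loci significant after Bonferroni correction across the
#' panel.
#'
#' @param ds a [genotype_dataset()].
#' @param population population label (default: the dataset's only one).
#' @param alpha family-wise significance level.
#' @return Data frame with counts, `exact_p`, `chi2_p` (NA at monomorphic
#'   loci), and logical `significant`; the Bonferroni level is in
#'   `attr(, "threshold")`.
#' @export
hwe_test <- function(ds, population = NULL, alpha = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(population)) {
    pops <- populations(ds)
    if (length(pops) != 1L) stop("dataset has several populations; name one")
    population <- pops
  }
  g <- subset_population(ds, population)$dosage
  rows <- lapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j][!is.na(g[, j])]
    n_II <- sum(gj == 2L); n_ID <- sum(gj == 1L); n_DD <- sum(gj == 0L)
    p <- (2 * n_II + n_ID) / (2 * length(gj))
    data.frame(locus = colnames(g)[j], n_II = n_II, n_ID = n_ID, n_DD = n_DD,
               exact_p = hwe_exact_test(n_II, n_ID, n_DD),
               chi2_p = if (p > 0 && p < 1)
                 hwe_chi2_test(n_II, n_ID, n_DD)$p_value else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- bonferroni_threshold(alpha, nrow(out))
  out$significant <- out$exact_p < thr
  attr(out, "threshold") <- thr
  out
}
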