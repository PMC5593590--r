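#' Weir-Cockerham Fst for biallelic loci
#'
#' Two-level Weir-Cockerham (1984) variance-component estimator computed
#' from genotype data: per-locus components `a` (between populations),
#' `b` (between individuals within populations) and `c` (within
#' individuals), with `theta = a / (a + b + c)` per locus and the
#' multi-locus estimate as the ratio of summed components
#' `sum(a) / sum(a + b + c)`. Negative estimates are reported as computed;
#' they are expected scatter around zero under no differentiation.
#'
#' @param ds a [genotype_dataset()].
#' @param populations_use labels of the populations to compare (default:
#'   all populations in `ds`; at least two).
#' @return List with `per_locus` data frame (`locus`, `a`, `b`, `c`,
#'   `theta`; `theta` is `NA` with `defined = FALSE` where
#'   `a + b + c == 0`) and the multi-locus `theta`.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for the
#'   analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(ds, populations_use = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- populations_use %||% populations(ds)
  if (length(pops) < 2L) stop("at least two populations are required")
  sub <- subset_population(ds, pops)
  comp <- wc_components_core(sub$dosage, sub$population, pops)
  tot <- comp$a + comp$b + comp$c
  defined <- is.finite(tot) & tot != 0
  theta <- ifelse(defined, comp$a / tot, NA_real_)
  per <- data.frame(locus = sub$loci, a = comp$a, b = comp$b, c = comp$c,
                    theta = theta, defined = defined,
                    stringsAsFactors = FALSE)
  list(per_locus = per,
       theta = sum(comp$a[defined]) / sum(tot[defined]))
}

# vectorised over loci; dosage rows grouped by `labels` into `pops`
wc_components_core <- function(dosage, labels, pops) {
  r <- length(pops)
  L <- ncol(dosage)
  n_i <- p_i <- h_i <- matrix(0, r, L)
  for (k in seq_len(r)) {
    g <- dosage[labels == pops[k], , drop = FALSE]
    n_i[k, ] <- colSums(!is.na(g))
    p_i[k, ] <- colSums(g, na.rm = TRUE) / (2 * n_i[k, ])
    h_i[k, ] <- colSums(g == 1L, na.rm = TRUE) / n_i[k, ]
  }
  if (any(n_i < 2))
    stop("every population needs >= 2 typed individuals at every locus")
  nbar <- colMeans(n_i)
  nc <- (r * nbar - colSums(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# multi-locus theta straight from a dosage matrix and a two-group split;
# permutation-loop workhorse
theta_multilocus <- function(dosage, labels, pops) {
  comp <- wc_components_core(dosage, labels, pops)
  tot <- comp$a + comp$b + comp$c
  keep <- is.finite(tot) & tot != 0
  sum(comp$a[keep]) / sum(tot[keep])
}

#' Pairwise multi-locus Fst matrix
#'
#' @param ds a [genotype_dataset()] with two or more populations.
#' @return Symmetric matrix of multi-locus Weir-Cockerham theta with zero
#'   diagonal, labelled by population.
#' @export
fst_matrix <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- populations(ds)
  if (length(pops) < 2L) stop("at least two populations are required")
  sizes <- table(ds$population)
  if (any(sizes < 2))
    stop("population(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)[-length(pops)]) for (b in (a + 1L):length(pops)) {
    th <- wc_fst(ds, c(pops[a], pops[b]))$theta
    m[a, b] <- m[b, a] <- th
  }
  m
}

#' Permutation p-value for pairwise Fst
#'
#' Permutes individuals between the two populations (sizes held fixed) and
#' compares the observed multi-locus theta with its permutation
#' distribution: `p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1)`.
#' Bit-reproducible given `seed`.
#'
#' @param ds a [genotype_dataset()].
#' @param pop_a,pop_b the two population labels.
#' @param n_perm number of permutations (>= 100).
#' @param seed mandatory integer seed.
#' @return List with `p_value`, `theta_obs`, `n_perm` and `seed`.
#' @export
fst_permutation_p <- function(ds, pop_a, pop_b, n_perm = 10000L, seed) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (missing(seed)) stop("'seed' is required")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  sub <- subset_population(ds, c(pop_a, pop_b))
  pops <- c(pop_a, pop_b)
  obs <- theta_multilocus(sub$dosage, sub$population, pops)
  n <- nrow(sub$dosage)
  n_a <- sum(sub$population == pop_a)
  perm_theta <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- rep(pop_b, n)
      lab[sample.int(n, n_a)] <- pop_a
      theta_multilocus(sub$dosage, lab, pops)
    }, numeric(1L))
  })
  list(p_value = (1 + sum(perm_theta >= obs)) / (n_perm + 1),
       theta_obs = obs, n_perm = n_perm, seed = seed)
}

#' Fisher exact test of allele-frequency difference at one locus
#'
#' Two-sided Fisher exact test on the 2 x 2 insertion/deletion allele-count
#' table of two populations.
#'
#' @param table_2x2 matrix `rbind(c(ins_a, del_a), c(ins_b, del_b))`.
#' @return The two-sided p-value; 1 (with a warning) for a zero-margin
#'   table.
#' @export
locus_differentiation_test <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!all(dim(tab) == 2L) || any(tab < 0) || anyNA(tab))
    stop("need a non-negative 2 x 2 allele count table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: no allele variation to test; p = 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Per-locus differentiation screen between two populations
#'
#' Applies [locus_differentiation_test()] at every locus and counts loci
#' significant after Bonferroni correction across the panel — the
#' per-comparison reporting convention of forensic population surveys.
#'
#' @param ds a [genotype_dataset()].
#' @param pop_a,pop_b population labels.
#' @param alpha family-wise level.
#' @return List with the per-locus data frame (`locus`, `p_value`,
#'   `significant`), the Bonferroni `threshold`, and `n_significant`.
#' @export
pairwise_differentiation <- function(ds, pop_a, pop_b, alpha = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"))
  fa <- allele_frequencies(ds, pop_a)
  fb <- allele_frequencies(ds, pop_b)
  stopifnot(identical(fa$locus, fb$locus))
  p <- vapply(seq_len(nrow(fa)), function(j) {
    tab <- rbind(
      round(c(2 * fa$n_typed[j] * fa$p_ins[j],
              2 * fa$n_typed[j] * (1 - fa$p_ins[j]))),
      round(c(2 * fb$n_typed[j] * fb$p_ins[j],
              2 * fb$n_typed[j] * (1 - fb$p_ins[j]))))
    suppressWarnings(locus_differentiation_test(tab))
  }, numeric(1L))
  m <- length(p)
  thr <- bonferroni_threshold(alpha, m)
  list(per_locus = data.frame(locus = fa$locus, p_value = p,
                              significant = p < thr,
                              stringsAsFactors = FALSE),
       threshold = thr,
       n_significant = count_significant_loci(p, alpha, m))
}

#' Count loci significant after Bonferroni correction
#'
#' @param p_values per-locus p-values.
#' @param alpha family-wise level.
#' @param m number of tests in the family (default `length(p_values)`).
#' @return Integer count of `p < alpha / m`.
#' @export
count_significant_loci <- function(p_values, alpha = 0.05, m = length(p_values)) {
  sum(p_values < bonferroni_threshold(alpha, m))
}
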