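#' EM haplotype frequencies for two unphased biallelic loci
#'
#' Estimates the four two-locus haplotype frequencies from a 3 x 3 table of
#' genotype counts (insertion dosage at locus A in rows 0/1/2, locus B in
#' columns). Only the double heterozygote is phase-ambiguous; the EM
#' algorithm splits it between the coupling (I-I / D-D) and repulsion
#' (I-D / D-I) phasings in proportion to the current haplotype-frequency
#' products, assuming Hardy-Weinberg within each locus.
#'
#' @param counts 3 x 3 matrix of genotype counts, `counts[i + 1, j + 1]` =
#'   number of individuals with insertion dosage `i` at locus A and `j` at
#'   locus B.
#' @param tol convergence tolerance on the largest haplotype-frequency
#'   change between iterations.
#' @param max_iter iteration cap.
#' @return Named numeric vector `c(II, ID, DI, DD)` of haplotype
#'   frequencies (first letter = allele at locus A), summing to 1, with the
#'   log-likelihood trace in `attr(, "loglik")`.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-8, max_iter = 1000L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || any(counts < 0) || anyNA(counts))
    stop("'counts' must be a non-negative 3 x 3 genotype count table")
  n <- sum(counts)
  if (n < 1) stop("at least one individual is required")
  pA <- sum(counts * (0:2)) / (2 * n)            # rows: dosage at A
  pB <- sum(t(counts) * (0:2)) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("LD undefined: a locus is monomorphic")

  # known haplotype counts from the eight unambiguous cells:
  # cell (i, j) with not both i and j == 1 contributes fixed allele pairs
  base <- c(II = 0, ID = 0, DI = 0, DD = 0)
  for (i in 0:2) for (j in 0:2) {
    if (i == 1L && j == 1L) next
    cnt <- counts[i + 1L, j + 1L]
    if (cnt == 0) next
    # haplotypes are determined: i copies of I at A pair with j copies of I
    # at B in the only consistent way for non-double-heterozygotes
    nII <- min(i, j); nDD <- min(2 - i, 2 - j)
    nID <- i - nII;   nDI <- j - nII
    base <- base + cnt * c(II = nII, ID = nID, DI = nDI, DD = nDD)
  }
  ndh <- counts[2L, 2L]                          # double heterozygotes

  f <- c(II = pA * pB, ID = pA * (1 - pB), DI = (1 - pA) * pB,
         DD = (1 - pA) * (1 - pB))               # linkage-equilibrium start
  ll_trace <- numeric(0)
  hap_name <- function(aI, bI)
    paste0(if (aI) "I" else "D", if (bI) "I" else "D")
  ll_of <- function(f) {
    # multinomial genotype log-likelihood under HWE with haplotype freqs f
    probs <- matrix(0, 3, 3)
    for (i in 0:2) for (j in 0:2) {
      if (i == 1L && j == 1L) {
        pr <- 2 * f["II"] * f["DD"] + 2 * f["ID"] * f["DI"]
      } else {
        # at most one locus heterozygous: the haplotype pair is determined
        h1 <- hap_name(i >= 1L, j >= 1L)
        h2 <- hap_name(i == 2L, j == 2L)
        pr <- f[h1] * f[h2] * (if (h1 == h2) 1 else 2)
      }
      probs[i + 1L, j + 1L] <- pr
    }
    sum(counts[counts > 0] * log(probs[counts > 0]))
  }
  for (it in seq_len(max_iter)) {
    # E-step: split double heterozygotes between the two phasings
    w_coup <- f["II"] * f["DD"]
    w_rep <- f["ID"] * f["DI"]
    frac <- if (w_coup + w_rep > 0) w_coup / (w_coup + w_rep) else 0.5
    hap <- base + ndh * c(II = frac, ID = 1 - frac, DI = 1 - frac, DD = frac)
    f_new <- hap / (2 * n)
    ll_trace <- c(ll_trace, ll_of(f_new))
    if (length(ll_trace) > 1L &&
        ll_trace[length(ll_trace)] < ll_trace[length(ll_trace) - 1L] - 1e-9)
      stop("internal error: EM log-likelihood decreased")
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  attr(f, "loglik") <- ll_trace
  f
}

#' Linkage-disequilibrium r-squared from haplotype frequencies
#'
#' `D = f(II) - pA * pB`; `r2 = D^2 / (pA qA pB qB)`.
#'
#' @param hap named haplotype-frequency vector as returned by
#'   [em_haplotype_freqs()] (order `II, ID, DI, DD`).
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(hap) {
  if (length(hap) != 4L || abs(sum(hap) - 1) > 1e-6 || any(hap < -1e-12))
    stop("'hap' must be four non-negative haplotype frequencies summing to 1")
  pA <- hap[1L] + hap[2L]
  pB <- hap[1L] + hap[3L]
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("r2 undefined: a locus is monomorphic")
  D <- hap[1L] - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Pairwise LD screen across a panel
#'
#' Evaluates r-squared for every unordered pair of polymorphic loci in one
#' population, via EM haplotype frequencies, and flags pairs at or above a
#' screening threshold (markers below it are treated as effectively
#' independent in downstream multi-locus products).
#'
#' @param ds a [genotype_dataset()].
#' @param population population label (default: the dataset's only one).
#' @param threshold screening threshold on r-squared (conventionally 0.1).
#' @return An object of class `ld_matrix`: list with the symmetric `r2`
#'   matrix (unit diagonal by convention), a long data frame `pairs`
#'   (`locus_a`, `locus_b`, `r2`, `flagged`), and `skipped`, the monomorphic
#'   loci left out.
#' @export
ld_matrix <- function(ds, population = NULL, threshold = 0.1) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(population)) {
    pops <- populations(ds)
    if (length(pops) != 1L) stop("dataset has several populations; name one")
    population <- pops
  }
  g <- subset_population(ds, population)$dosage
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1)
  skipped <- colnames(g)[setdiff(seq_len(ncol(g)), poly)]
  if (length(skipped))
    warning("monomorphic loci skipped in LD screen: ",
            paste(skipped, collapse = ", "))
  if (length(poly) < 2L) stop("need at least two polymorphic loci")
  loci <- colnames(g)[poly]
  r2 <- matrix(NA_real_, length(poly), length(poly),
               dimnames = list(loci, loci))
  diag(r2) <- 1
  pairs <- list()
  for (a in seq_along(poly)[-length(poly)]) for (b in (a + 1L):length(poly)) {
    ga <- g[, poly[a]]; gb <- g[, poly[b]]
    ok <- !is.na(ga) & !is.na(gb)
    tab <- matrix(0, 3, 3)
    tt <- table(factor(ga[ok], levels = 0:2), factor(gb[ok], levels = 0:2))
    tab[] <- tt
    val <- ld_r2(em_haplotype_freqs(tab))
    r2[a, b] <- r2[b, a] <- val
    pairs[[length(pairs) + 1L]] <-
      data.frame(locus_a = loci[a], locus_b = loci[b], r2 = val,
                 flagged = val >= threshold, stringsAsFactors = FALSE)
  }
  structure(list(r2 = r2, pairs = do.call(rbind, pairs),
                 skipped = skipped, threshold = threshold,
                 population = population),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("<ld_matrix> %d loci, %d pairs, %d flagged at r2 >= %g\n",
              nrow(x$r2), nrow(x$pairs), sum(x$pairs$flagged), x$threshold))
  if (length(x$skipped))
    cat("  skipped monomorphic loci:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
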