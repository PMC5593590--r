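#' Forensic efficiency parameters for biallelic loci
#'
#' Per-locus statistics used to rate a marker panel for forensic
#' identification and paternity testing. All are plain functions of the
#' genotype counts `(n_II, n_ID, n_DD)` or the insertion-allele frequency
#' `p` at one locus.
#'
#' * `observed_heterozygosity()`: Ho = n_ID / n.
#' * `expected_heterozygosity()`: He = 2 p (1 - p), the Hardy-Weinberg
#'   heterozygosity without a small-sample correction (see
#'   `unbiased = TRUE` for the `2n/(2n-1)` corrected variant).
#' * `pic()`: polymorphic information content,
#'   PIC = 1 - p^2 - q^2 - 2 p^2 q^2 with q = 1 - p.
#' * `match_probability()`: MP = sum of squared *observed* genotype
#'   frequencies; `power_of_discrimination()` is its complement DP = 1 - MP.
#' * `power_of_exclusion()`: PE = h^2 (1 - 2 h H^2) with h = Ho, H = 1 - Ho.
#' * `typical_paternity_index()`: TPI = 1 / (2 (1 - Ho)).
#'
#' @param n_II,n_ID,n_DD genotype counts (insertion homozygote,
#'   heterozygote, deletion homozygote).
#' @param p insertion-allele frequency in `[0, 1]`.
#' @param Ho observed heterozygosity in `[0, 1]`.
#' @param n diploid sample size (only used when `unbiased = TRUE`).
#' @param unbiased if `TRUE`, apply the `2n/(2n-1)` unbiased correction to
#'   He. Off by default: the conventional spreadsheet estimator is the
#'   uncorrected one.
#' @return A single numeric value.
#' @name forensic_parameters
#' @examples
#' observed_heterozygosity(121, 182, 210)   # 182/513
#' expected_heterozygosity(0.5)             # 0.5
#' pic(0.5)                                 # 0.375
#' power_of_exclusion(0.5283)               # ~0.2135
NULL

check_counts <- function(n_II, n_ID, n_DD) {
  counts <- c(n_II, n_ID, n_DD)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0))
    stop("genotype counts must be three non-negative numbers")
  n <- sum(counts)
  if (n < 1) stop("at least one typed genotype is required")
  n
}

check_p <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("allele frequency must be a single value in [0, 1]")
  p
}

#' @rdname forensic_parameters
#' @export
observed_heterozygosity <- function(n_II, n_ID, n_DD) {
  n <- check_counts(n_II, n_ID, n_DD)
  n_ID / n
}

#' @rdname forensic_parameters
#' @export
expected_heterozygosity <- function(p, unbiased = FALSE, n = NULL) {
  check_p(p)
  he <- 2 * p * (1 - p)
  if (unbiased) {
    if (is.null(n) || n < 1) stop("'n' is required for the unbiased estimator")
    he <- he * 2 * n / (2 * n - 1)
  }
  he
}

#' @rdname forensic_parameters
#' @export
pic <- function(p) {
  check_p(p)
  q <- 1 - p
  1 - p^2 - q^2 - 2 * p^2 * q^2
}

#' @rdname forensic_parameters
#' @export
match_probability <- function(n_II, n_ID, n_DD) {
  n <- check_counts(n_II, n_ID, n_DD)
  sum((c(n_II, n_ID, n_DD) / n)^2)
}

#' @rdname forensic_parameters
#' @export
power_of_discrimination <- function(n_II, n_ID, n_DD) {
  1 - match_probability(n_II, n_ID, n_DD)
}

#' @rdname forensic_parameters
#' @export
power_of_exclusion <- function(Ho) {
  if (length(Ho) != 1L || is.na(Ho) || Ho < 0 || Ho > 1)
    stop("Ho must be a single value in [0, 1]")
  H <- 1 - Ho
  Ho^2 * (1 - 2 * Ho * H^2)
}

#' @rdname forensic_parameters
#' @export
typical_paternity_index <- function(Ho) {
  if (length(Ho) != 1L || is.na(Ho) || Ho < 0 || Ho > 1)
    stop("Ho must be a single value in [0, 1]")
  if (Ho == 1) stop("TPI is infinite when every individual is heterozygous")
  1 / (2 * (1 - Ho))
}

#' Combined discrimination and exclusion power over a panel
#'
#' `CDP = 1 - prod(MP)` and `CPE = 1 - prod(1 - PE)` across loci, evaluated
#' in log space so values extremely close to 1 keep their distance from 1
#' (a 30-locus CDP of ~1 - 1e-12 is representable).
#'
#' @param mp per-locus match probabilities.
#' @param pe per-locus powers of exclusion.
#' @return A list with elements `cdp` and `cpe`.
#' @export
combined_powers <- function(mp, pe) {
  if (length(mp) == 0L || length(pe) == 0L)
    stop("per-locus MP and PE vectors must be non-empty")
  if (any(mp < 0 | mp > 1) || any(pe < 0 | pe > 1))
    stop("MP and PE values must lie in [0, 1]")
  list(cdp = -expm1(sum(log(mp))),
       cpe = -expm1(sum(log1p(-pe))))
}

#' Full forensic summary of one population
#'
#' Assembles, for every locus: genotype counts, insertion frequency, Ho, He,
#' MP, DP, PE, TPI, PIC and the exact Hardy-Weinberg p-value, plus the
#' panel-level combined powers CDP and CPE.
#'
#' @param ds a [genotype_dataset()].
#' @param population population label; defaults to the only population when
#'   the dataset has exactly one.
#' @return A `forensic_summary` object: list with `per_locus` data frame,
#'   `cdp`, `cpe`, `population` and `n_samples`. `as.data.frame()` returns
#'   the per-locus table.
#' @export
forensic_summary <- function(ds, population = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(population)) {
    pops <- populations(ds)
    if (length(pops) != 1L)
      stop("dataset has several populations; name one")
    population <- pops
  }
  sub <- subset_population(ds, population)
  g <- sub$dosage
  per <- lapply(seq_along(sub$loci), function(j) {
    gj <- g[, j]
    gj <- gj[!is.na(gj)]
    n_II <- sum(gj == 2L); n_ID <- sum(gj == 1L); n_DD <- sum(gj == 0L)
    n <- n_II + n_ID + n_DD
    if (n == 0L) stop("locus ", sub$loci[j], " has no typed genotypes")
    p <- (2 * n_II + n_ID) / (2 * n)
    ho <- observed_heterozygosity(n_II, n_ID, n_DD)
    mp <- match_probability(n_II, n_ID, n_DD)
    data.frame(
      locus = sub$loci[j], n_typed = n,
      n_II = n_II, n_ID = n_ID, n_DD = n_DD, p_ins = p,
      Ho = ho, He = expected_heterozygosity(p),
      MP = mp, DP = 1 - mp,
      PE = power_of_exclusion(ho),
      TPI = if (ho < 1) typical_paternity_index(ho) else Inf,
      PIC = pic(p),
      HWE_p = hwe_exact_test(n_II, n_ID, n_DD),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  cp <- combined_powers(per$MP, per$PE)
  structure(list(per_locus = per, cdp = cp$cdp, cpe = cp$cpe,
                 population = population, n_samples = nrow(g)),
            class = "forensic_summary")
}

#' @export
as.data.frame.forensic_summary <- function(x, ...) x$per_locus

#' @export
print.forensic_summary <- function(x, digits = 4L, ...) {
  cat(sprintf("<forensic_summary> population %s, %d samples, %d loci\n",
              x$population, x$n_samples, nrow(x$per_locus)))
  show <- x$per_locus[c("locus", "Ho", "He", "MP", "DP", "PE", "TPI",
                        "PIC", "HWE_p")]
  num <- vapply(show, is.numeric, logical(1L))
  show[num] <- lapply(show[num], round_half_up, digits = digits)
  print(utils::head(show, 10L), row.names = FALSE)
  if (nrow(show) > 10L) cat("  ...\n")
  cat(sprintf("CDP = %.15f\nCPE = %.4f\n", x$cdp, round_half_up(x$cpe, 4L)))
  invisible(x)
}

#' Write a forensic summary to CSV and/or JSON
#'
#' The CSV holds one row per locus (full precision); the JSON additionally
#' carries the panel-level CDP and CPE.
#'
#' @param fs a `forensic_summary`.
#' @param csv,json output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_forensic_summary <- function(fs, csv = NULL, json = NULL) {
  stopifnot(inherits(fs, "forensic_summary"))
  if (!is.null(csv))
    utils::write.csv(fs$per_locus, csv, row.names = FALSE, quote = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(population = fs$population, n_samples = fs$n_samples,
           cdp = fs$cdp, cpe = fs$cpe, per_locus = fs$per_locus),
      json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}
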