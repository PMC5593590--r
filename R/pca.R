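#' Principal component analysis of individual genotypes
#'
#' Each genotype entry is normalised as
#' `x = (g - 2 p) / sqrt(2 p (1 - p))` with `p` the pooled insertion
#' frequency of the locus (the frequency-variance scaling standard in
#' genotype PCA). Monomorphic loci are dropped; missing entries contribute
#' zero after centring (mean imputation). Coordinates are deterministic up
#' to per-axis sign.
#'
#' @param ds a [genotype_dataset()].
#' @return A `pca_result`: list with `scores` (samples x components, row
#'   names = sample ids), `eigenvalues` (descending), `var_frac`
#'   (eigenvalue / total variance), `loci_used`, and the sample
#'   `population` labels.
#' @export
pca_individuals <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (nrow(ds$dosage) < 2L) stop("at least two samples are required")
  g <- ds$dosage
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- which(!is.na(p) & p > 0 & p < 1)
  if (!length(keep)) stop("all loci are monomorphic")
  x <- sweep(g[, keep, drop = FALSE], 2, 2 * p[keep])
  x <- sweep(x, 2, sqrt(2 * p[keep] * (1 - p[keep])), `/`)
  x[is.na(x)] <- 0
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, eigenvalues = ev, var_frac = ev / sum(ev),
                 loci_used = ds$loci[keep], population = ds$population),
            class = "pca_result")
}

#' Principal component analysis of population allele frequencies
#'
#' PCA of the centred population x locus insertion-frequency matrix, with
#' no per-locus scaling (frequencies are already commensurate).
#'
#' @param ft a [freq_table()] panel with at least three populations.
#' @return A `pca_result` with one score row per population.
#' @export
pca_populations <- function(ft) {
  fm <- freq_matrix(ft)
  if (nrow(fm) < 3L) stop("at least three populations are required")
  pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x, eigenvalues = ev, var_frac = ev / sum(ev),
                 loci_used = colnames(fm), population = rownames(fm)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$var_frac))
  cat(sprintf("<pca_result> %d rows x %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$var_frac[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}
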