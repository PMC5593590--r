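# Shared fixture builders (everything is generated in code).

# dataset with prescribed genotype counts at each locus, one population
ds_from_counts <- function(counts_list, population = "POP", loci = NULL) {
  cols <- lapply(counts_list, function(cnt) {
    rep(c(2L, 1L, 0L), times = cnt)
  })
  n <- unique(vapply(cols, length, integer(1L)))
  stopifnot(length(n) == 1L)
  dosage <- do.call(cbind, cols)
  loci <- loci %||% paste0("L", seq_along(counts_list))
  genotype_dataset(dosage, population = rep(population, n), loci = loci,
                   sample_id = paste0(population, seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genotype CSV text written to a temp file
write_geno_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

rdirichlet_test <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# independent exact-HWE oracle: enumerate every genotype triple compatible
# with the observed allele counts and sum the probabilities of those no more
# probable than the observed configuration
hwe_enum_oracle <- function(n_II, n_ID, n_DD) {
  n <- n_II + n_ID + n_DD
  n_ins <- 2 * n_II + n_ID
  configs <- list()
  for (het in 0:n) {
    ii <- (n_ins - het) / 2
    if (ii < 0 || ii != floor(ii)) next
    dd <- n - ii - het
    if (dd < 0) next
    configs[[length(configs) + 1L]] <- c(ii, het, dd)
  }
  w <- vapply(configs, function(cf) {
    exp(lfactorial(n) - sum(lfactorial(cf)) + cf[2L] * log(2))
  }, numeric(1L))
  probs <- w / sum(w)
  obs <- which(vapply(configs, function(cf) cf[2L] == n_ID, logical(1L)))
  sum(probs[probs <= probs[obs] * (1 + 1e-12)])
}
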