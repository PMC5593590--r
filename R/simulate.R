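#' Balding-Nichols population allele frequencies
#'
#' Draws per-population insertion frequencies around ancestral values under
#' the Balding-Nichols model: each population's frequency at a locus with
#' ancestral frequency `p` is `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)`,
#' so the between-population variance is `F p (1 - p)` — the model is
#' parameterised directly by the Fst the divergence should induce.
#'
#' @param p_anc ancestral insertion frequencies (strictly inside (0, 1)).
#' @param F divergence parameter in (0, 1); a scalar or one value per
#'   population.
#' @param n_pops number of populations to draw.
#' @param seed mandatory integer seed.
#' @return Matrix `n_pops x length(p_anc)` of population frequencies.
#' @export
balding_nichols_freqs <- function(p_anc, F, n_pops, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (any(p_anc <= 0 | p_anc >= 1))
    stop("ancestral frequencies must lie strictly inside (0, 1)")
  F <- rep_len(F, n_pops)
  if (any(F <= 0 | F >= 1)) stop("F must lie strictly inside (0, 1)")
  L <- length(p_anc)
  with_seed(seed, {
    out <- matrix(0, n_pops, L)
    for (k in seq_len(n_pops)) {
      out[k, ] <- stats::rbeta(L, p_anc * (1 - F[k]) / F[k],
                               (1 - p_anc) * (1 - F[k]) / F[k])
    }
    out
  })
}

#' Simulate Hardy-Weinberg genotypes from population frequencies
#'
#' Dosages are independent `Binomial(2, p)` draws per individual and locus,
#' i.e. random mating within each population.
#'
#' @param pop_freqs matrix of insertion frequencies, one row per
#'   population (row names become population labels) and one column per
#'   locus.
#' @param n_per_pop diploid sample size per population (recycled).
#' @param seed mandatory integer seed.
#' @param loci optional locus names (default `colnames(pop_freqs)` or
#'   `L1..`).
#' @return A [genotype_dataset()].
#' @export
simulate_genotypes <- function(pop_freqs, n_per_pop, seed, loci = NULL) {
  if (missing(seed)) stop("'seed' is required")
  pop_freqs <- as.matrix(pop_freqs)
  if (any(pop_freqs < 0 | pop_freqs > 1)) stop("frequencies must lie in [0, 1]")
  n_pops <- nrow(pop_freqs)
  L <- ncol(pop_freqs)
  pops <- rownames(pop_freqs) %||% paste0("pop", seq_len(n_pops))
  loci <- loci %||% colnames(pop_freqs) %||% paste0("L", seq_len(L))
  n_per_pop <- rep_len(n_per_pop, n_pops)
  with_seed(seed, {
    blocks <- lapply(seq_len(n_pops), function(k) {
      matrix(stats::rbinom(n_per_pop[k] * L, 2L,
                           rep(pop_freqs[k, ], each = n_per_pop[k])),
             nrow = n_per_pop[k])
    })
    dosage <- do.call(rbind, blocks)
    labels <- rep(pops, n_per_pop)
    genotype_dataset(dosage, population = labels,
                     sample_id = paste0(labels, "_",
                                        unlist(lapply(n_per_pop, seq_len))),
                     loci = loci)
  })
}

#' Simulate admixed individuals with known ancestry
#'
#' Each of an individual's two allele copies at each locus first draws an
#' ancestry `k` from the individual's row of `Q_true`, then an allele from
#' `Bernoulli(f_k)`. The generating `Q_true` is attached for recovery
#' tests.
#'
#' @param source_freqs K x L matrix of source-population insertion
#'   frequencies.
#' @param Q_true n x K matrix of true ancestry proportions (rows sum to 1).
#' @param seed mandatory integer seed.
#' @param population label(s) for the simulated samples.
#' @param loci optional locus names.
#' @return A [genotype_dataset()] with `attr(, "Q_true")`.
#' @export
simulate_admixed <- function(source_freqs, Q_true, seed,
                             population = "admixed", loci = NULL) {
  if (missing(seed)) stop("'seed' is required")
  source_freqs <- as.matrix(source_freqs)
  Q_true <- as.matrix(Q_true)
  if (ncol(Q_true) != nrow(source_freqs))
    stop("ncol(Q_true) must equal the number of source populations")
  if (any(Q_true < 0) || any(abs(rowSums(Q_true) - 1) > 1e-8))
    stop("Q_true rows must be non-negative and sum to 1")
  n <- nrow(Q_true)
  L <- ncol(source_freqs)
  K <- nrow(source_freqs)
  loci <- loci %||% colnames(source_freqs) %||% paste0("L", seq_len(L))
  population <- rep_len(population, n)
  with_seed(seed, {
    dosage <- matrix(0L, n, L)
    for (i in seq_len(n)) {
      anc <- sample.int(K, 2L * L, replace = TRUE, prob = Q_true[i, ])
      alle <- stats::rbinom(2L * L, 1L, source_freqs[cbind(anc, rep(seq_len(L), 2L))])
      dosage[i, ] <- alle[seq_len(L)] + alle[L + seq_len(L)]
    }
    ds <- genotype_dataset(dosage, population = population,
                           sample_id = paste0(population, "_", seq_len(n)),
                           loci = loci)
    attr(ds, "Q_true") <- Q_true
    ds
  })
}

#' Configuration for a study-scale synthetic reference panel
#'
#' Defaults emulate a 24-population, 30-locus InDel survey: four regional
#' ancestral poles diverged from one ancestor, drift populations drawn
#' around each pole, one near-identical population pair, and admixed
#' Central-Asian-style populations drawing ancestry from the East-Asian and
#' European poles (one of them the large focal sample).
#'
#' @param n_loci number of biallelic loci.
#' @param anc_range range of the Uniform ancestral insertion frequencies
#'   (kept away from 0/1 so loci stay informative).
#' @param pole_fst named divergence of each regional pole from the shared
#'   ancestor.
#' @param pole_pops populations per pole (drifted at `within_fst`).
#' @param within_fst within-region divergence of each population from its
#'   pole.
#' @param admix_weights list of mixture weights (over the first two poles)
#'   for the admixed populations; the first is the focal population. The
#'   first two entries share identical weights, giving the panel its
#'   near-identical population pair (their distance is pure sampling
#'   noise).
#' @param admix_conc Dirichlet concentration scaling individual ancestry
#'   around the population weights.
#' @param focal_size,ref_size diploid sample sizes for the focal and the
#'   reference populations.
#' @param focal_name name of the focal population.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_loci = 30L,
                         anc_range = c(0.2, 0.8),
                         pole_fst = c(EAS = 0.025, EUR = 0.025,
                                      AMR = 0.055, SIB = 0.035),
                         pole_pops = c(EAS = 9L, EUR = 5L, AMR = 6L, SIB = 1L),
                         within_fst = 0.008,
                         admix_weights = list(FOCAL = c(0.5, 0.5),
                                              CAS2 = c(0.5, 0.5),
                                              CAS3 = c(0.4, 0.6)),
                         admix_conc = 50,
                         focal_size = 513L,
                         ref_size = 100L,
                         focal_name = "FOCAL") {
  stopifnot(identical(names(pole_fst), names(pole_pops)),
            all(pole_fst > 0 & pole_fst < 1),
            within_fst > 0, within_fst < 1,
            anc_range[1] > 0, anc_range[2] < 1, anc_range[1] < anc_range[2])
  structure(list(n_loci = as.integer(n_loci), anc_range = anc_range,
                 pole_fst = pole_fst, pole_pops = pole_pops,
                 within_fst = within_fst,
                 admix_weights = admix_weights, admix_conc = admix_conc,
                 focal_size = as.integer(focal_size),
                 ref_size = as.integer(ref_size),
                 focal_name = focal_name),
            class = "panel_config")
}

#' Generate a multi-population genotype panel with known structure
#'
#' Builds the panel described by a [panel_config()]: ancestral frequencies,
#' regional poles under Balding-Nichols divergence, drift populations per
#' pole (the first pole contributes a near-identical pair), admixed
#' populations with Dirichlet individual ancestries, Hardy-Weinberg
#' genotypes throughout. A pure function of `(config, seed)`.
#'
#' @param config a [panel_config()].
#' @param seed mandatory integer seed.
#' @return List with `genotypes` (a [genotype_dataset()]), `frequencies`
#'   (the per-population [freq_table()] computed from the realised
#'   genotypes), `truth` (ancestral/pole/population frequency matrices and
#'   admixed Q draws) and `config`.
#' @export
generate_reference_panel <- function(config = panel_config(), seed) {
  if (missing(seed)) stop("'seed' is required")
  stopifnot(inherits(config, "panel_config"))
  cf <- config
  loci <- paste0("HLD", sprintf("%02d", seq_len(cf$n_loci)))
  with_seed(seed, {
    p_anc <- stats::runif(cf$n_loci, cf$anc_range[1], cf$anc_range[2])
    # regional poles around the shared ancestor
    poles <- matrix(0, length(cf$pole_fst), cf$n_loci,
                    dimnames = list(names(cf$pole_fst), loci))
    for (r in seq_along(cf$pole_fst)) {
      poles[r, ] <- stats::rbeta(
        cf$n_loci, p_anc * (1 - cf$pole_fst[r]) / cf$pole_fst[r],
        (1 - p_anc) * (1 - cf$pole_fst[r]) / cf$pole_fst[r])
    }
    poles[] <- pmin(pmax(poles, 1e-4), 1 - 1e-4)
    # drift populations around their poles
    pop_freqs <- NULL
    for (r in seq_along(cf$pole_pops)) {
      npop <- cf$pole_pops[r]
      if (npop == 0L) next
      f <- cf$within_fst
      block <- matrix(stats::rbeta(
        npop * cf$n_loci,
        rep(poles[r, ] * (1 - f) / f, each = npop),
        rep((1 - poles[r, ]) * (1 - f) / f, each = npop)), nrow = npop)
      rownames(block) <- paste0(names(cf$pole_pops)[r], seq_len(npop))
      pop_freqs <- rbind(pop_freqs, block)
    }
    colnames(pop_freqs) <- loci
    pop_freqs[] <- pmin(pmax(pop_freqs, 1e-4), 1 - 1e-4)
    ds_drift <- simulate_genotypes(pop_freqs, cf$ref_size,
                                   seed = substream_seed(seed, "drift"),
                                   loci = loci)
    # admixed populations over the first two poles
    admix_names <- names(cf$admix_weights)
    sizes <- ifelse(admix_names == cf$focal_name, cf$focal_size, cf$ref_size)
    names(sizes) <- admix_names
    src <- poles[1:2, , drop = FALSE]
    admix_parts <- list()
    q_truth <- list()
    for (a in seq_along(cf$admix_weights)) {
      w <- cf$admix_weights[[a]]
      Qt <- rdirichlet(sizes[a], cf$admix_conc * w)
      ds_a <- simulate_admixed(src, Qt,
                               seed = substream_seed(seed, paste0("admix", a)),
                               population = admix_names[a], loci = loci)
      q_truth[[admix_names[a]]] <- Qt
      admix_parts[[a]] <- ds_a
    }
    dosage <- do.call(rbind, c(list(ds_drift$dosage),
                               lapply(admix_parts, `[[`, "dosage")))
    labels <- c(ds_drift$population,
                unlist(lapply(admix_parts, `[[`, "population")))
    ids <- c(ds_drift$sample_id,
             unlist(lapply(admix_parts, `[[`, "sample_id")))
    ds <- genotype_dataset(dosage, population = labels,
                           sample_id = ids, loci = loci)
    list(genotypes = ds,
         frequencies = allele_frequencies(ds),
         truth = list(p_anc = p_anc, poles = poles,
                      pop_freqs = pop_freqs, Q_admixed = q_truth),
         config = cf)
  })
}
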