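#' Configuration for a full panel analysis run
#'
#' Exactly one of `genotype_path` (a genotype CSV in the package dialect)
#' or `sim_config` (a [panel_config()], genotypes simulated at run time)
#' must be supplied. All randomness in the run flows from `seed` through
#' named per-stage substreams, so any stage is individually reproducible.
#'
#' @param genotype_path path to a genotype CSV, or `NULL`.
#' @param sim_config a [panel_config()], or `NULL`.
#' @param focal_population label of the population whose forensic summary,
#'   HWE and LD screens are computed; default: the simulated focal
#'   population, or the largest population of the input file.
#' @param alpha family-wise significance level for the Bonferroni screens.
#' @param n_perm permutations for the optional Fst permutation test between
#'   the focal population and its nearest neighbour.
#' @param K_list admixture model sizes to fit and cross-validate.
#' @param n_restarts,tol EM settings passed to [admixture_em()].
#' @param seed mandatory root seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(genotype_path = NULL, sim_config = NULL,
                            focal_population = NULL, alpha = 0.05,
                            n_perm = 1000L, K_list = 2:4,
                            n_restarts = 3L, tol = 1e-5, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (is.null(genotype_path) == is.null(sim_config))
    stop("supply exactly one of 'genotype_path' or 'sim_config'")
  if (!is.null(sim_config)) stopifnot(inherits(sim_config, "panel_config"))
  structure(list(genotype_path = genotype_path, sim_config = sim_config,
                 focal_population = focal_population, alpha = alpha,
                 n_perm = as.integer(n_perm), K_list = as.integer(K_list),
                 n_restarts = as.integer(n_restarts), tol = tol,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full panel analysis
#'
#' Executes, in order: allele frequencies; forensic summary with combined
#' powers; Hardy-Weinberg screen; LD screen; pairwise Fst matrix and
#' per-locus differentiation counts against the focal population; DA
#' distance matrix; neighbor-joining trees (DA and Nei standard metrics);
#' individual- and population-level PCA; admixture fits for each K with
#' cross-validated K choice; and a run manifest. Each stage logs one line
#' and writes its outputs before the next stage starts, so a failure
#' preserves earlier results. Output is a pure function of
#' `(config, seed)`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of all written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  paths <- list()
  out <- function(f) file.path(out_dir, f)
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    v
  }

  ds <- stage("input", {
    if (!is.null(config$sim_config)) {
      panel <- generate_reference_panel(config$sim_config,
                                        seed = substream_seed(seed, "simulate"))
      panel$genotypes
    } else {
      read_genotype_table(config$genotype_path)
    }
  })
  message(sprintf("[input] %d samples x %d loci, %d populations",
                  nrow(ds$dosage), ncol(ds$dosage),
                  length(populations(ds))))
  focal <- config$focal_population %||%
    if (!is.null(config$sim_config)) config$sim_config$focal_name else
      names(which.max(table(ds$population)))
  if (!focal %in% ds$population)
    stop("focal population '", focal, "' not present")

  freqs <- stage("frequencies", {
    ft <- allele_frequencies(ds)
    write_frequency_table(ft, paths$frequencies <- out("frequencies.csv"))
    ft
  })

  stage("forensic", {
    fs <- forensic_summary(ds, focal)
    write_forensic_summary(fs,
      csv = paths$forensic_csv <- out("forensic_summary.csv"),
      json = paths$forensic_json <- out("forensic_summary.json"))
  })

  stage("hwe", {
    hw <- hwe_test(ds, focal, alpha = config$alpha)
    utils::write.csv(hw, paths$hwe <- out("hwe.csv"), row.names = FALSE)
  })

  stage("ld", {
    ld <- ld_matrix(ds, focal)
    utils::write.csv(ld$r2, paths$ld_matrix <- out("ld_r2.csv"), quote = FALSE)
    utils::write.csv(ld$pairs, paths$ld_pairs <- out("ld_pairs.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  stage("fst", {
    fm <- fst_matrix(ds)
    write_distance_matrix(fm, paths$fst_matrix <- out("fst_matrix.csv"))
    long <- data.frame(pop_a = rownames(fm)[row(fm)[upper.tri(fm)]],
                       pop_b = colnames(fm)[col(fm)[upper.tri(fm)]],
                       fst = pmax(fm[upper.tri(fm)], 0))
    utils::write.csv(long, paths$fst_long <- out("fst_long.csv"),
                     row.names = FALSE, quote = FALSE)
    refs <- setdiff(populations(ds), focal)
    sig <- vapply(refs, function(p)
      pairwise_differentiation(ds, focal, p, alpha = config$alpha)$n_significant,
      numeric(1L))
    utils::write.csv(data.frame(population = refs, n_significant_loci = sig),
                     paths$locus_sig <- out("locus_significance.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  stage("distance", {
    da <- da_matrix(freqs)
    write_distance_matrix(da, paths$da_matrix <- out("da_matrix.csv"))
  })

  stage("trees", {
    to_newick(frequency_tree(freqs, "da"),
              paths$tree_da <- out("tree_da.nwk"))
    to_newick(frequency_tree(freqs, "nei"),
              paths$tree_nei <- out("tree_nei.nwk"))
  })

  stage("pca", {
    pi_ <- pca_individuals(ds)
    utils::write.csv(
      data.frame(sample_id = rownames(pi_$scores),
                 population = pi_$population,
                 pi_$scores[, seq_len(min(10L, ncol(pi_$scores))), drop = FALSE]),
      paths$pca_ind <- out("pca_individuals.csv"), row.names = FALSE,
      quote = FALSE)
    pp <- pca_populations(freqs)
    utils::write.csv(
      data.frame(population = rownames(pp$scores),
                 pp$scores[, seq_len(min(10L, ncol(pp$scores))), drop = FALSE]),
      paths$pca_pop <- out("pca_populations.csv"), row.names = FALSE,
      quote = FALSE)
    utils::write.csv(
      data.frame(component = seq_along(pp$var_frac),
                 var_frac_individual = c(pi_$var_frac,
                   rep(NA, max(0, length(pp$var_frac) - length(pi_$var_frac))))[
                     seq_along(pp$var_frac)],
                 var_frac_population = pp$var_frac),
      paths$pca_var <- out("pca_variance.csv"), row.names = FALSE,
      quote = FALSE)
  })

  stage("admixture", {
    for (K in config$K_list) {
      fit <- admixture_em(ds, K, seed = substream_seed(seed, paste0("admix", K)),
                          tol = config$tol, n_restarts = config$n_restarts)
      qdf <- data.frame(sample_id = rownames(fit$Q),
                        population = ds$population, fit$Q)
      names(qdf)[-(1:2)] <- paste0("q", seq_len(K))
      utils::write.csv(qdf, paths[[paste0("admixture_K", K)]] <-
                         out(sprintf("admixture_K%d.csv", K)),
                       row.names = FALSE, quote = FALSE)
    }
    cv <- choose_k(ds, config$K_list, folds = 3L,
                   seed = substream_seed(seed, "choose_k"),
                   tol = max(config$tol, 1e-4),
                   n_restarts = max(1L, config$n_restarts %/% 2L))
    utils::write.csv(cv, paths$cv_errors <- out("cv_errors.csv"),
                     row.names = FALSE, quote = FALSE)
  })

  stage("manifest", {
    cfg_file <- tempfile(fileext = ".json")
    jsonlite::write_json(config[setdiff(names(config), "sim_config")],
                         cfg_file, auto_unbox = TRUE, digits = NA,
                         null = "null")
    manifest <- list(
      seed = seed,
      focal_population = focal,
      config_hash = unname(tools::md5sum(cfg_file)),
      n_samples = nrow(ds$dosage), n_loci = ncol(ds$dosage),
      populations = populations(ds),
      package_version = as.character(utils::packageVersion("popindel")),
      r_version = R.version.string,
      outputs = lapply(paths, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, paths$manifest <- out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    unlink(cfg_file)
  })

  invisible(paths)
}
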