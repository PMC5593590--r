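#' Maximum-likelihood admixture model fitted by EM
#'
#' Fits the standard unsupervised admixture model for unlinked biallelic
#' loci: individual `i`'s two allele copies at locus `l` are independent
#' draws whose insertion probability is `sum_k q_ik f_kl`, where `Q`
#' (n x K) holds ancestry proportions and `F` (K x L) ancestral insertion
#' frequencies. The log-likelihood
#' `sum_il [g_il log(mu_il) + (2 - g_il) log(1 - mu_il)]`
#' is maximised by EM; each iteration provably does not decrease it, and
#' the run with the best final likelihood over `n_restarts` random starts
#' is returned. Missing genotypes contribute nothing to the sums.
#'
#' @param ds a [genotype_dataset()].
#' @param K number of ancestral populations (>= 1, <= n samples).
#' @param seed mandatory integer seed (drives the random restarts).
#' @param tol stop when the log-likelihood gain drops below this.
#' @param max_iter iteration cap per restart.
#' @param n_restarts random restarts; the default 10 guards against local
#'   optima at small K.
#' @return An `admixture_result`: list with `Q` (rows sum to 1, row names =
#'   sample ids), `F` (clipped to `[1e-6, 1 - 1e-6]`), `loglik`, the
#'   per-iteration `trace` of the best restart, `iterations`, `K` and
#'   `seed`.
#' @export
admixture_em <- function(ds, K, seed, tol = 1e-6, max_iter = 2000L,
                         n_restarts = 10L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (missing(seed)) stop("'seed' is required")
  n <- nrow(ds$dosage)
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("K cannot exceed the number of samples")
  G <- ds$dosage
  with_seed(seed, {
    best <- NULL
    for (rep in seq_len(n_restarts)) {
      fit <- admixture_em_once(G, K, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    rownames(best$Q) <- ds$sample_id
    colnames(best$F) <- ds$loci
    structure(c(best, list(K = K, seed = seed)), class = "admixture_result")
  })
}

# one EM run from a random start; G is the dosage matrix (NA = missing)
admixture_em_once <- function(G, K, tol, max_iter) {
  n <- nrow(G); L <- ncol(G)
  obs <- !is.na(G)
  g <- G; g[!obs] <- 0
  gc_ <- 2 - G; gc_[!obs] <- 0
  n_alleles_i <- 2 * rowSums(obs)
  if (any(n_alleles_i == 0)) stop("sample with no typed genotypes")
  Q <- rdirichlet(n, rep(1, K))
  Fm <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
  clip <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  ll_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    P <- Q %*% Fm                       # n x L insertion prob per copy
    P <- clip(P)
    ll <- sum(g * log(P) + gc_ * log1p(-P))
    if (ll < ll_old - 1e-6 * max(1, abs(ll_old)))
      stop("internal error: EM log-likelihood decreased")
    trace <- c(trace, ll)
    converged <- (ll - ll_old) < tol && it > 1L
    ll_old <- ll
    if (converged) break
    # E-step / M-step in one sweep over ancestries
    A <- matrix(0, n, K)                # expected allele copies per ancestry
    FA <- matrix(0, K, L)               # expected insertion copies
    FB <- matrix(0, K, L)               # expected total copies
    WI <- g / P                         # shared ratios
    WD <- gc_ / (1 - P)
    for (k in seq_len(K)) {
      a_k <- (Q[, k] %o% Fm[k, ]) * WI        # insertion copies from k
      b_k <- (Q[, k] %o% (1 - Fm[k, ])) * WD  # deletion copies from k
      A[, k] <- rowSums(a_k + b_k)
      FA[k, ] <- colSums(a_k)
      FB[k, ] <- colSums(a_k + b_k)
    }
    Q <- A / n_alleles_i
    Q <- Q / rowSums(Q)
    Fm <- clip(FA / pmax(FB, 1e-300))
  }
  list(Q = Q, F = Fm, loglik = ll_old, trace = trace,
       iterations = length(trace))
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("<admixture_result> K = %d, %d samples, logLik = %.2f, %d iterations\n",
              x$K, nrow(x$Q), x$loglik, x$iterations))
  invisible(x)
}

#' Cross-validated choice of the number of ancestral populations
#'
#' Non-missing genotype entries are split at random into `folds` folds;
#' for each fold the model is refitted with the fold masked and the
#' held-out entries are scored by binomial deviance at the fitted allele
#' dose `mu_il = sum_k q_ik f_kl`. For scoring, `mu` is floored away from
#' the boundary at `1 / (2 n + 2)` (add-one smoothing scale): a fit on `n`
#' diploids cannot support a more extreme predicted frequency, and without
#' the floor a handful of boundary `F` estimates dominate the deviance.
#' Lower mean deviance indicates a better supported K. Deterministic given
#' `seed`.
#'
#' @inheritParams admixture_em
#' @param K_list candidate K values.
#' @param folds number of cross-validation folds (>= 2).
#' @param ... further arguments passed to [admixture_em()] (e.g. `tol`,
#'   `n_restarts`) for the fold fits.
#' @return Data frame with columns `K` and `cv_error` (mean held-out
#'   deviance per allele), one row per candidate, plus attribute `best_k`.
#' @export
choose_k <- function(ds, K_list, folds = 3L, seed, ...) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (missing(seed)) stop("'seed' is required")
  if (folds < 2L) stop("at least two folds are required")
  if (any(K_list < 1L)) stop("every K must be >= 1")
  G <- ds$dosage
  obs_idx <- which(!is.na(G))
  fold_of <- with_seed(seed, {
    for (attempt in 1:10) {
      f <- sample(rep_len(seq_len(folds), length(obs_idx)))
      ok <- TRUE
      for (fd in seq_len(folds)) {
        Gm <- G
        Gm[obs_idx[f == fd]] <- NA
        if (any(rowSums(!is.na(Gm)) == 0) || any(colSums(!is.na(Gm)) == 0)) {
          ok <- FALSE; break
        }
      }
      if (ok) break
      if (attempt == 10) stop("could not draw folds leaving every sample and locus typed")
    }
    f
  })
  cv <- vapply(K_list, function(K) {
    dev <- 0; n_held <- 0
    for (fd in seq_len(folds)) {
      held <- obs_idx[fold_of == fd]
      Gm <- G
      Gm[held] <- NA
      ds_m <- genotype_dataset(Gm, ds$population, ds$sample_id, ds$loci)
      fit <- admixture_em(ds_m, K,
                          seed = substream_seed(seed, paste0("cv", K, ".", fd)),
                          ...)
      floor_p <- 1 / (2 * nrow(G) + 2)
      mu <- pmin(pmax(fit$Q %*% fit$F, floor_p), 1 - floor_p)
      gh <- G[held]
      dev <- dev - 2 * sum(gh * log(mu[held]) + (2 - gh) * log1p(-mu[held]))
      n_held <- n_held + 2 * length(held)
    }
    dev / n_held
  }, numeric(1L))
  out <- data.frame(K = K_list, cv_error = cv)
  attr(out, "best_k") <- K_list[which.min(cv)]
  out
}

#' Resolve label switching between two Q matrices
#'
#' Ancestry components are identified only up to permutation; this finds
#' the column permutation of `Q_b` minimising the mean absolute difference
#' to `Q_a` (exhaustive for K <= 8, greedy above with a warning). Ties go
#' to the lexicographically smallest permutation.
#'
#' @param Q_a,Q_b two n x K ancestry-proportion matrices over the same
#'   samples.
#' @return List with `perm` (apply as `Q_b[, perm]`), and the achieved
#'   `residual` mean absolute difference.
#' @export
align_q_labels <- function(Q_a, Q_b) {
  Q_a <- as.matrix(Q_a); Q_b <- as.matrix(Q_b)
  if (!all(dim(Q_a) == dim(Q_b)))
    stop("Q matrices must have identical dimensions")
  K <- ncol(Q_a)
  score <- function(perm) mean(abs(Q_a - Q_b[, perm, drop = FALSE]))
  if (K <= 8L) {
    perms <- all_permutations(K)
    best <- perms[[1L]]; best_s <- score(best)
    for (p in perms[-1L]) {
      s <- score(p)
      if (s < best_s) { best_s <- s; best <- p }
    }
  } else {
    warning("K > 8: greedy label alignment")
    best <- integer(K); used <- logical(K)
    for (k in seq_len(K)) {
      d <- vapply(seq_len(K), function(j)
        if (used[j]) Inf else mean(abs(Q_a[, k] - Q_b[, j])), numeric(1L))
      best[k] <- which.min(d); used[best[k]] <- TRUE
    }
    best_s <- score(best)
  }
  list(perm = best, residual = best_s)
}

# permutations of 1:k in lexicographic order
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_permutations(k - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[p])
  }
  out
}
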