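test_that("individual PCA separates diverged populations and keeps identities", {
  f <- rbind(A = c(rep(0.9, 15), rep(0.1, 15)),
             B = c(rep(0.1, 15), rep(0.9, 15)))
  ds <- simulate_genotypes(f, 100, seed = 71)
  pc <- pca_individuals(ds)
  s1 <- pc$scores[pc$population == "A", 1]
  s2 <- pc$scores[pc$population == "B", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))  # no PC1 overlap
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))      # sorted descending

  # duplicated sample rows land on identical coordinates
  d2 <- rbind(ds$dosage, ds$dosage[1, , drop = FALSE])
  ds2 <- genotype_dataset(d2, c(ds$population, "A"),
                          c(ds$sample_id, "copy"), ds$loci)
  pc2 <- pca_individuals(ds2)
  expect_equal(unname(pc2$scores["copy", ]),
               unname(pc2$scores[ds$sample_id[1], ]))
  mono <- genotype_dataset(matrix(2L, 5, 3), rep("A", 5))
  expect_error(pca_individuals(mono), "monomorphic")
})

test_that("population PCA is centred-only with the expected rank behaviour", {
  # three collinear frequency vectors: second eigenvalue vanishes
  base <- seq(0.2, 0.8, length.out = 10)
  ft <- freq_table(data.frame(
    population = rep(c("P1", "P2", "P3"), each = 10),
    locus = rep(paste0("L", 1:10), 3),
    p_ins = c(base, base + 0.05, base + 0.10), n_typed = 100))
  pc <- pca_populations(ft)
  expect_lt(pc$eigenvalues[2], 1e-12)
  # permuting locus order leaves the eigenvalues unchanged
  ord <- c(7, 2, 9, 4, 1, 10, 3, 6, 5, 8)
  ft_p <- freq_table(ft[order(match(ft$locus, paste0("L", ord))), ])
  expect_equal(pca_populations(ft_p)$eigenvalues, pc$eigenvalues)
  expect_error(pca_populations(freq_table(ft[ft$population != "P3", ])),
               "three populations")
})

test_that("admixture EM at K = 1 reduces to pooled frequencies", {
  set.seed(81)
  f <- matrix(runif(10, 0.3, 0.7), 1, dimnames = list("P", NULL))
  ds <- simulate_genotypes(f, 50, seed = 82)
  fit <- admixture_em(ds, 1, seed = 83, n_restarts = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 50))
  p_hat <- colMeans(ds$dosage) / 2
  expect_equal(unname(fit$F[1, ]), unname(p_hat), tolerance = 1e-6)
  # log-likelihood equals the binomial likelihood at the MLE
  ll <- sum(ds$dosage * log(rep(p_hat, each = 50)) +
              (2 - ds$dosage) * log(rep(1 - p_hat, each = 50)))
  expect_equal(fit$loglik, ll, tolerance = 1e-4)
  # trace is monotone and Q rows stay on the simplex
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_equal(unname(rowSums(fit$Q)), rep(1, 50), tolerance = 1e-8)
  expect_true(all(fit$F >= 1e-6 & fit$F <= 1 - 1e-6))
})

test_that("admixture EM recovers ancestry from strongly diverged sources", {
  src <- matrix(c(rep(0.95, 30), rep(0.05, 30)), 2, 30, byrow = TRUE)
  Qt <- rbind(matrix(rep(c(1, 0), 80), 80, 2, byrow = TRUE),
              matrix(rep(c(0, 1), 80), 80, 2, byrow = TRUE),
              matrix(rep(c(0.5, 0.5), 40), 40, 2, byrow = TRUE))
  ds <- simulate_admixed(src, Qt, seed = 91,
                         population = rep(c("A", "B", "MIX"), c(80, 80, 40)))
  fit <- admixture_em(ds, 2, seed = 92, n_restarts = 3, tol = 1e-7,
                      max_iter = 5000)
  al <- align_q_labels(Qt, fit$Q)
  Qa <- fit$Q[, al$perm]
  expect_lt(mean(abs(Qt - Qa)), 0.05)
  # 50/50 admixed individuals average near half ancestry
  expect_equal(mean(Qa[161:200, 1]), 0.5, tolerance = 0.1)
})

test_that("cross-validated K selection is seeded and handles a single K", {
  f <- balding_nichols_freqs(seq(0.3, 0.7, length.out = 20), 0.3, 3, seed = 95)
  ds <- simulate_genotypes(f, 40, seed = 96)
  cv1 <- choose_k(ds, K_list = 1L, folds = 2, seed = 97, n_restarts = 1,
                  tol = 1e-3)
  expect_equal(nrow(cv1), 1L)
  expect_equal(attr(cv1, "best_k"), 1L)
  cv2 <- choose_k(ds, K_list = 1L, folds = 2, seed = 97, n_restarts = 1,
                  tol = 1e-3)
  expect_identical(cv1, cv2)
})

test_that("label alignment recovers permutations and breaks ties low", {
  set.seed(99)
  Q <- rdirichlet_test(40, c(2, 1, 1))
  al <- align_q_labels(Q, Q[, c(3, 1, 2)])
  expect_equal(al$perm, c(2, 3, 1))   # inverse permutation restores Q
  expect_equal(al$residual, 0)
  # symmetric Q: both permutations tie, lexicographically first wins
  Qs <- matrix(0.5, 10, 2)
  expect_equal(align_q_labels(Qs, Qs)$perm, c(1, 2))
  # noisy copy aligns with residual at the noise scale
  Qn <- Q + matrix(runif(120, -0.02, 0.02), 40)
  Qn <- pmax(Qn, 0); Qn <- Qn / rowSums(Qn)
  al2 <- align_q_labels(Q, Qn[, c(2, 3, 1)])
  expect_equal(al2$perm, c(3, 1, 2))
  expect_lt(al2$residual, 0.03)
})
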