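test_that("exact HWE p-values match full enumeration", {
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_equal(hwe_exact_test(1, 0, 4), 1 / 9)
  expect_equal(hwe_exact_test(0, 2, 3), 1)
  # grid of counts against the independent enumeration oracle
  for (cnt in list(c(5, 5, 5), c(10, 2, 3), c(0, 9, 1), c(7, 0, 7),
                   c(121, 182, 210), c(2, 11, 37))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 info = paste(cnt, collapse = ","))
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("chi-square HWE test matches a hand computation", {
  exact_hwe <- hwe_chi2_test(25, 50, 25)
  expect_equal(exact_hwe$statistic, 0)
  expect_equal(exact_hwe$p_value, 1)
  split_hwe <- hwe_chi2_test(50, 0, 50)
  expect_equal(split_hwe$statistic, 100)      # statistic equals n at maximal disequilibrium
  expect_lt(split_hwe$p_value, 1e-20)
  # (30, 40, 30): p = 0.5, expected (25, 50, 25), X2 = 1 + 2 + 1 = 4
  res <- hwe_chi2_test(30, 40, 30)
  expect_equal(res$statistic, 4)
  expect_equal(res$p_value, pchisq(4, 1, lower.tail = FALSE))
  expect_error(hwe_chi2_test(10, 0, 0), "monomorphic")
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_equal(bonferroni_threshold(0.05, 30, digits = 4), 0.0017)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("dataset-level HWE screen flags by corrected threshold", {
  ds <- ds_from_counts(list(c(25, 50, 25), c(50, 0, 50)))
  res <- hwe_test(ds, alpha = 0.05)
  expect_equal(attr(res, "threshold"), 0.025)
  expect_false(res$significant[1L])
  expect_true(res$significant[2L])
})

test_that("EM haplotype frequencies resolve phase correctly", {
  # fully determined phase: equal numbers of (2,2) and (0,0) individuals
  tab <- matrix(0, 3, 3); tab[3, 3] <- 5; tab[1, 1] <- 5
  h <- em_haplotype_freqs(tab)
  expect_equal(unname(h[c("II", "DD")]), c(0.5, 0.5))
  expect_equal(unname(h[c("ID", "DI")]), c(0, 0))

  # independence fixed point at p = q = 0.5 (cells at product expectations)
  tab2 <- 16 * outer(c(.25, .5, .25), c(.25, .5, .25))
  h2 <- em_haplotype_freqs(tab2)
  expect_equal(as.numeric(h2), rep(0.25, 4), tolerance = 1e-6)

  # single double heterozygote: symmetric likelihood, 50/50 phase mixture
  tab3 <- matrix(0, 3, 3); tab3[2, 2] <- 1
  h3 <- em_haplotype_freqs(tab3)
  expect_equal(as.numeric(h3), rep(0.25, 4), tolerance = 1e-6)

  expect_error(em_haplotype_freqs(matrix(c(4, rep(0, 8)), 3, 3)), "monomorphic")
  # log-likelihood trace is monotone non-decreasing
  set.seed(7)
  for (i in 1:20) {
    t_r <- matrix(rpois(9, 5), 3, 3)
    if (sum(t_r * (0:2)) %in% c(0, 2 * sum(t_r)) ||
        sum(t(t_r) * (0:2)) %in% c(0, 2 * sum(t_r))) next
    hr <- em_haplotype_freqs(t_r)
    expect_true(all(diff(attr(hr, "loglik")) >= -1e-9))
    expect_equal(sum(hr), 1)
    expect_true(all(hr >= 0))
  }
})

test_that("r2 follows its definition and is label-swap invariant", {
  expect_equal(ld_r2(c(0.5, 0, 0, 0.5)), 1)
  expect_equal(ld_r2(c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(ld_r2(c(0.4, 0.1, 0.1, 0.4)), 0.36)
  # swapping allele labels at locus A maps (II,ID,DI,DD) -> (DI,DD,II,ID)
  h <- c(0.35, 0.15, 0.2, 0.3)
  expect_equal(ld_r2(h), ld_r2(h[c(3, 4, 1, 2)]))
  # and at locus B -> (ID,II,DD,DI)
  expect_equal(ld_r2(h), ld_r2(h[c(2, 1, 4, 3)]))
  expect_error(ld_r2(c(1, 0, 0, 0)), "monomorphic")
})

test_that("LD screen covers all pairs and flags perfect correlation", {
  set.seed(13)
  f <- matrix(runif(30, 0.3, 0.7), 1, dimnames = list("P", NULL))
  ds <- simulate_genotypes(f, 500, seed = 17)
  ld <- ld_matrix(ds)
  expect_equal(nrow(ld$pairs), 30 * 29 / 2)
  expect_true(isSymmetric(ld$r2))
  expect_true(all(ld$r2 >= 0 & ld$r2 <= 1))
  # independent simulated loci at n = 500: nothing should exceed 0.1
  expect_false(any(ld$pairs$flagged))

  # duplicated locus column gives r2 = 1 for that pair
  d2 <- cbind(ds$dosage[, 1:3], dup = ds$dosage[, 3])
  ds2 <- genotype_dataset(d2, ds$population, ds$sample_id,
                          c(ds$loci[1:3], "dup"))
  ld2 <- ld_matrix(ds2)
  expect_equal(ld2$r2["L3", "dup"], 1)
  expect_true(ld2$pairs$flagged[ld2$pairs$locus_a == "L3" &
                                  ld2$pairs$locus_b == "dup"])

  # monomorphic loci are skipped with a warning and recorded
  d3 <- cbind(ds$dosage[, 1:2], mono = rep(2L, nrow(ds$dosage)))
  ds3 <- genotype_dataset(d3, ds$population, ds$sample_id,
                          c(ds$loci[1:2], "mono"))
  expect_warning(ld3 <- ld_matrix(ds3), "monomorphic")
  expect_identical(ld3$skipped, "mono")
})
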