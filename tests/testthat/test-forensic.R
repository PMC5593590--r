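test_that("per-locus parameters reproduce their closed forms", {
  expect_equal(observed_heterozygosity(0, 5, 0), 1)
  expect_equal(observed_heterozygosity(5, 0, 5), 0)
  expect_equal(observed_heterozygosity(121, 182, 210), 182 / 513)

  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(0), 0)
  expect_equal(expected_heterozygosity(0.7641), 2 * 0.7641 * 0.2359)
  # the unbiased variant is strictly larger for 0 < p < 1
  expect_gt(expected_heterozygosity(0.5, unbiased = TRUE, n = 513), 0.5)

  expect_equal(pic(0.5), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(round(pic(0.7641), 4), 0.2955)

  expect_equal(match_probability(7, 0, 0), 1)
  expect_equal(match_probability(1, 1, 1), 1 / 3)
  expect_equal(power_of_discrimination(1, 1, 1), 2 / 3)

  expect_equal(power_of_exclusion(0), 0)
  expect_equal(typical_paternity_index(0), 0.5)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_error(typical_paternity_index(1), "infinite")
})

test_that("parameter identities and monotonicity hold across the range", {
  hs <- seq(0.01, 0.99, by = 0.01)
  pe <- vapply(hs, power_of_exclusion, numeric(1L))
  tpi <- vapply(hs, typical_paternity_index, numeric(1L))
  expect_true(all(diff(pe) > 0))
  expect_true(all(diff(tpi) > 0))
  ps <- seq(0, 1, by = 0.01)
  he <- vapply(ps, expected_heterozygosity, numeric(1L))
  pc <- vapply(ps, pic, numeric(1L))
  expect_equal(he, rev(he))            # He(p) = He(1-p)
  expect_equal(pc, rev(pc))            # PIC(p) = PIC(1-p)
  inner <- ps > 0 & ps < 1
  expect_true(all(pc[inner] < he[inner]))
  expect_equal(pc[!inner], he[!inner])
  # DP + MP = 1 exactly
  for (cnt in list(c(3, 4, 5), c(10, 0, 2), c(1, 1, 1))) {
    expect_identical(match_probability(cnt[1], cnt[2], cnt[3]) +
                       power_of_discrimination(cnt[1], cnt[2], cnt[3]), 1)
  }
})

test_that("combined powers multiply complements across loci", {
  one <- combined_powers(0.4, 0.2)
  expect_equal(one$cdp, 0.6)
  expect_equal(one$cpe, 0.2)
  expect_equal(combined_powers(rep(0.4, 30), rep(0.2, 30))$cdp, 1 - 0.4^30)
  expect_equal(combined_powers(rep(0.4, 30), rep(0.0887, 30))$cpe,
               1 - prod(rep(1 - 0.0887, 30)))
  # monotone non-decreasing in the number of loci
  mp <- runif(10, 0.3, 0.6); pe <- runif(10, 0.05, 0.3)
  cdp <- vapply(1:10, function(k) combined_powers(mp[1:k], pe[1:k])$cdp,
                numeric(1L))
  cpe <- vapply(1:10, function(k) combined_powers(mp[1:k], pe[1:k])$cpe,
                numeric(1L))
  expect_true(all(diff(cdp) >= 0) && all(diff(cpe) >= 0))
  expect_error(combined_powers(numeric(0), numeric(0)), "non-empty")
})

test_that("forensic summary is exact on Hardy-Weinberg counts and invariant to row order", {
  # every locus with p = 0.5 and exact HWE proportions (25, 50, 25)
  ds <- ds_from_counts(list(c(25, 50, 25), c(25, 50, 25)))
  fs <- forensic_summary(ds)
  expect_equal(fs$per_locus$He, c(0.5, 0.5))
  expect_equal(fs$per_locus$PIC, c(0.375, 0.375))
  expect_equal(fs$per_locus$Ho, c(0.5, 0.5))

  set.seed(21)
  f <- matrix(runif(8, 0.3, 0.7), 1, dimnames = list("P", NULL))
  ds2 <- simulate_genotypes(f, 40, seed = 9)
  perm <- sample(nrow(ds2$dosage))
  ds2p <- genotype_dataset(ds2$dosage[perm, ], ds2$population[perm],
                           ds2$sample_id[perm], ds2$loci)
  expect_equal(forensic_summary(ds2p)$per_locus, forensic_summary(ds2)$per_locus)
})

test_that("forensic summary agrees with a brute-force recomputation", {
  set.seed(31)
  f <- matrix(runif(12, 0.25, 0.75), 1, dimnames = list("SIM", NULL))
  ds <- simulate_genotypes(f, 120, seed = 41)
  fs <- forensic_summary(ds)
  # naive recomputation, locus by locus, plain arithmetic
  mp_all <- pe_all <- numeric(0)
  for (j in seq_along(ds$loci)) {
    g <- ds$dosage[, j]
    n <- length(g)
    cnt <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    p <- (2 * cnt[1] + cnt[2]) / (2 * n); q <- 1 - p
    ho <- cnt[2] / n
    row <- fs$per_locus[j, ]
    expect_equal(row$Ho, ho)
    expect_equal(row$He, 2 * p * q)
    expect_equal(row$MP, sum((cnt / n)^2))
    expect_equal(row$DP, 1 - sum((cnt / n)^2))
    expect_equal(row$PE, ho^2 * (1 - 2 * ho * (1 - ho)^2))
    expect_equal(row$TPI, 1 / (2 * (1 - ho)))
    expect_equal(row$PIC, 1 - p^2 - q^2 - 2 * p^2 * q^2)
    mp_all <- c(mp_all, sum((cnt / n)^2))
    pe_all <- c(pe_all, ho^2 * (1 - 2 * ho * (1 - ho)^2))
  }
  expect_equal(fs$cdp, 1 - prod(mp_all))
  expect_equal(fs$cpe, 1 - prod(1 - pe_all))
})
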