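test_that("genotype CSV parsing codes dosages and normalises DI", {
  path <- write_geno_csv(c("sample_id,population,HLD39,HLD77,HLD118",
                           "S1,KAZ,II,ID,DD",
                           "S2,KAZ,di,dd,ii"))
  ds <- read_genotype_table(path)
  expect_identical(ds$loci, c("HLD39", "HLD77", "HLD118"))
  expect_identical(unname(ds$dosage["S1", ]), c(2L, 1L, 0L))
  # DI == ID regardless of case
  expect_identical(unname(ds$dosage["S2", ]), c(1L, 0L, 2L))
  expect_identical(ds$population, c("KAZ", "KAZ"))
})

test_that("missing cells, malformed cells and duplicate ids are handled", {
  path <- write_geno_csv(c("sample_id,population,HLD39,HLD77",
                           "S1,KAZ,-,II"))
  ds <- read_genotype_table(path)
  expect_true(is.na(ds$dosage["S1", "HLD39"]))
  expect_identical(ds$dosage[["S1", "HLD77"]], 2L)

  bad <- write_geno_csv(c("sample_id,population,HLD39,HLD77",
                          "S1,KAZ,XX,II"))
  expect_error(read_genotype_table(bad), "row S1, locus HLD39")

  dup <- write_geno_csv(c("sample_id,population,HLD39",
                          "S1,KAZ,II", "S1,KAZ,DD"))
  expect_error(read_genotype_table(dup), "duplicate sample_id")
})

test_that("genotype table round-trips through CSV", {
  ds <- ds_from_counts(list(c(3, 2, 1), c(1, 1, 4)), population = "P1")
  ds$dosage[2L, 1L] <- NA
  path <- tempfile(fileext = ".csv")
  write_genotype_table(ds, path)
  back <- read_genotype_table(path)
  expect_identical(back$dosage, ds$dosage)
  expect_identical(back$population, ds$population)
})

test_that("allele frequencies follow the insertion-counting rule", {
  expect_equal(allele_frequencies(ds_from_counts(list(c(10, 0, 0))))$p_ins, 1)
  expect_equal(allele_frequencies(ds_from_counts(list(c(1, 2, 1))))$p_ins, 0.5)
  # the study-size case: (120, 271, 122) at n = 513
  ft <- allele_frequencies(ds_from_counts(list(c(120, 271, 122))))
  expect_equal(ft$p_ins, (240 + 271) / 1026)
  expect_equal(ft$n_typed, 513)
})

test_that("missing genotypes are excluded locus-wise", {
  ds <- ds_from_counts(list(c(2, 2, 0), c(2, 2, 0)))
  ds$dosage[1L, 2L] <- NA   # drops an II at locus 2 only
  ft <- allele_frequencies(ds)
  expect_equal(ft$n_typed, c(4, 3))
  expect_equal(ft$p_ins, c(6 / 8, 4 / 6))

  ds$dosage[, 2L] <- NA
  expect_error(allele_frequencies(ds), "no typed genotypes")
})

test_that("frequency tables round-trip and are validated on read", {
  ft <- freq_table(data.frame(population = "A", locus = c("L1", "L2"),
                              p_ins = c(0.123456789, 1 / 3), n_typed = 513))
  path <- tempfile(fileext = ".csv")
  write_frequency_table(ft, path)
  back <- read_frequency_table(path)
  expect_equal(back$p_ins, ft$p_ins, tolerance = 1e-9)
  expect_equal(back$n_typed, ft$n_typed)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("population,locus,p_ins,n_typed", "A,L1,1.2,10"), bad)
  expect_error(read_frequency_table(bad), "p_ins")

  empty <- tempfile(fileext = ".csv")
  writeLines("population,locus,p_ins,n_typed", empty)
  expect_error(read_frequency_table(empty), "no records")
})

test_that("frequencies are invariant to sample order and pool consistently", {
  set.seed(11)
  f <- matrix(runif(2 * 10, 0.2, 0.8), 2, dimnames = list(c("A", "B"), NULL))
  ds <- simulate_genotypes(f, c(30, 50), seed = 5)
  perm <- sample(nrow(ds$dosage))
  ds_p <- genotype_dataset(ds$dosage[perm, ], ds$population[perm],
                           ds$sample_id[perm], ds$loci)
  expect_equal(allele_frequencies(ds_p, "A"), allele_frequencies(ds, "A"))

  # pooled frequency equals the n-weighted average of per-population counts
  pooled <- genotype_dataset(ds$dosage, rep("ALL", nrow(ds$dosage)),
                             ds$sample_id, ds$loci)
  ft <- allele_frequencies(ds)
  by_pop <- split(ft, ft$population)
  wavg <- Reduce(`+`, lapply(by_pop, function(x) x$p_ins * x$n_typed)) /
    Reduce(`+`, lapply(by_pop, function(x) x$n_typed))
  expect_equal(allele_frequencies(pooled)$p_ins, wavg)
})

test_that("STRUCTURE export writes two allele rows per individual", {
  ds <- ds_from_counts(list(c(1, 1, 0), c(0, 0, 2)))
  ds$dosage[1L, 2L] <- NA
  path <- tempfile()
  write_structure_file(ds, path)
  lines <- readLines(path)
  expect_length(lines, 2L * nrow(ds$dosage))
  f1 <- strsplit(lines[1L], " ")[[1L]]
  f2 <- strsplit(lines[2L], " ")[[1L]]
  # first sample is II at locus 1 (alleles 1/1), missing at locus 2 (-9/-9)
  expect_identical(f1[3:4], c("1", "-9"))
  expect_identical(f2[3:4], c("1", "-9"))
})
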