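#' Genotype dataset for a biallelic InDel panel
#'
#' Container for diploid genotypes at biallelic insertion/deletion loci.
#' Genotypes are stored as the dosage of the Insertion allele (0 = DD,
#' 1 = ID, 2 = II), with `NA` marking missing genotypes. The deletion allele
#' is always implicit: its dosage is `2 - dosage`.
#'
#' @param dosage integer matrix, samples in rows and loci in columns; entries
#'   in `{0, 1, 2}` or `NA` for missing.
#' @param population character vector of population labels, one per sample.
#' @param sample_id unique sample identifiers; defaults to the row names of
#'   `dosage`.
#' @param loci locus names; defaults to the column names of `dosage`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `sample_id`, `population`, `loci` and the integer `dosage` matrix
#'   (missingness is `is.na(dosage)`).
#' @examples
#' g <- matrix(c(2L, 1L, 0L, 1L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("HLD6", "HLD39")))
#' ds <- genotype_dataset(g, population = c("KAZ", "KAZ"))
#' ds
#' @export
genotype_dataset <- function(dosage, population, sample_id = rownames(dosage),
                             loci = colnames(dosage)) {
  if (!is.matrix(dosage)) stop("'dosage' must be a matrix")
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  if (n < 1L) stop("dataset must contain at least one sample")
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(dosage)))
  sample_id <- as.character(sample_id)
  loci <- as.character(loci)
  population <- as.character(population)
  if (length(sample_id) != n || length(population) != n)
    stop("'sample_id' and 'population' must have one entry per dosage row")
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (anyDuplicated(loci))
    stop("duplicate locus names: ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "))
  if (length(loci) != ncol(dosage))
    stop("'loci' must have one entry per dosage column")
  if (anyNA(population) || any(!nzchar(population)))
    stop("every sample must carry a non-empty population label")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(sample_id, loci)
  structure(
    list(sample_id = sample_id, population = population,
         loci = loci, dosage = dosage),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d samples x %d loci, %d population(s)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$population))))
  miss <- sum(is.na(x$dosage))
  cat(sprintf("  populations: %s\n",
              paste(utils::head(sort(unique(x$population)), 8L), collapse = ", ")))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", miss,
              100 * miss / length(x$dosage)))
  invisible(x)
}

#' Population labels present in a dataset
#' @param ds a `genotype_dataset`.
#' @return Character vector of unique population labels, in first-appearance
#'   order.
#' @export
populations <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  unique(ds$population)
}

#' Restrict a dataset to one or more populations
#' @param ds a `genotype_dataset`.
#' @param population character vector of labels to keep.
#' @return A `genotype_dataset` containing only the matching samples, row
#'   order preserved.
#' @export
subset_population <- function(ds, population) {
  stopifnot(inherits(ds, "genotype_dataset"))
  missing_pops <- setdiff(population, ds$population)
  if (length(missing_pops))
    stop("population(s) not in dataset: ", paste(missing_pops, collapse = ", "))
  keep <- ds$population %in% population
  genotype_dataset(ds$dosage[keep, , drop = FALSE],
                   population = ds$population[keep],
                   sample_id = ds$sample_id[keep],
                   loci = ds$loci)
}

# genotype string <-> insertion dosage coding
.geno_codes <- c(II = 2L, ID = 1L, DI = 1L, DD = 0L)

#' Read a genotype table from CSV
#'
#' Reads the package's genotype CSV dialect: a header row
#' `sample_id,population,<locus>,...`, then one row per sample with genotype
#' cells `II`, `ID`, `DI` (normalised to `ID`), `DD`, or `-` for missing.
#' Genotype strings are case-insensitive.
#'
#' @param path path to a CSV file.
#' @return A [genotype_dataset()].
#' @seealso [write_genotype_table()]
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (nrow(raw) == 0L) stop("no records in ", path)
  hdr <- tolower(names(raw))
  if (length(hdr) < 3L || hdr[1L] != "sample_id" || hdr[2L] != "population")
    stop("header must start with 'sample_id,population' followed by locus columns")
  loci <- names(raw)[-(1:2)]
  sample_id <- raw[[1L]]
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  cells <- toupper(as.matrix(raw[, -(1:2), drop = FALSE]))
  dosage <- matrix(NA_integer_, nrow(cells), ncol(cells))
  known <- cells %in% names(.geno_codes)
  missing_cell <- cells == "-" | cells == ""
  bad <- which(!known & !missing_cell, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed genotype '%s' at row %s, locus %s",
                 cells[bad[1L, , drop = FALSE]],
                 sample_id[bad[1L, 1L]], loci[bad[1L, 2L]]))
  }
  dosage[known] <- .geno_codes[cells[known]]
  genotype_dataset(dosage, population = raw[[2L]],
                   sample_id = sample_id, loci = loci)
}

#' Write a genotype table as CSV
#' @param ds a `genotype_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  strs <- c("DD", "ID", "II")[ds$dosage + 1L]
  strs[is.na(strs)] <- "-"
  m <- matrix(strs, nrow = nrow(ds$dosage),
              dimnames = list(NULL, ds$loci))
  out <- data.frame(sample_id = ds$sample_id, population = ds$population,
                    m, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export genotypes in a STRUCTURE-style two-row format
#'
#' Writes one header-free line pair per individual: `sample_id population`
#' followed by one allele per locus, coded 1 for Insertion, 2 for Deletion
#' and -9 for missing.
#'
#' @param ds a `genotype_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(ds, path) {
  stopifnot(inherits(ds, "genotype_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ds$sample_id)) {
    g <- ds$dosage[i, ]
    a1 <- ifelse(is.na(g), -9L, ifelse(g >= 1L, 1L, 2L))
    a2 <- ifelse(is.na(g), -9L, ifelse(g == 2L, 1L, 2L))
    writeLines(c(paste(c(ds$sample_id[i], ds$population[i], a1), collapse = " "),
                 paste(c(ds$sample_id[i], ds$population[i], a2), collapse = " ")),
               con)
  }
  invisible(path)
}
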