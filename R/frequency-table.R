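#' Per-population insertion-allele frequency table
#'
#' A `freq_table` is a data frame with columns `population`, `locus`,
#' `p_ins` (insertion-allele frequency) and `n_typed` (diploid individuals
#' typed at that locus, i.e. `2 * n_typed` alleles). Because the loci are
#' biallelic the deletion frequency is always `1 - p_ins` and is never
#' stored. A table may hold one population or a panel of several.
#'
#' @param df data frame with the four columns above.
#' @return The validated data frame with class `freq_table`.
#' @export
freq_table <- function(df) {
  need <- c("population", "locus", "p_ins", "n_typed")
  if (!all(need %in% names(df)))
    stop("freq_table needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$population <- as.character(df$population)
  df$locus <- as.character(df$locus)
  df$p_ins <- as.numeric(df$p_ins)
  df$n_typed <- as.numeric(df$n_typed)
  if (nrow(df) == 0L) stop("no records")
  if (anyNA(df$p_ins) || any(df$p_ins < 0 | df$p_ins > 1))
    stop("p_ins must lie in [0, 1]")
  if (anyNA(df$n_typed) || any(df$n_typed < 1))
    stop("n_typed must be >= 1")
  if (anyDuplicated(df[c("population", "locus")]))
    stop("duplicated (population, locus) rows")
  class(df) <- c("freq_table", "data.frame")
  df
}

#' Insertion-allele frequencies from genotype counts
#'
#' Computes per-locus insertion-allele frequencies
#' `p_ins = (2 n_II + n_ID) / (2 n_typed)` for one population or every
#' population in the dataset. Missing genotypes are excluded locus-wise
#' (complete-case per locus), so `n_typed` can differ between loci.
#'
#' @param ds a [genotype_dataset()].
#' @param population a single population label, or `NULL` (default) for all
#'   populations in the dataset.
#' @return A [freq_table()].
#' @examples
#' ds <- genotype_dataset(matrix(c(2L, 1L, 1L, 0L), 2, 2), c("A", "A"))
#' allele_frequencies(ds)
#' @export
allele_frequencies <- function(ds, population = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  pops <- population %||% populations(ds)
  missing_pops <- setdiff(pops, ds$population)
  if (length(missing_pops))
    stop("population(s) not in dataset: ", paste(missing_pops, collapse = ", "))
  res <- lapply(pops, function(p) {
    g <- ds$dosage[ds$population == p, , drop = FALSE]
    n_typed <- colSums(!is.na(g))
    if (any(n_typed == 0L))
      stop("locus with no typed genotypes in population ", p, ": ",
           paste(ds$loci[n_typed == 0L], collapse = ", "))
    data.frame(population = p, locus = ds$loci,
               p_ins = colSums(g, na.rm = TRUE) / (2 * n_typed),
               n_typed = as.numeric(n_typed),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  freq_table(do.call(rbind, res))
}

#' @rdname freq_table
#' @param ft a `freq_table`.
#' @param path CSV path.
#' @export
write_frequency_table <- function(ft, path) {
  ft <- freq_table(ft)
  out <- ft
  # full double precision so the round trip is lossless well past 6 decimals
  out$p_ins <- sprintf("%.12g", out$p_ins)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname freq_table
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path)
  freq_table(df)
}

# wide population x locus matrix of p_ins, common locus order enforced
freq_matrix <- function(ft) {
  ft <- freq_table(ft)
  pops <- unique(ft$population)
  loci <- unique(ft$locus)
  m <- matrix(NA_real_, length(pops), length(loci),
              dimnames = list(pops, loci))
  m[cbind(match(ft$population, pops), match(ft$locus, loci))] <- ft$p_ins
  if (anyNA(m))
    stop("populations do not share a common locus set")
  m
}
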