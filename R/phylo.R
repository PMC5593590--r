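#' Nei's DA genetic distance between two populations
#'
#' For biallelic loci with insertion frequencies `p_a`, `p_b`:
#' `DA = 1 - mean over loci of [sqrt(p_a p_b) + sqrt((1 - p_a)(1 - p_b))]`.
#' Zero for identical frequency vectors, 1 when every locus is fixed for
#' opposite alleles.
#'
#' @param freq_a,freq_b insertion-frequency vectors over the same ordered
#'   locus set, or single-population [freq_table()]s (matched by locus
#'   name).
#' @return The DA distance in `[0, 1]`.
#' @export
nei_da <- function(freq_a, freq_b) {
  v <- align_freq_pair(freq_a, freq_b)
  1 - mean(sqrt(v$a * v$b) + sqrt((1 - v$a) * (1 - v$b)))
}

#' Nei's standard genetic distance
#'
#' `D = -log(Jab / sqrt(Ja * Jb))` with `J` the locus-averaged sums of
#' squared (or cross-product) allele frequencies. Offered as the
#' alternative metric for frequency-based trees.
#'
#' @inheritParams nei_da
#' @return Nei's standard distance (non-negative, unbounded).
#' @export
nei_standard <- function(freq_a, freq_b) {
  v <- align_freq_pair(freq_a, freq_b)
  jab <- mean(v$a * v$b + (1 - v$a) * (1 - v$b))
  ja <- mean(v$a^2 + (1 - v$a)^2)
  jb <- mean(v$b^2 + (1 - v$b)^2)
  if (jab <= 0) stop("undefined: no shared alleles anywhere")
  -log(jab / sqrt(ja * jb))
}

align_freq_pair <- function(freq_a, freq_b) {
  as_vec <- function(x) {
    if (inherits(x, "freq_table") || is.data.frame(x)) {
      x <- freq_table(x)
      if (length(unique(x$population)) != 1L)
        stop("frequency table must hold exactly one population")
      stats::setNames(x$p_ins, x$locus)
    } else stats::setNames(as.numeric(x), names(x))
  }
  a <- as_vec(freq_a); b <- as_vec(freq_b)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("locus sets differ between the two populations")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("frequency vectors must cover the same loci")
  }
  if (any(a < 0 | a > 1) || any(b < 0 | b > 1))
    stop("frequencies must lie in [0, 1]")
  list(a = unname(a), b = unname(b))
}

#' Pairwise genetic distance matrix over a frequency panel
#'
#' @param ft a [freq_table()] holding two or more populations over a common
#'   locus set.
#' @param metric `"da"` (default) or `"nei"` (Nei standard distance).
#' @return Symmetric labelled matrix with zero diagonal.
#' @export
da_matrix <- function(ft, metric = c("da", "nei")) {
  metric <- match.arg(metric)
  fm <- freq_matrix(ft)
  if (nrow(fm) < 2L) stop("at least two populations are required")
  fun <- if (metric == "da") nei_da else nei_standard
  pops <- rownames(fm)
  m <- matrix(0, nrow(fm), nrow(fm), dimnames = list(pops, pops))
  for (a in seq_len(nrow(fm) - 1L)) for (b in (a + 1L):nrow(fm)) {
    m[a, b] <- m[b, a] <- fun(fm[a, ], fm[b, ])
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q-criterion with the standard
#' branch-length formulas. On an additive distance matrix the generating
#' topology and branch lengths are recovered exactly. Ties in the Q
#' minimisation are broken deterministically by the lowest (row, column)
#' index pair of the working matrix (merged nodes are appended last), so
#' output is bit-reproducible. Negative branch lengths, which NJ can
#' produce, are retained.
#'
#' @param dm symmetric numeric matrix with zero diagonal and non-negative
#'   entries; labels from `rownames`.
#' @return An unrooted `ape::phylo` tree with a trifurcating root node.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("at least three taxa are required")
  if (ncol(dm) != n || max(abs(dm - t(dm))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(dm < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(dm)) > 1e-12)) stop("diagonal must be zero")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  # each active node carries its Newick fragment (no outer branch length)
  frag <- labels
  D <- dm
  fmt <- function(x) sprintf("%.17g", x)
  while (length(frag) > 3L) {
    r <- length(frag)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest (row, col) pair among minima, scanning i < j row-major
    best <- c(NA_integer_, NA_integer_); qmin <- Inf
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      if (Q[i, j] < qmin) { qmin <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    d_new <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new[keep]),
               c(d_new[keep], 0))
    frag <- c(frag[keep], new_frag)
  }
  # final trifurcation
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(x1), frag[2], fmt(x2), frag[3], fmt(x3))
  # negative branch lengths are documented NJ output, no need to re-warn
  suppressWarnings(from_newick(nwk))
}

#' Newick serialisation
#'
#' Thin wrappers over `ape` with the package's error policy: malformed
#' strings raise an error, and negative branch lengths (legitimate NJ
#' output) are accepted with a warning on parse.
#'
#' @param tree an `ape::phylo` object.
#' @param path optional file path; if `NULL`, `to_newick()` returns the
#'   string.
#' @param text a Newick string (or use `path` to read a file).
#' @return `to_newick()`: the Newick string (invisibly, when written to a
#'   file); `from_newick()`: an `ape::phylo`.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' @rdname to_newick
#' @export
from_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path))
    stop("supply exactly one of 'text' or 'path'")
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    pos <- NA_integer_
    if (!is.null(text)) {
      # locate the first structural defect: unbalanced depth or a bad char
      chars <- strsplit(text, "")[[1L]]
      depth <- cumsum((chars == "(") - (chars == ")"))
      if (any(depth < 0)) pos <- which(depth < 0)[1L]
      else if (utils::tail(depth, 1L) != 0) pos <- length(chars)
      else {
        bad <- regexpr("[^(),:;a-zA-Z0-9._' -]", text)
        if (bad > 0) pos <- as.integer(bad)
      }
    }
    stop("malformed Newick string",
         if (!is.na(pos)) paste0(" near character ", pos) else "")
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    warning("tree contains negative branch lengths")
  tr
}

#' Distance-based population tree from a frequency panel
#'
#' Convenience composition: pairwise genetic distances ([da_matrix()], DA
#' by default or Nei standard) followed by neighbor-joining.
#'
#' @inheritParams da_matrix
#' @return An `ape::phylo` tree with one leaf per population.
#' @export
frequency_tree <- function(ft, metric = c("da", "nei")) {
  neighbor_joining(da_matrix(ft, metric = match.arg(metric)))
}

#' Write a distance matrix as square CSV or PHYLIP lower-triangle text
#'
#' @param dm symmetric labelled matrix.
#' @param path output path.
#' @param format `"csv"` (square, labelled) or `"phylip"` (lower triangle).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  dm <- as.matrix(dm)
  if (format == "csv") {
    utils::write.csv(dm, path, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm)), con)
    for (i in seq_len(nrow(dm))) {
      writeLines(paste(c(sprintf("%-10s", rownames(dm)[i]),
                         sprintf("%.6f", dm[i, seq_len(i - 1)])),
                       collapse = " "), con)
    }
  }
  invisible(path)
}
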