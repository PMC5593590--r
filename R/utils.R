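# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`, then
#' restores the previous RNG state, so seeded package functions never disturb
#' the caller's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from one root seed, so pipeline stages
# can be rerun independently. Kept below 2^31 - 1.
substream_seed <- function(root_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 104729
  as.integer((as.numeric(root_seed) %% 2147483647 * 7919 + h) %% 2147483647)
}

# round-half-up at `digits` decimals (matches forensic spreadsheet reporting;
# base round() is round-half-even)
round_half_up <- function(x, digits = 4L) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}
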