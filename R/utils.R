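#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive per-run seeds from a master seed
#'
#' Deterministic counter scheme: run `k` gets a seed drawn from the stream
#' seeded by the master seed, so ensembles are reproducible and individual
#' runs can be replayed in isolation.
#'
#' @param master_seed integer master seed.
#' @param n number of seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Rand index between two partitions
#'
#' Pair-counting Rand index: the fraction of node pairs on which two
#' partitions agree (both together or both apart). 1 means identical
#' partitions up to relabeling.
#'
#' @param g1,g2 label vectors (or matrices, compared as flattened
#'   supra-node partitions) of equal length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(g1, g2) {
  g1 <- as.vector(g1); g2 <- as.vector(g2)
  stopifnot(length(g1) == length(g2), length(g1) >= 2)
  n <- length(g1)
  tab <- table(g1, g2)
  s <- function(x) sum(choose(x, 2))
  a <- s(tab)                       # together in both
  m1 <- s(rowSums(tab)); m2 <- s(colSums(tab))
  total <- choose(n, 2)
  d <- total - m1 - m2 + a          # apart in both
  (a + d) / total
}

# internal: stop with a classed validation error (CLI maps these to exit 2)
fc_stop <- function(msg, class = "funcarto_validation_error") {
  stop(errorCondition(msg, class = c(class, "funcarto_error")))
}

# internal: check a square numeric matrix is symmetric within tol
check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    fc_stop(sprintf("%s is not square (%d x %d)", what, nrow(m), ncol(m)))
  asym <- max(abs(m - t(m)))
  if (asym > tol)
    fc_stop(sprintf("%s is not symmetric (max asymmetry %.3g > tol %.3g)",
                    what, asym, tol))
  invisible(asym)
}
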