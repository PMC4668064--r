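# (gamma, omega) grid search with flexibility-variability selection and
# z-Rand partition-similarity diagnostics.

#' z-score of the Rand coefficient between two partitions
#'
#' Standardizes the pair-counting Rand statistic under the hypergeometric
#' null that fixes both partitions' group sizes: with \eqn{M} node pairs,
#' \eqn{M_1}/\eqn{M_2} pairs co-grouped in each partition and \eqn{w}
#' pairs co-grouped in both, \eqn{z = (w - M_1 M_2 / M)/\sigma_w}.
#' Larger values mean more similar partitions; independent random
#' partitions score about 0. Degenerate comparisons with zero null
#' variance (e.g. all-singletons vs all-singletons) are reported as 0
#' with a `"degenerate"` attribute.
#'
#' @param g1,g2 label vectors over the same node set.
#' @return scalar z-score.
#' @export
zrand_similarity <- function(g1, g2) {
  g1 <- as.vector(g1); g2 <- as.vector(g2)
  stopifnot(length(g1) == length(g2))
  n <- length(g1)
  if (n < 4) fc_stop("z-Rand needs at least 4 nodes")
  tab <- table(g1, g2)
  nc1 <- rowSums(tab); nc2 <- colSums(tab)
  M <- n * (n - 1) / 2
  M1 <- sum(choose(nc1, 2)); M2 <- sum(choose(nc2, 2))
  w <- sum(choose(tab, 2))
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(nc1^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(nc2^3)
  a1 <- 4 * M1 - 2 * M; a2 <- 4 * M2 - 2 * M
  vw <- M / 16 - a1^2 * a2^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    (a1^2 - 4 * C1 - 4 * M) * (a2^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (vw <= 0) {
    z <- 0
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  (w - M1 * M2 / M) / sqrt(vw)
}

# internal: mean pairwise z-Rand between runs (flattened supra-node
# partitions) and, within runs, between slices.
ensemble_similarity <- function(ensemble) {
  parts <- ensemble$partitions
  O <- length(parts)
  across_runs <- NA_real_
  if (O >= 2) {
    pairs <- utils::combn(O, 2)
    across_runs <- mean(apply(pairs, 2, function(p)
      zrand_similarity(parts[[p[1]]]$labels, parts[[p[2]]]$labels)))
  }
  Tn <- ncol(parts[[1]]$labels)
  across_slices <- NA_real_
  if (Tn >= 2) {
    spairs <- utils::combn(Tn, 2)
    across_slices <- mean(vapply(parts, function(p)
      mean(apply(spairs, 2, function(q)
        zrand_similarity(p$labels[, q[1]], p$labels[, q[2]]))),
      numeric(1)))
  }
  list(across_runs = across_runs, across_slices = across_slices)
}

#' Grid search over resolution and coupling parameters
#'
#' Runs a partition ensemble at every (gamma, omega) grid point and
#' records, per point: mean and standard deviation (across nodes) of the
#' ensemble-averaged flexibility, mean pairwise z-Rand partition
#' similarity across runs and across slices, mean community count and
#' mean quality. Deterministic given `seed` (every grid point uses the
#' same master seed, so points differ only through the parameters).
#'
#' @param net a `multilayer_network` (its stored gamma/omega are
#'   overridden pointwise).
#' @param gamma_grid,omega_grid numeric vectors of grid values.
#' @param n_runs optimizations per grid point (default 20).
#' @param seed master seed.
#' @return data.frame with one row per grid point: `gamma`, `omega`,
#'   `flex_mean`, `flex_std`, `sim_across_runs`, `sim_across_slices`,
#'   `n_communities`, `quality`.
#' @export
grid_search <- function(net, gamma_grid, omega_grid, n_runs = 20, seed = 1) {
  stopifnot(inherits(net, "multilayer_network"),
            length(gamma_grid) >= 1, length(omega_grid) >= 1)
  grid <- expand.grid(gamma = gamma_grid, omega = omega_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net$gamma <- rep(grid$gamma[i], n_slices(net))
    net$omega <- grid$omega[i]
    ens <- run_ensemble(net, n_runs = n_runs, seed = seed)
    fl <- flexibility(ens)
    sim <- ensemble_similarity(ens)
    ncomm <- mean(vapply(ens$partitions, function(p)
      length(unique(as.vector(p$labels))), numeric(1)))
    data.frame(gamma = grid$gamma[i], omega = grid$omega[i],
               flex_mean = mean(fl$f), flex_std = stats::sd(fl$f),
               sim_across_runs = sim$across_runs,
               sim_across_slices = sim$across_slices,
               n_communities = ncomm, quality = mean(ens$qualities))
  })
  do.call(rbind, rows)
}

#' Select operating parameters from grid-search results
#'
#' Primary criterion: maximize the standard deviation of the flexibility
#' coefficient across nodes (the point where regions differ most between
#' highly flexible and highly stable). Among candidates within
#' `tie_tol` (relative) of the maximum, prefers higher partition
#' similarity across runs, then lower similarity across slices.
#' Permutation-invariant in the row order of `results`.
#'
#' @param results data.frame from [grid_search()].
#' @param tie_tol relative tolerance defining the tie set (default 0.01).
#' @return one-row data.frame: the selected grid point.
#' @export
select_parameters <- function(results, tie_tol = 0.01) {
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  best <- max(results$flex_std, na.rm = TRUE)
  cand <- results[!is.na(results$flex_std) &
                    results$flex_std >= best * (1 - tie_tol), , drop = FALSE]
  if (nrow(cand) > 1) {
    o <- order(-replace(cand$sim_across_runs, is.na(cand$sim_across_runs),
                        -Inf),
               replace(cand$sim_across_slices, is.na(cand$sim_across_slices),
                       Inf),
               cand$gamma, cand$omega)
    cand <- cand[o, , drop = FALSE]
  }
  cand[1, , drop = FALSE]
}
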