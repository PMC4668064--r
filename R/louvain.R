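# Generalized Louvain maximization of categorical multislice modularity.
#
# The quality function is linear in co-assignment indicators, so the whole
# multilayer problem reduces to ordinary Louvain on the dense supra-
# modularity matrix B (intraslice A - gamma*V blocks plus omega coupling
# entries). Aggregation sums B over community blocks, which automatically
# carries every super-node's interslice coupling contributions.

# internal: one Louvain level on a symmetric modularity-like matrix B.
# Starts from singletons; sweeps nodes in a freshly shuffled order, moving
# each to the community with maximal positive gain (ties broken by lowest
# community index); repeats sweeps until no move improves Q by more than
# tol. Returns integer community labels.
louvain_one_level <- function(B, twomu, tol = 1e-10) {
  n <- nrow(B)
  comm <- seq_len(n)
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      bi <- B[, i]
      w <- rowsum(bi, comm)                 # community -> sum of B[i, .]
      cur <- comm[i]
      w[as.character(cur), 1] <- w[as.character(cur), 1] - B[i, i]
      best_gain <- -Inf; best <- cur
      wv <- w[, 1]
      ids <- as.integer(rownames(w))
      wcur <- wv[ids == cur]
      gains <- 2 * (wv - wcur) / twomu
      top <- max(gains)
      cand <- ids[gains >= top - 1e-15]
      best <- min(cand)
      if (best != cur && top > tol) {
        comm[i] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  comm
}

# internal: aggregate B over communities (sum of blocks); returns list with
# the reduced matrix and the mapping old-community-id -> new index.
aggregate_B <- function(B, comm) {
  f <- factor(comm)
  Bc <- rowsum(t(rowsum(B, f)), f)     # levels(f) order on both axes
  list(B = as.matrix(Bc), levels = as.integer(levels(f)))
}

#' Single generalized Louvain optimization
#'
#' One seeded run of the two-phase Louvain heuristic on the multislice
#' quality function: phase 1 moves supra-nodes (node, slice) greedily
#' between communities; phase 2 aggregates communities into super-nodes
#' (summing intra- and inter-community weights, coupling included) and
#' recurses. Deterministic given `seed`.
#'
#' @param net a `multilayer_network`.
#' @param seed integer seed controlling the node visitation order.
#' @param tol minimum quality gain for a move (absolute).
#' @return list with `partition` (canonical labels, N x T) and `quality`.
#' @export
louvain_once <- function(net, seed, tol = 1e-10) {
  stopifnot(inherits(net, "multilayer_network"))
  N <- n_nodes(net); Tn <- n_slices(net)
  B <- supra_modularity_matrix(net)
  twomu <- 2 * quality_context(net)$mu
  debug <- isTRUE(getOption("funcarto.debug"))
  flat <- seq_len(N * Tn)      # supra-node -> current top-level community
  with_seed(seed, {
    Bcur <- B
    q_prev <- -Inf
    repeat {
      comm <- louvain_one_level(Bcur, twomu, tol)
      if (all(comm == seq_len(nrow(Bcur)))) break   # no merges: converged
      agg <- aggregate_B(Bcur, comm)
      flat <- match(comm[flat], agg$levels)
      if (debug) {
        q_now <- sum(B[outer(flat, flat, "==")]) / twomu
        stopifnot(q_now >= q_prev - 1e-12)
        q_prev <- q_now
      }
      if (nrow(agg$B) == nrow(Bcur)) break
      Bcur <- agg$B
    }
  })
  labels <- matrix(flat, nrow = N, ncol = Tn,
                   dimnames = list(net$node_ids, net$slice_ids))
  part <- canonicalize_partition(partition(labels))
  q <- sum(B[outer(flat, flat, "==")]) / twomu
  list(partition = part, quality = q)
}

#' Ensemble of independent Louvain optimizations
#'
#' Runs `n_runs` independent seeded optimizations (per-run seeds derived
#' deterministically from the master seed) and retains every partition:
#' the module allegiance matrix consumes the full ensemble, so no
#' consensus collapse is performed.
#'
#' @param net a `multilayer_network`.
#' @param n_runs number of optimizations (default 100).
#' @param seed master seed.
#' @return object of class `partition_ensemble`: list with `partitions`,
#'   `qualities`, `seeds` and `params` (gamma, omega).
#' @export
run_ensemble <- function(net, n_runs = 100, seed = 1) {
  stopifnot(n_runs >= 1)
  seeds <- derive_seeds(seed, n_runs)
  runs <- lapply(seeds, function(s) louvain_once(net, s))
  structure(
    list(partitions = lapply(runs, `[[`, "partition"),
         qualities = vapply(runs, `[[`, numeric(1), "quality"),
         seeds = seeds,
         params = list(gamma = net$gamma, omega = net$omega)),
    class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf(
    "partition_ensemble: %d runs, %d nodes x %d slices, Q in [%.4f, %.4f]\n",
    length(x$partitions), nrow(x$partitions[[1]]$labels),
    ncol(x$partitions[[1]]$labels), min(x$qualities), max(x$qualities)))
  invisible(x)
}
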