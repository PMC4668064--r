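# Module allegiance, recruitment/integration coefficients, permutation
# null model and the nine-role functional cartography.

#' Construct a system map
#'
#' Assigns every node to exactly one named system (a node-set such as a
#' resting-state cognitive system). Systems are ordered by first
#' appearance in the input.
#'
#' @param assignment named character vector or factor: `names()` are node
#'   ids, values are system labels. An unnamed vector is accepted when
#'   `node_ids` is given.
#' @param node_ids optional node ids (required if `assignment` unnamed).
#' @return object of class `system_map` with elements `assignment` (named
#'   character), `systems` (labels in first-appearance order), `sizes`,
#'   and `n` (total node count).
#' @export
system_map <- function(assignment, node_ids = NULL) {
  assignment <- as.character(assignment) |> stats::setNames(
    if (!is.null(node_ids)) node_ids else names(assignment))
  if (is.null(names(assignment)) || anyNA(names(assignment)))
    fc_stop("system_map needs node ids (names or 'node_ids')")
  if (anyDuplicated(names(assignment)))
    fc_stop(sprintf("duplicate node ids in system map: %s",
                    paste(unique(names(assignment)[duplicated(names(assignment))]),
                          collapse = ", ")))
  if (anyNA(assignment) || any(assignment == ""))
    fc_stop("every node must be assigned to a system")
  systems <- unique(assignment)
  sizes <- stats::setNames(as.integer(table(factor(assignment, systems))),
                           systems)
  if (any(sizes == 0)) fc_stop("empty system in system map")
  structure(list(assignment = assignment, systems = systems,
                 sizes = sizes, n = length(assignment)),
            class = "system_map")
}

#' @export
print.system_map <- function(x, ...) {
  cat(sprintf("system_map: %d nodes in %d systems (%s)\n", x$n,
              length(x$systems),
              paste(sprintf("%s:%d", x$systems, x$sizes), collapse = ", ")))
  invisible(x)
}

#' Module allegiance matrix of a partition ensemble
#'
#' \eqn{P_{ij}} is the fraction of (optimization, slice) pairs in which
#' nodes i and j are assigned to the same community:
#' \eqn{P_{ij} = \frac{1}{OT} \sum_{o=1}^{O} \sum_{t=1}^{T}
#' [g_{it}^{(o)} = g_{jt}^{(o)}]}. Symmetric, entries in \[0, 1\],
#' diagonal exactly 1.
#'
#' @param ensemble a `partition_ensemble`, or a single `partition`
#'   (treated as an ensemble of one).
#' @return object of class `allegiance_matrix`: list with `P`,
#'   `n_optimizations`, `n_slices`.
#' @export
module_allegiance <- function(ensemble) {
  if (inherits(ensemble, "partition"))
    ensemble <- structure(list(partitions = list(ensemble)),
                          class = "partition_ensemble")
  stopifnot(inherits(ensemble, "partition_ensemble"),
            length(ensemble$partitions) >= 1)
  labels1 <- ensemble$partitions[[1]]$labels
  N <- nrow(labels1); Tn <- ncol(labels1)
  P <- matrix(0, N, N)
  for (p in ensemble$partitions) {
    lab <- p$labels
    for (t in seq_len(Tn)) {
      g <- lab[, t]
      P <- P + (outer(g, g, "==") * 1)
    }
  }
  P <- P / (length(ensemble$partitions) * Tn)
  dimnames(P) <- list(rownames(labels1), rownames(labels1))
  structure(list(P = P, n_optimizations = length(ensemble$partitions),
                 n_slices = Tn),
            class = "allegiance_matrix")
}

#' @export
print.allegiance_matrix <- function(x, ...) {
  cat(sprintf(
    "allegiance_matrix: %d nodes (O = %d optimizations, T = %d slices)\n",
    nrow(x$P), x$n_optimizations, x$n_slices))
  invisible(x)
}

# internal: extract the P matrix, aligned to a system map if provided
allegiance_P <- function(P, systems = NULL) {
  if (inherits(P, "allegiance_matrix")) P <- P$P
  P <- as.matrix(P)
  if (!is.null(systems)) {
    if (nrow(P) != systems$n)
      fc_stop(sprintf("allegiance matrix has %d nodes, system map has %d",
                      nrow(P), systems$n))
    if (!is.null(rownames(P))) {
      if (!setequal(rownames(P), names(systems$assignment)))
        fc_stop("node ids of allegiance matrix and system map differ")
      P <- P[names(systems$assignment), names(systems$assignment)]
    }
  }
  P
}

#' Region-level recruitment and integration coefficients
#'
#' For each region i belonging to system S:
#' recruitment \eqn{R_i^S = \frac{1}{n_S}\sum_{j \in S} P_{ij}} (the self
#' term \eqn{P_{ii} = 1} is included, as the summation range is written)
#' and integration \eqn{I_i^S = \frac{1}{N - n_S}\sum_{j \notin S} P_{ij}}.
#'
#' @param P an `allegiance_matrix` (or bare matrix).
#' @param systems a `system_map` covering all nodes of `P`.
#' @param include_self include the diagonal term in recruitment (default
#'   `TRUE`, the literal formula); `FALSE` averages over the
#'   \eqn{n_S - 1} other members.
#' @return data.frame with columns `node`, `system`, `recruitment`,
#'   `integration`.
#' @export
region_coefficients <- function(P, systems, include_self = TRUE) {
  P <- allegiance_P(P, systems)
  N <- nrow(P)
  sys <- factor(systems$assignment, systems$systems)
  if (nlevels(sys) < 2)
    fc_stop("integration is undefined with a single system")
  nS <- systems$sizes[as.character(sys)]
  S_sum <- t(rowsum(t(P), sys))            # N x systems: row sums by system
  own <- S_sum[cbind(seq_len(N), as.integer(sys))]
  if (include_self) {
    R <- own / nS
  } else {
    if (any(nS == 1))
      fc_stop("include_self = FALSE requires every system size > 1")
    R <- (own - diag(P)) / (nS - 1)
  }
  I <- (rowSums(P) - own) / (N - nS)
  data.frame(node = names(systems$assignment),
             system = as.character(sys),
             recruitment = unname(R), integration = unname(I),
             stringsAsFactors = FALSE)
}

#' System-level recruitment and integration coefficients
#'
#' System recruitment \eqn{R_S = \frac{1}{n_S^2} \sum_{i,j \in S} P_{ij}},
#' pairwise integration \eqn{I_{S_k S_l} = \frac{1}{n_{S_k} n_{S_l}}
#' \sum_{i \in S_k} \sum_{j \in S_l} P_{ij}} for \eqn{k \ne l}, and total
#' integration \eqn{I_S = \frac{1}{n_S (N - n_S)} \sum_{i \in S}
#' \sum_{j \notin S} P_{ij}} (the size-weighted average of the pairwise
#' integrations).
#'
#' @inheritParams region_coefficients
#' @return list with `recruitment` (named vector \eqn{R_S}),
#'   `pairwise_integration` (symmetric systems x systems matrix, diagonal
#'   `NA`), and `integration` (named vector \eqn{I_S}).
#' @export
system_coefficients <- function(P, systems) {
  P <- allegiance_P(P, systems)
  sys <- factor(systems$assignment, systems$systems)
  if (nlevels(sys) < 2) fc_stop("at least 2 systems required")
  block <- rowsum(t(rowsum(P, sys)), sys)   # systems x systems block sums
  block <- as.matrix(block)[systems$systems, systems$systems]
  nS <- systems$sizes
  R_S <- diag(block) / nS^2
  Ipair <- block / outer(nS, nS)
  diag(Ipair) <- NA_real_
  N <- systems$n
  I_S <- (rowSums(block) - diag(block)) / (nS * (N - nS))
  list(recruitment = R_S, pairwise_integration = Ipair, integration = I_S)
}

#' Permutation null model for system coefficients
#'
#' Repeatedly permutes the region-to-system assignment uniformly at
#' random -- preserving the number of systems and every system's size --
#' and recomputes \eqn{R_S}, \eqn{I_S} and the pairwise integrations on
#' the same allegiance matrix. Percentile confidence bands from these
#' replicates calibrate the observed coefficients.
#'
#' @inheritParams region_coefficients
#' @param n_perm number of permutation replicates (default 1000; a
#'   warning is issued below 100, where percentile CIs are unstable).
#' @param seed integer seed.
#' @return object of class `cartography_null`: list with matrices
#'   `recruitment` and `integration` (n_perm x systems), array
#'   `pairwise` (systems x systems x n_perm), and `ci` (2.5/97.5
#'   percentile bands per system).
#' @export
permutation_null <- function(P, systems, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  if (n_perm < 100)
    warning("fewer than 100 permutation replicates: percentile CIs unstable")
  P <- allegiance_P(P, systems)
  K <- length(systems$systems)
  Rn <- matrix(NA_real_, n_perm, K, dimnames = list(NULL, systems$systems))
  In <- Rn
  Pn <- array(NA_real_, c(K, K, n_perm),
              dimnames = list(systems$systems, systems$systems, NULL))
  base_assign <- systems$assignment
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- system_map(stats::setNames(sample(base_assign),
                                         names(base_assign)))
      # preserve system ordering for stable columns
      perm$systems <- systems$systems
      perm$sizes <- systems$sizes
      sc <- system_coefficients(P, perm)
      Rn[b, ] <- sc$recruitment[systems$systems]
      In[b, ] <- sc$integration[systems$systems]
      Pn[, , b] <- sc$pairwise_integration[systems$systems, systems$systems]
    }
  })
  ci <- list(
    recruitment = apply(Rn, 2, stats::quantile, c(0.025, 0.975)),
    integration = apply(In, 2, stats::quantile, c(0.025, 0.975)))
  structure(list(recruitment = Rn, integration = In, pairwise = Pn,
                 ci = ci, n_perm = n_perm),
            class = "cartography_null")
}

#' Classify systems into nine dynamic network roles
#'
#' Each axis is trichotomized against the permutation-null 95% band:
#' recruitment below the 2.5th percentile is *ephemeral*, inside the band
#' *unstable*, above the 97.5th percentile *stable*; integration maps the
#' same way to *loner* / *connector* / *integrator*. The role is the pair,
#' e.g. `"stable loner"`.
#'
#' @param coeffs output of [system_coefficients()].
#' @param null output of [permutation_null()] for the same systems.
#' @return named character vector of role labels per system.
#' @export
classify_roles <- function(coeffs, null) {
  systems <- names(coeffs$recruitment)
  stopifnot(all(systems %in% colnames(null$ci$recruitment)))
  axis <- function(x, band, labels) {
    lo <- band["2.5%", systems]; hi <- band["97.5%", systems]
    ifelse(x < lo, labels[1], ifelse(x > hi, labels[3], labels[2]))
  }
  rec <- axis(coeffs$recruitment[systems], null$ci$recruitment,
              c("ephemeral", "unstable", "stable"))
  int <- axis(coeffs$integration[systems], null$ci$integration,
              c("loner", "connector", "integrator"))
  stats::setNames(paste(rec, int), systems)
}

#' Flag significant pairwise integration edges
#'
#' Compares each observed pairwise integration \eqn{I_{S_k S_l}} against
#' the 2.5-97.5 percentile band of its permutation-null distribution
#' (whose location is the mean allegiance weight between random
#' size-matched node-sets): pairs strictly above the band are flagged
#' `"stronger"`, strictly below `"weaker"`, otherwise `"ns"`.
#'
#' @param coeffs output of [system_coefficients()].
#' @param null output of [permutation_null()].
#' @return symmetric character matrix (systems x systems, diagonal `NA`)
#'   with entries in `{"stronger", "weaker", "ns"}`.
#' @export
flag_integration_edges <- function(coeffs, null) {
  systems <- rownames(coeffs$pairwise_integration)
  K <- length(systems)
  flags <- matrix(NA_character_, K, K, dimnames = list(systems, systems))
  for (k in seq_len(K - 1)) for (l in seq((k + 1), K)) {
    obs <- coeffs$pairwise_integration[k, l]
    nulls <- null$pairwise[k, l, ]
    band <- stats::quantile(nulls, c(0.025, 0.975))
    flags[k, l] <- flags[l, k] <-
      if (obs > band[2]) "stronger" else if (obs < band[1]) "weaker" else "ns"
  }
  flags
}

#' Full cartography of a partition ensemble
#'
#' Convenience wrapper chaining [module_allegiance()],
#' [region_coefficients()], [system_coefficients()],
#' [permutation_null()], [classify_roles()] and
#' [flag_integration_edges()].
#'
#' @param ensemble a `partition_ensemble`.
#' @param systems a `system_map`.
#' @param n_perm permutation replicates for the null model.
#' @param seed seed for the permutation null.
#' @param include_self include the allegiance diagonal in region
#'   recruitment (see [region_coefficients()]).
#' @return object of class `cartography_result`: list with `allegiance`,
#'   `region`, `system`, `null`, `roles`, `edge_flags`, and the
#'   ensemble-averaged `flexibility`.
#' @export
cartography <- function(ensemble, systems, n_perm = 1000, seed = 1,
                        include_self = TRUE) {
  P <- module_allegiance(ensemble)
  region <- region_coefficients(P, systems, include_self = include_self)
  coeffs <- system_coefficients(P, systems)
  null <- permutation_null(P, systems, n_perm = n_perm, seed = seed)
  structure(
    list(allegiance = P, region = region, system = coeffs, null = null,
         roles = classify_roles(coeffs, null),
         edge_flags = flag_integration_edges(coeffs, null),
         flexibility = flexibility(ensemble)),
    class = "cartography_result")
}

#' @export
print.cartography_result <- function(x, ...) {
  cat(sprintf("cartography_result: %d systems, %d-node allegiance matrix\n",
              length(x$roles), nrow(x$allegiance$P)))
  for (s in names(x$roles))
    cat(sprintf("  %-14s R = %.3f  I = %.3f  ->  %s\n", s,
                x$system$recruitment[s], x$system$integration[s],
                x$roles[s]))
  cat(sprintf("  mean network flexibility: %.3f\n",
              x$flexibility$network_mean))
  invisible(x)
}
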