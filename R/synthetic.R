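# Planted multilayer networks, planted-role scenarios and block-covariance
# multi-condition time series. These generators define the synthetic study
# conditions under which the pipeline is validated end to end.

#' Describe a planted multilayer scenario
#'
#' A planted scenario fixes a ground-truth system map and per-slice
#' community structure: in each slice a node keeps its system's community
#' label with probability `1 - flip_prob` and is otherwise reassigned
#' uniformly at random to another system. Edge weights are Gaussian around
#' `mu_in` within slice-communities and `mu_out` between them.
#'
#' @param systems a `system_map` giving the ground-truth node-to-system
#'   labels, or `NULL` to build one from `n_systems`/`nodes_per_system`.
#' @param n_systems,nodes_per_system used when `systems` is `NULL`
#'   (default 4 systems of 8 nodes); `nodes_per_system` may be a vector
#'   of per-system sizes.
#' @param n_slices number of slices (conditions), default 8.
#' @param flip_prob probability in \[0, 1\] that a node's slice community
#'   deviates from its system label, default 0.1.
#' @param mu_in,mu_out mean edge weight within / between slice
#'   communities (defaults 0.8 / 0.2, a contrast comparable to strong vs
#'   weak Fisher-z coupling).
#' @param sigma edge-weight noise standard deviation, default 0.1.
#' @param seed integer seed.
#' @return object of class `planted_scenario`.
#' @export
planted_scenario <- function(systems = NULL, n_systems = 4,
                             nodes_per_system = 8, n_slices = 8,
                             flip_prob = 0.1, mu_in = 0.8, mu_out = 0.2,
                             sigma = 0.1, seed = 1) {
  if (is.null(systems)) {
    sizes <- rep_len(nodes_per_system, n_systems)
    labels <- rep(paste0("S", seq_len(n_systems)), times = sizes)
    ids <- sprintf("n%02d", seq_along(labels))
    systems <- system_map(stats::setNames(labels, ids))
  }
  stopifnot(inherits(systems, "system_map"))
  if (flip_prob < 0 || flip_prob > 1)
    fc_stop("flip_prob must be in [0, 1]")
  if (n_slices < 1) fc_stop("n_slices must be positive")
  if (sigma < 0) fc_stop("sigma must be non-negative")
  if (mu_in <= mu_out)
    warning("mu_in <= mu_out: planted structure is not recoverable")
  structure(list(systems = systems, n_slices = as.integer(n_slices),
                 flip_prob = flip_prob, mu_in = mu_in, mu_out = mu_out,
                 sigma = sigma, seed = as.integer(seed)),
            class = "planted_scenario")
}

# internal: draw slice community labels for one scenario.
# flip_targets restricts which systems a flipped node may land in;
# frozen_systems' nodes never flip.
draw_slice_labels <- function(systems, n_slices, flip_prob,
                              flip_targets = systems$systems,
                              frozen_systems = character()) {
  sys_idx <- match(systems$assignment, systems$systems)
  N <- systems$n
  labels <- matrix(rep(sys_idx, n_slices), N, n_slices)
  for (t in seq_len(n_slices)) {
    for (i in seq_len(N)) {
      own <- systems$systems[sys_idx[i]]
      if (own %in% frozen_systems) next
      if (stats::runif(1) < flip_prob) {
        others <- setdiff(flip_targets, own)
        if (length(others) > 0)
          labels[i, t] <- match(sample(others, 1), systems$systems)
      }
    }
  }
  labels
}

# internal: build symmetric weighted slices from a label matrix.
# Same-community pairs get N(mu_in, sigma) weights, others N(mu_out,
# sigma); weights symmetrized by averaging, diagonal zero. Negative draws
# pass through: the network's sign policy decides their fate.
# decoupled: optional N x T logical; a decoupled (node, slice) carries no
# signal at all -- every edge weight involving it is zero in that slice
# (the region transiently disengages rather than joining another
# community).
slices_from_labels <- function(labels, mu_in, mu_out, sigma, node_ids,
                               decoupled = NULL) {
  N <- nrow(labels)
  lapply(seq_len(ncol(labels)), function(t) {
    g <- labels[, t]
    mu <- ifelse(outer(g, g, "=="), mu_in, mu_out)
    A <- mu + matrix(stats::rnorm(N * N, 0, sigma), N, N)
    if (!is.null(decoupled) && any(decoupled[, t])) {
      A[decoupled[, t], ] <- 0
      A[, decoupled[, t]] <- 0
    }
    A <- (A + t(A)) / 2
    diag(A) <- 0
    dimnames(A) <- list(node_ids, node_ids)
    A
  })
}

#' Generate a planted multilayer network
#'
#' Draws slice-wise community labels and edge weights according to a
#' [planted_scenario()] and returns both the network and its ground-truth
#' partition. Negative sampled weights are handled by the network's sign
#' policy at construction.
#'
#' @param scenario a `planted_scenario`.
#' @param gamma,omega resolution and coupling parameters stored in the
#'   returned network (defaults 1 and 0.1; see the package vignette for
#'   the choice of the synthetic-analysis coupling).
#' @param sign_policy negative-weight policy for the network.
#' @return list with `network` (a `multilayer_network`) and `truth` (the
#'   planted `partition`).
#' @export
generate_planted_multilayer <- function(scenario, gamma = 1, omega = 0.1,
                                        sign_policy = "truncate_negative") {
  stopifnot(inherits(scenario, "planted_scenario"))
  systems <- scenario$systems
  with_seed(scenario$seed, {
    labels <- draw_slice_labels(systems, scenario$n_slices,
                                scenario$flip_prob)
    slices <- slices_from_labels(labels, scenario$mu_in, scenario$mu_out,
                                 scenario$sigma, names(systems$assignment))
  })
  net <- multilayer_network(slices, node_ids = names(systems$assignment),
                            gamma = gamma, omega = omega,
                            sign_policy = sign_policy)
  truth <- partition(labels, node_ids = names(systems$assignment),
                     slice_ids = net$slice_ids)
  list(network = net, truth = canonicalize_partition(truth))
}

#' Generate a planted-role scenario
#'
#' Modifies one designated system's generative rules so that its expected
#' cartography role is known by construction:
#' \describe{
#'   \item{stable_loner}{its nodes never scatter and never share
#'     above-background weights with outsiders.}
#'   \item{stable_integrator}{its nodes never scatter individually, but
#'     in every slice the whole block merges (community and `mu_in`
#'     weights) with one uniformly chosen other system.}
#'   \item{stable_connector}{as the integrator, but the block merges in
#'     roughly 70% of slices, which places its integration at the centre
#'     of the null band (mean-field identity; see the vignette).}
#'   \item{ephemeral_loner}{each of its nodes transiently disengages with
#'     high probability (0.9 per slice): it becomes a singleton community
#'     with zero-weight edges, never merging with other systems.}
#' }
#' Background dynamics differ from [generate_planted_multilayer()]: a
#' non-designated node deviating from its system (with probability
#' `base$flip_prob`) transiently *decouples* into a zero-weight singleton
#' instead of defecting into another system. Wholesale defection would
#' inflate the between-system allegiance baseline to the point where no
#' block merging with one partner at a time could ever exceed the
#' permutation band (see the package vignette for the mean-field
#' argument), so decoupling is what makes the contrast roles
#' identifiable.
#'
#' @param role one of `"stable_loner"`, `"stable_integrator"`,
#'   `"stable_connector"`, `"ephemeral_loner"`.
#' @param base a `planted_scenario`. The role-scenario default differs
#'   from the plain planted default: the designated system is small (8
#'   nodes) relative to three 16-node background systems and the
#'   background deviation rate is 0.35. Both choices come from the
#'   mean-field identifiability analysis in the vignette: a small
#'   designated system keeps its own cross cells from dominating the
#'   global allegiance mean that anchors the permutation null, and
#'   moderate background decoupling lowers that mean below the
#'   integrator's merge share, while a designated system larger than the
#'   number of systems guarantees (pigeonhole) that permuted
#'   pseudo-systems retain same-system pairs, keeping the null floor
#'   above a truly ephemeral system.
#' @param designated label of the designated system (default: first).
#' @param gamma,omega resolution and coupling for the returned network.
#'   Roles are allegiance-based, and per-slice co-occurrence needs no
#'   cross-slice label alignment, so the role pipeline defaults to
#'   `omega = 0`: with categorical coupling any positive omega drags a
#'   transiently disengaged node back into the community its replicas
#'   occupy (coupling carries no null-model penalty), masking planted
#'   ephemerality.
#' @inheritParams generate_planted_multilayer
#' @return list with `network`, `truth`, `systems` (the ground-truth
#'   map), `designated` and `expected_role` (e.g. `"stable loner"`).
#' @export
generate_role_scenario <- function(role = c("stable_loner",
                                            "stable_integrator",
                                            "stable_connector",
                                            "ephemeral_loner"),
                                   base = planted_scenario(
                                     n_systems = 4,
                                     nodes_per_system = c(8, 16, 16, 16),
                                     flip_prob = 0.35),
                                   designated = NULL,
                                   gamma = 1, omega = 0,
                                   sign_policy = "truncate_negative") {
  role <- match.arg(role)
  stopifnot(inherits(base, "planted_scenario"))
  systems <- base$systems
  if (is.null(designated)) designated <- systems$systems[1]
  if (!designated %in% systems$systems)
    fc_stop(sprintf("designated system '%s' absent from the scenario",
                    designated))
  if (length(systems$systems) < 2)
    fc_stop("role scenarios need at least 2 systems")
  des_nodes <- which(systems$assignment == designated)
  others <- setdiff(systems$systems, designated)
  N <- systems$n
  Tn <- base$n_slices
  with_seed(base$seed, {
    sys_idx <- match(systems$assignment, systems$systems)
    labels <- matrix(rep(sys_idx, Tn), N, Tn)
    decoupled <- matrix(FALSE, N, Tn)
    # background: transient decoupling of non-designated nodes
    bg <- setdiff(seq_len(N), des_nodes)
    decoupled[bg, ] <- stats::runif(length(bg) * Tn) < base$flip_prob
    if (role == "ephemeral_loner")
      decoupled[des_nodes, ] <-
        stats::runif(length(des_nodes) * Tn) < 0.9
    next_label <- length(systems$systems)
    for (t in seq_len(Tn)) for (i in which(decoupled[, t])) {
      next_label <- next_label + 1L      # unique singleton community
      labels[i, t] <- next_label
    }
    if (role %in% c("stable_integrator", "stable_connector")) {
      p_merge <- if (role == "stable_integrator") 1 else 0.7
      for (t in seq_len(Tn)) {
        if (stats::runif(1) < p_merge) {
          partner <- sample(others, 1)
          pid <- match(partner, systems$systems)
          pnodes <- which(systems$assignment == partner)
          # both parties of a merge are fully engaged in that slice
          decoupled[pnodes, t] <- FALSE
          labels[pnodes, t] <- pid
          labels[des_nodes, t] <- pid
        }
      }
    }
    slices <- slices_from_labels(labels, base$mu_in, base$mu_out,
                                 base$sigma, names(systems$assignment),
                                 decoupled = decoupled)
  })
  net <- multilayer_network(slices, node_ids = names(systems$assignment),
                            gamma = gamma, omega = omega,
                            sign_policy = sign_policy)
  expected <- c(stable_loner = "stable loner",
                stable_integrator = "stable integrator",
                stable_connector = "stable connector",
                ephemeral_loner = "ephemeral loner")[[role]]
  list(network = net,
       truth = canonicalize_partition(
         partition(labels, node_ids = names(systems$assignment),
                   slice_ids = net$slice_ids)),
       systems = systems, designated = designated, expected_role = expected)
}

#' Generate block-covariance multi-condition time series
#'
#' Draws, for each condition, multivariate normal samples whose
#' covariance is 1 on the diagonal, `rho_in` within systems and `rho_out`
#' between systems. If the block covariance is not positive semi-definite
#' `rho_in` is shrunk towards `rho_out` (in steps of 5%) until it is, with
#' a warning; failure after 20 attempts is an error.
#'
#' @param systems a `system_map` defining the correlation blocks.
#' @param n_conditions number of conditions.
#' @param samples_per_condition timepoints per condition (>= 3, the
#'   minimum for a correlation estimate).
#' @param rho_in,rho_out within/between-system correlations, with
#'   `0 <= rho_out <= rho_in < 1`.
#' @param seed integer seed.
#' @return a `condition_timeseries` with condition labels
#'   `"cond_001" ...` in generation order.
#' @export
generate_timeseries <- function(systems, n_conditions = 4,
                                samples_per_condition = 50,
                                rho_in = 0.6, rho_out = 0.1, seed = 1) {
  stopifnot(inherits(systems, "system_map"),
            n_conditions >= 1, samples_per_condition >= 3)
  if (rho_out > rho_in) fc_stop("rho_out must not exceed rho_in")
  if (rho_in >= 1 || rho_in < 0 || rho_out < 0)
    fc_stop("correlations must satisfy 0 <= rho_out <= rho_in < 1")
  N <- systems$n
  same <- outer(systems$assignment, systems$assignment, "==")
  build_sigma <- function(ri) {
    S <- ifelse(same, ri, rho_out)
    diag(S) <- 1
    S
  }
  Sigma <- build_sigma(rho_in)
  tries <- 0
  while (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <
         -1e-10) {
    tries <- tries + 1
    if (tries > 20)
      fc_stop("block covariance not positive semi-definite after shrinkage")
    rho_in <- rho_out + 0.95 * (rho_in - rho_out)
    warning(sprintf("shrinking rho_in to %.4f for positive semi-definiteness",
                    rho_in))
    Sigma <- build_sigma(rho_in)
  }
  cond <- sprintf("cond_%03d", seq_len(n_conditions))
  samples <- with_seed(seed, {
    do.call(rbind, lapply(cond, function(cc)
      MASS::mvrnorm(samples_per_condition, mu = rep(0, N), Sigma = Sigma)))
  })
  colnames(samples) <- names(systems$assignment)
  condition_timeseries(samples, rep(cond, each = samples_per_condition))
}
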