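# Shared fixtures and independent oracles used across the suite.

# random symmetric zero-diagonal weight matrix
random_slice <- function(n, scale = 1) {
  A <- matrix(stats::runif(n * n, 0, scale), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# random multilayer network of given size
random_network <- function(n, t, gamma = 1, omega = 0.5, scale = 1) {
  multilayer_network(replicate(t, random_slice(n, scale), simplify = FALSE),
                     gamma = gamma, omega = omega)
}

# Independent term-by-term evaluation of the multislice quality function:
# a literal quadruple sum over (i, j, s, r), no shared code with the
# package's supra-matrix path.
brute_force_modularity <- function(net, labels) {
  N <- length(net$node_ids); Tn <- length(net$slices)
  k <- sapply(net$slices, rowSums)
  k <- matrix(k, nrow = N)
  m_s <- colSums(k) / 2
  mu <- (sum(k) + N * Tn * (Tn - 1) * net$omega) / 2
  total <- 0
  for (s in seq_len(Tn)) for (r in seq_len(Tn)) {
    for (i in seq_len(N)) for (j in seq_len(N)) {
      term <- 0
      if (s == r) {
        V <- if (m_s[s] > 0) k[i, s] * k[j, s] / (2 * m_s[s]) else 0
        term <- term + net$slices[[s]][i, j] - net$gamma[s] * V
      }
      if (i == j && s != r) term <- term + net$omega
      if (labels[i, s] == labels[j, r]) total <- total + term
    }
  }
  total / (2 * mu)
}

# All set partitions of n elements as canonical label vectors (restricted
# growth strings). n must stay small (Bell(8) = 4140).
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      grow(c(prefix, lab), max(maxlab, lab))
  }
  grow(1L, 1L)
  do.call(rbind, out)
}

# Exhaustive global maximum of multislice modularity over every partition
# of the N*T supra-nodes, evaluated on the supra-modularity matrix by a
# direct pairwise sum (vectorized over partitions).
exhaustive_max_modularity <- function(net) {
  N <- length(net$node_ids); Tn <- length(net$slices)
  n <- N * Tn
  parts <- all_partitions(n)
  B <- funcarto:::supra_modularity_matrix(net)
  twomu <- 2 * quality_context(net)$mu
  pair <- which(upper.tri(B), arr.ind = TRUE)
  eq <- parts[, pair[, 1]] == parts[, pair[, 2]]
  qs <- (2 * (eq %*% B[pair]) + sum(diag(B))) / twomu
  list(q = max(qs), labels = matrix(parts[which.max(qs), ], N, Tn))
}

# small deterministic ensemble from explicit label matrices
ensemble_from_labels <- function(label_list) {
  structure(list(partitions = lapply(label_list, partition),
                 qualities = rep(NA_real_, length(label_list)),
                 seeds = seq_along(label_list),
                 params = list()),
            class = "partition_ensemble")
}

# four-systems-of-eight ground-truth map used by several fixtures
four_system_map <- function(n_systems = 4, nodes_per_system = 8) {
  labels <- rep(paste0("S", seq_len(n_systems)), each = nodes_per_system)
  system_map(stats::setNames(labels, sprintf("n%02d", seq_along(labels))))
}
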