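# Multilayer network container and the multislice modularity quality function.
#
# A multilayer network is an ordered stack of T symmetric weighted N x N
# adjacency matrices (slices) over a fixed node set, with interslice
# coupling of weight omega between each node and itself in every other
# slice (categorical coupling: all slice pairs, no temporal ordering).

#' Construct a multilayer network
#'
#' @param slices list of symmetric numeric N x N matrices, one per slice
#'   (condition). Diagonals are forced to zero: self-weights carry no
#'   information for community structure.
#' @param node_ids optional character vector of node labels; defaults to
#'   dimnames of the first slice or `"n1" ... "nN"`.
#' @param slice_ids optional labels for the slices (condition names).
#' @param gamma structural resolution parameter, a single value applied to
#'   every slice or one value per slice.
#' @param omega interslice coupling weight (categorical: node j in slice s
#'   couples to node j in every slice r != s with weight omega).
#' @param sign_policy `"truncate_negative"` (default) sets negative weights
#'   to zero so the Newman-Girvan null model is well defined; `"keep"`
#'   passes them through.
#' @param tol symmetry tolerance for input validation.
#' @return an object of class `multilayer_network`.
#' @export
multilayer_network <- function(slices, node_ids = NULL, slice_ids = NULL,
                               gamma = 1, omega = 0.45,
                               sign_policy = c("truncate_negative", "keep"),
                               tol = 1e-10) {
  sign_policy <- match.arg(sign_policy)
  if (!is.list(slices) || length(slices) == 0)
    fc_stop("'slices' must be a non-empty list of matrices")
  n <- nrow(slices[[1]])
  for (s in seq_along(slices)) {
    m <- slices[[s]]
    if (!is.matrix(m) || !is.numeric(m))
      fc_stop(sprintf("slice %d is not a numeric matrix", s))
    if (nrow(m) != ncol(m))
      fc_stop(sprintf("slice %d is not square (%d x %d)",
                      s, nrow(m), ncol(m)))
    if (nrow(m) != n || ncol(m) != n)
      fc_stop(sprintf("slice %d has dimensions %d x %d, expected %d x %d",
                      s, nrow(m), ncol(m), n, n))
    if (anyNA(m)) fc_stop(sprintf("slice %d contains missing values", s))
    check_symmetric(m, tol, sprintf("slice %d", s))
    m <- (m + t(m)) / 2
    diag(m) <- 0
    slices[[s]] <- m
  }
  if (is.null(node_ids)) {
    node_ids <- rownames(slices[[1]])
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(n))
  }
  stopifnot(length(node_ids) == n)
  if (is.null(slice_ids)) slice_ids <- paste0("s", seq_along(slices))
  stopifnot(length(slice_ids) == length(slices))
  if (length(gamma) == 1) gamma <- rep(gamma, length(slices))
  stopifnot(length(gamma) == length(slices), omega >= 0 || sign_policy == "keep")
  slices <- lapply(slices, function(m) {
    dimnames(m) <- list(node_ids, node_ids); m
  })
  net <- structure(
    list(slices = slices, node_ids = node_ids, slice_ids = slice_ids,
         gamma = gamma, omega = omega, sign_policy = sign_policy),
    class = "multilayer_network")
  apply_sign_policy(net)
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf(
    "multilayer_network: %d nodes x %d slices (gamma = %s, omega = %g, %s)\n",
    length(x$node_ids), length(x$slices),
    paste(unique(signif(x$gamma, 4)), collapse = "/"), x$omega,
    x$sign_policy))
  invisible(x)
}

#' Apply the network's negative-weight policy
#'
#' Under `truncate_negative` every negative intraslice weight is set to
#' zero; under `keep` the network is returned unchanged. Truncation never
#' increases a slice's total edge weight.
#'
#' @param net a `multilayer_network`.
#' @return the network with the policy applied.
#' @export
apply_sign_policy <- function(net) {
  stopifnot(inherits(net, "multilayer_network"))
  if (net$sign_policy == "truncate_negative")
    net$slices <- lapply(net$slices, function(m) { m[m < 0] <- 0; m })
  net
}

#' Number of nodes / slices of a multilayer network
#' @param net a `multilayer_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname n_nodes
#' @export
n_slices <- function(net) length(net$slices)

#' Strength and total-weight bookkeeping for the quality function
#'
#' Computes, for each slice, the node strengths \eqn{k_{js}}, slice totals
#' \eqn{m_s = \frac12\sum_{ij} A_{ijs}}, the interslice coupling strengths
#' \eqn{c_{js} = (T-1)\omega}, and the grand total
#' \eqn{\mu = \frac12 \sum_{js} (k_{js} + c_{js})}.
#'
#' @param net a `multilayer_network`.
#' @return a list with `strengths` (N x T matrix), `slice_totals` (length
#'   T), `coupling_strength` (scalar) and `mu`.
#' @export
quality_context <- function(net) {
  k <- vapply(net$slices, rowSums, numeric(n_nodes(net)))
  k <- matrix(k, nrow = n_nodes(net))   # N x T even when N == 1
  m_s <- colSums(k) / 2
  Tn <- n_slices(net)
  c_js <- (Tn - 1) * net$omega
  mu <- (sum(k) + n_nodes(net) * Tn * c_js) / 2
  list(strengths = k, slice_totals = m_s, coupling_strength = c_js, mu = mu)
}

#' Newman-Girvan null model for one slice
#'
#' Expected edge weight under degree-preserving randomization within a
#' slice: \eqn{V_{ijs} = k_{is} k_{js} / (2 m_s)}. An empty slice
#' (\eqn{m_s = 0}) yields an all-zero null matrix with a warning.
#'
#' @param net a `multilayer_network`.
#' @param slice_index slice to evaluate.
#' @return N x N numeric matrix.
#' @export
newman_girvan_null <- function(net, slice_index) {
  stopifnot(inherits(net, "multilayer_network"),
            slice_index >= 1, slice_index <= n_slices(net))
  k <- rowSums(net$slices[[slice_index]])
  m <- sum(k) / 2
  if (m <= 0) {
    warning(sprintf("slice %d is empty (m_s = 0); null model is zero",
                    slice_index))
    return(matrix(0, length(k), length(k)))
  }
  outer(k, k) / (2 * m)
}

# internal: dense supra-modularity matrix B of size (N*T) x (N*T).
# Supra-node index of (node i, slice s) is (s-1)*N + i.
# B[(s,i),(s,j)] = A_ijs - gamma_s * V_ijs   (includes i = j diagonal)
# B[(s,i),(r,i)] = omega for s != r          (categorical coupling)
# Q = sum_{pq} B_pq [g_p == g_q] / (2*mu).
supra_modularity_matrix <- function(net) {
  N <- n_nodes(net); Tn <- n_slices(net)
  B <- matrix(0, N * Tn, N * Tn)
  for (s in seq_len(Tn)) {
    A <- net$slices[[s]]
    k <- rowSums(A)
    m <- sum(k) / 2
    V <- if (m > 0) outer(k, k) / (2 * m) else matrix(0, N, N)
    idx <- (s - 1L) * N + seq_len(N)
    B[idx, idx] <- A - net$gamma[s] * V
  }
  if (net$omega != 0 && Tn > 1) {
    for (s in seq_len(Tn - 1)) for (r in seq((s + 1), Tn)) {
      is <- (s - 1L) * N + seq_len(N)
      ir <- (r - 1L) * N + seq_len(N)
      B[cbind(is, ir)] <- B[cbind(is, ir)] + net$omega
      B[cbind(ir, is)] <- B[cbind(ir, is)] + net$omega
    }
  }
  B
}

#' Multislice modularity of a partition
#'
#' Evaluates the categorical multislice quality function
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijsr} \left[ (A_{ijs} - \gamma_s V_{ijs})
#'   \delta_{sr} + \delta_{ij}\,\omega \right] \delta(g_{is}, g_{jr})}
#' where \eqn{V_{ijs}} is the per-slice Newman-Girvan null and every
#' ordered pair of distinct slices contributes the coupling \eqn{\omega}
#' when a node keeps the same community label. Pure, deterministic
#' evaluation; no optimization.
#'
#' @param net a `multilayer_network`.
#' @param partition a `partition` object or an N x T integer label matrix.
#' @return scalar quality Q.
#' @export
multislice_modularity <- function(net, partition) {
  labels <- partition_labels(partition)
  N <- n_nodes(net); Tn <- n_slices(net)
  if (!all(dim(labels) == c(N, Tn)))
    fc_stop(sprintf("partition is %d x %d but network is %d x %d",
                    nrow(labels), ncol(labels), N, Tn))
  B <- supra_modularity_matrix(net)
  g <- as.vector(labels)
  mu <- quality_context(net)$mu
  sum(B[outer(g, g, "==")]) / (2 * mu)
}
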