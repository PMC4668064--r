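# Partition container: community labels per (node, slice).

#' Construct a partition
#'
#' @param labels integer matrix \[N x T\]: community label of each node in
#'   each slice. Any label values are accepted; `canonicalize_partition()`
#'   renumbers them 1, 2, ... by first appearance.
#' @param node_ids,slice_ids optional dimension labels.
#' @return an object of class `partition`.
#' @export
partition <- function(labels, node_ids = NULL, slice_ids = NULL) {
  labels <- as.matrix(labels)
  if (anyNA(labels)) fc_stop("partition labels contain missing values")
  storage.mode(labels) <- "integer"
  if (!is.null(node_ids)) rownames(labels) <- node_ids
  if (!is.null(slice_ids)) colnames(labels) <- slice_ids
  structure(list(labels = labels), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes x %d slices, %d communities\n",
              nrow(x$labels), ncol(x$labels),
              length(unique(as.vector(x$labels)))))
  invisible(x)
}

# internal: accept a partition object or a bare label matrix
partition_labels <- function(p) {
  if (inherits(p, "partition")) p$labels else as.matrix(p)
}

#' Canonicalize community labels
#'
#' Renumbers labels 1, 2, ... in order of first appearance when reading
#' the label matrix column-major (node-fastest within slice 1, then slice
#' 2, ...). A bijection on label values: community structure is unchanged.
#'
#' @param p a `partition` or label matrix.
#' @return a `partition` with canonical labels.
#' @export
canonicalize_partition <- function(p) {
  labels <- partition_labels(p)
  v <- as.vector(labels)
  canon <- match(v, unique(v))
  out <- matrix(as.integer(canon), nrow(labels), ncol(labels),
                dimnames = dimnames(labels))
  partition(out)
}

#' Flexibility of each node
#'
#' The proportion of consecutive slice transitions in which a node changes
#' its community label: \eqn{f_i = \#\{t : g_{i,t} \ne g_{i,t+1}\}/(T-1)},
#' slices taken in input order. For a partition ensemble the per-node
#' flexibility is averaged over the ensemble's runs.
#'
#' @param p a `partition`, label matrix, or `partition_ensemble`.
#' @return a list of class `flexibility_vector` with elements `f`
#'   (per-node flexibility in \[0, 1\]) and `network_mean`.
#' @export
flexibility <- function(p) {
  if (inherits(p, "partition_ensemble")) {
    fs <- vapply(p$partitions, function(q) flexibility(q)$f,
                 numeric(nrow(p$partitions[[1]]$labels)))
    f <- rowMeans(matrix(fs, ncol = length(p$partitions)))
    names(f) <- rownames(p$partitions[[1]]$labels)
  } else {
    labels <- partition_labels(p)
    Tn <- ncol(labels)
    if (Tn < 2) fc_stop("flexibility requires at least 2 slices")
    changes <- labels[, -1, drop = FALSE] != labels[, -Tn, drop = FALSE]
    f <- rowMeans(changes)
  }
  structure(list(f = f, network_mean = mean(f)), class = "flexibility_vector")
}
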