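# Plain-text readers and writers: matrix stacks, edge lists, system maps,
# partitions, and run manifests. All numeric output is written with 17
# significant digits so write/read round-trips are bit-exact for doubles.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

# internal: write one numeric matrix with a node-id header as TSV
write_matrix_file <- function(m, path, sep = "\t") {
  ids <- colnames(m) %||% paste0("n", seq_len(ncol(m)))
  out <- apply(m, 2, fmt_num)
  out <- matrix(out, nrow(m), ncol(m))
  lines <- c(paste(ids, collapse = sep),
             apply(out, 1, paste, collapse = sep))
  writeLines(lines, path)
  invisible(path)
}

# internal: read one delimited numeric matrix with a header row
read_matrix_file <- function(path, sep = "\t") {
  if (!file.exists(path)) fc_stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) fc_stop(sprintf("non-numeric entries in %s", path))
  rownames(m) <- NULL
  m
}

#' Write a matrix stack to a directory
#'
#' Writes one delimited matrix file per condition (`<condition>.tsv`,
#' header row of node ids) plus a `stack.json` manifest recording the
#' condition order, node order and transform, which makes the read/write
#' pair round-trip exactly.
#'
#' @param stack a `connectivity_stack` or `multilayer_network`.
#' @param dir output directory (created if needed).
#' @param sep field separator (default tab).
#' @return invisibly, the manifest path.
#' @export
write_matrix_stack <- function(stack, dir, sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(stack, "multilayer_network")) {
    mats <- stack$slices; conds <- stack$slice_ids; nodes <- stack$node_ids
    transform <- "adjacency"
  } else {
    stopifnot(inherits(stack, "connectivity_stack"))
    mats <- stack$matrices; conds <- stack$condition_ids
    nodes <- stack$node_ids; transform <- stack$transform
  }
  files <- paste0(make.names(conds), ".tsv")
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    dimnames(m) <- list(nodes, nodes)
    write_matrix_file(m, file.path(dir, files[i]), sep)
  }
  manifest <- list(condition_ids = conds, files = files,
                   node_ids = nodes, transform = transform)
  mpath <- file.path(dir, "stack.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Read a matrix stack from a directory or file list
#'
#' Reads the matrices written by [write_matrix_stack()] (or any set of
#' delimited square matrices with identical node-id headers). Asymmetry
#' up to `symmetrize_tol` is symmetrized by averaging with a warning;
#' beyond it, an error reports the maximum asymmetry and the offending
#' file. `NaN` entries and dimension mismatches are errors.
#'
#' @param path directory containing `stack.json`, or a character vector
#'   of matrix file paths.
#' @param tol symmetry tolerance below which matrices are accepted as-is.
#' @param symmetrize_tol asymmetry ceiling for silent repair (values in
#'   `(tol, symmetrize_tol]` are symmetrized with a warning).
#' @param sep field separator.
#' @param gamma,omega,sign_policy network parameters, used when the
#'   manifest marks the stack as adjacency matrices (then a
#'   `multilayer_network` is returned instead of a stack).
#' @return a `connectivity_stack` (transform from the manifest, default
#'   `"fisher_z"` for bare file lists), or a `multilayer_network` for
#'   adjacency stacks written from one.
#' @export
read_matrix_stack <- function(path, tol = 1e-10, symmetrize_tol = 1e-6,
                              sep = "\t", gamma = 1, omega = 0.45,
                              sign_policy = "truncate_negative") {
  if (length(path) == 1 && dir.exists(path)) {
    mpath <- file.path(path, "stack.json")
    if (!file.exists(mpath))
      fc_stop(sprintf("no stack.json manifest in %s", path))
    manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    files <- file.path(path, manifest$files)
    conds <- manifest$condition_ids
    transform <- manifest$transform
  } else {
    files <- path
    conds <- sub("\\.[^.]*$", "", basename(files))
    transform <- "fisher_z"
  }
  mats <- vector("list", length(files))
  nodes <- NULL
  for (i in seq_along(files)) {
    m <- read_matrix_file(files[i], sep)
    if (anyNA(m) || any(!is.finite(m)))
      fc_stop(sprintf("non-finite entries in %s", files[i]))
    if (nrow(m) != ncol(m))
      fc_stop(sprintf("%s is %d x %d, not square",
                      files[i], nrow(m), ncol(m)))
    if (is.null(nodes)) nodes <- colnames(m)
    if (nrow(m) != length(nodes) || !identical(colnames(m), nodes))
      fc_stop(sprintf("node header of %s does not match the first file",
                      files[i]))
    asym <- max(abs(m - t(m)))
    if (asym > symmetrize_tol)
      fc_stop(sprintf("%s is not symmetric (max asymmetry %.3g > %.3g)",
                      files[i], asym, symmetrize_tol))
    if (asym > tol) {
      warning(sprintf("symmetrizing %s (max asymmetry %.3g)",
                      files[i], asym))
      m <- (m + t(m)) / 2
    }
    rownames(m) <- nodes
    mats[[i]] <- m
  }
  if (identical(transform, "adjacency"))
    return(multilayer_network(mats, node_ids = nodes, slice_ids = conds,
                              gamma = gamma, omega = omega,
                              sign_policy = sign_policy,
                              tol = symmetrize_tol))
  connectivity_stack(mats, condition_ids = conds, transform = transform,
                     tol = symmetrize_tol)
}

#' Write / read a multilayer edge list
#'
#' Single-file alternative to the per-condition matrix format: a
#' four-column delimited table `slice, node_i, node_j, weight` holding
#' each undirected edge once (upper triangle). Zero-weight edges are
#' omitted; dimensions and node order travel in a header comment.
#'
#' @param net a `multilayer_network`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "multilayer_network"))
  rows <- list(sprintf("# nodes: %s", paste(net$node_ids, collapse = ",")),
               sprintf("# slices: %s", paste(net$slice_ids, collapse = ",")),
               "slice\tnode_i\tnode_j\tweight")
  for (s in seq_along(net$slices)) {
    A <- net$slices[[s]]
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    if (nrow(idx) > 0)
      rows[[length(rows) + 1]] <- paste(net$slice_ids[s],
                                        net$node_ids[idx[, 1]],
                                        net$node_ids[idx[, 2]],
                                        fmt_num(A[idx]), sep = "\t")
  }
  writeLines(unlist(rows), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @param gamma,omega,sign_policy parameters for the reconstructed
#'   network.
#' @export
read_edgelist <- function(path, gamma = 1, omega = 0.45,
                          sign_policy = "truncate_negative") {
  if (!file.exists(path)) fc_stop(sprintf("file not found: %s", path))
  header <- readLines(path, n = 2)
  nodes <- strsplit(sub("^# nodes: ", "", header[1]), ",")[[1]]
  slices <- strsplit(sub("^# slices: ", "", header[2]), ",")[[1]]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  mats <- lapply(slices, function(ss) {
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    sub <- df[df$slice == ss, , drop = FALSE]
    if (nrow(sub) > 0) {
      A[cbind(sub$node_i, sub$node_j)] <- sub$weight
      A[cbind(sub$node_j, sub$node_i)] <- sub$weight
    }
    A
  })
  multilayer_network(mats, node_ids = nodes, slice_ids = slices,
                     gamma = gamma, omega = omega, sign_policy = sign_policy)
}

#' Read a region-to-system map
#'
#' Two-column delimited table (`node_id`, `system_label`), with or
#' without a header line. When `node_ids` is supplied (the authoritative
#' order, from the matrix headers), the map is validated against it and
#' reordered to match.
#'
#' @param path file path.
#' @param node_ids optional node order to align to.
#' @param sep field separator.
#' @return a `system_map`.
#' @export
read_system_map <- function(path, node_ids = NULL, sep = "\t") {
  if (!file.exists(path)) fc_stop(sprintf("file not found: %s", path))
  first <- strsplit(readLines(path, n = 1), sep)[[1]]
  header <- identical(tolower(first[1:2]), c("node_id", "system_label")) ||
    identical(tolower(first[1:2]), c("node", "system"))
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character")
  if (ncol(df) != 2)
    fc_stop(sprintf("%s has %d columns, expected 2 (node, system)",
                    path, ncol(df)))
  if (anyDuplicated(df[[1]]))
    fc_stop(sprintf("duplicate node rows in %s: %s", path,
                    paste(unique(df[[1]][duplicated(df[[1]])]),
                          collapse = ", ")))
  assignment <- stats::setNames(df[[2]], df[[1]])
  if (!is.null(node_ids)) {
    missing <- setdiff(node_ids, names(assignment))
    extra <- setdiff(names(assignment), node_ids)
    if (length(missing) > 0)
      fc_stop(sprintf("nodes missing from system map: %s",
                      paste(missing, collapse = ", ")))
    if (length(extra) > 0)
      fc_stop(sprintf("system-map nodes absent from matrices: %s",
                      paste(extra, collapse = ", ")))
    assignment <- assignment[node_ids]
  }
  system_map(assignment)
}

#' Write a system map
#' @param systems a `system_map`.
#' @param path output file.
#' @param sep field separator.
#' @return invisibly, `path`.
#' @export
write_system_map <- function(systems, path, sep = "\t") {
  stopifnot(inherits(systems, "system_map"))
  writeLines(c(paste("node_id", "system_label", sep = sep),
               paste(names(systems$assignment), systems$assignment,
                     sep = sep)),
             path)
  invisible(path)
}

#' Write / read a partition ensemble
#'
#' One delimited label table per ensemble member (rows = nodes, columns =
#' slices, canonical community labels) plus an `ensemble.json` manifest
#' with per-run seeds, qualities and parameters.
#'
#' @param ensemble a `partition_ensemble`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("partition_%04d.tsv", seq_along(ensemble$partitions))
  for (i in seq_along(ensemble$partitions)) {
    lab <- ensemble$partitions[[i]]$labels
    df <- data.frame(node_id = rownames(lab) %||%
                       paste0("n", seq_len(nrow(lab))), lab,
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(files = files, seeds = ensemble$seeds,
                   qualities = ensemble$qualities,
                   params = ensemble$params)
  mpath <- file.path(dir, "ensemble.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_ensemble
#' @param dir directory containing `ensemble.json`.
#' @export
read_ensemble <- function(dir) {
  mpath <- file.path(dir, "ensemble.json")
  if (!file.exists(mpath))
    fc_stop(sprintf("no ensemble.json manifest in %s", dir))
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  parts <- lapply(file.path(dir, manifest$files), function(f) {
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            check.names = FALSE)
    lab <- as.matrix(df[, -1, drop = FALSE])
    rownames(lab) <- df[[1]]
    partition(lab)
  })
  structure(list(partitions = parts,
                 qualities = manifest$qualities,
                 seeds = manifest$seeds,
                 params = manifest$params),
            class = "partition_ensemble")
}

#' Write a run manifest
#'
#' Records command, parameters, seeds, input checksums (MD5), package
#' version and a timestamp, sufficient to re-run a pipeline step
#' bit-identically.
#'
#' @param dir output directory.
#' @param command command name.
#' @param parameters named list of parameters.
#' @param seeds seeds used.
#' @param inputs character vector of input paths to checksum.
#' @return invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, command, parameters = list(),
                               seeds = NULL, inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  checksums <- if (length(inputs) > 0)
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    command = command, parameters = parameters, seeds = seeds,
    input_checksums = checksums,
    software = list(package = "funcarto",
                    version = as.character(utils::packageVersion("funcarto")),
                    r_version = R.version.string),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a delimited multi-condition time series
#'
#' First column = condition label, remaining columns = node signals;
#' header row carries node ids.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a `condition_timeseries`.
#' @export
read_timeseries <- function(path, sep = "\t") {
  if (!file.exists(path)) fc_stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  condition_timeseries(as.matrix(df[, -1, drop = FALSE]), df[[1]])
}

#' Write a delimited multi-condition time series
#' @param ts a `condition_timeseries`.
#' @param path output file.
#' @param sep field separator.
#' @return invisibly, `path`.
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  stopifnot(inherits(ts, "condition_timeseries"))
  header <- paste(c("condition", colnames(ts$samples)), collapse = sep)
  body <- paste(ts$condition_labels,
                apply(matrix(fmt_num(ts$samples), nrow(ts$samples)),
                      1, paste, collapse = sep),
                sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}
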