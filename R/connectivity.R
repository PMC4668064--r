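# Multi-condition time series -> per-condition Fisher-z functional
# connectivity stack, including design-matrix residualization and
# rest-style windowing.

#' Construct a multi-condition time series
#'
#' @param samples numeric matrix \[timepoints x nodes\]; column names are
#'   node ids.
#' @param condition_labels one label per timepoint (row); sampling order
#'   is preserved.
#' @return object of class `condition_timeseries`.
#' @export
condition_timeseries <- function(samples, condition_labels) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples))
    fc_stop("time series must be numeric with no missing values")
  if (length(condition_labels) != nrow(samples))
    fc_stop(sprintf("%d condition labels for %d timepoints",
                    length(condition_labels), nrow(samples)))
  if (is.null(colnames(samples)))
    colnames(samples) <- paste0("n", seq_len(ncol(samples)))
  structure(list(samples = samples,
                 condition_labels = as.character(condition_labels)),
            class = "condition_timeseries")
}

#' @export
print.condition_timeseries <- function(x, ...) {
  cat(sprintf("condition_timeseries: %d timepoints x %d nodes, %d conditions\n",
              nrow(x$samples), ncol(x$samples),
              length(unique(x$condition_labels))))
  invisible(x)
}

#' Residualize a time series against a design matrix
#'
#' Regresses each node's series on the design matrix (an intercept is
#' always included) by ordinary least squares and returns the residuals,
#' which then feed functional connectivity estimation. Residualization is
#' idempotent. A rank-deficient design is handled by pivoted least
#' squares (the projection, hence the residuals, is still unique) with a
#' warning.
#'
#' @param ts a `condition_timeseries`.
#' @param design numeric matrix \[timepoints x regressors\], e.g. one
#'   task regressor per condition convolved with a hemodynamic response
#'   (constructed upstream and consumed here as-is). `NULL` means
#'   intercept only, i.e. mean-centering.
#' @return a `condition_timeseries` of residuals.
#' @export
residualize <- function(ts, design = NULL) {
  stopifnot(inherits(ts, "condition_timeseries"))
  Y <- ts$samples
  if (is.null(design)) {
    X <- matrix(1, nrow(Y), 1)
  } else {
    design <- as.matrix(design)
    if (nrow(design) != nrow(Y))
      fc_stop(sprintf("design has %d rows but time series has %d timepoints",
                      nrow(design), nrow(Y)))
    if (anyNA(design)) fc_stop("design matrix contains missing values")
    if (any(colSums(abs(design)) == 0))
      fc_stop("design matrix contains all-zero columns")
    X <- cbind(1, design)
  }
  fit <- stats::lm.fit(X, Y)
  if (fit$rank < ncol(X))
    warning(sprintf("design matrix is rank deficient (rank %d < %d columns)",
                    fit$rank, ncol(X)))
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(Y)
  condition_timeseries(res, ts$condition_labels)
}

#' Per-condition Pearson correlation matrices
#'
#' Computes the Pearson product-moment correlation between every pair of
#' node series, separately within each condition. Conditions are ordered
#' by first appearance in the input. A node with zero variance within a
#' condition gets zero correlations (unit self-correlation) with a
#' warning rather than propagating `NA`.
#'
#' @param ts a `condition_timeseries`; every condition must cover at
#'   least 3 timepoints.
#' @return object of class `connectivity_stack` with `transform =
#'   "raw_r"`.
#' @export
condition_correlation <- function(ts) {
  stopifnot(inherits(ts, "condition_timeseries"))
  conds <- unique(ts$condition_labels)
  counts <- table(factor(ts$condition_labels, conds))
  if (any(counts < 3))
    fc_stop(sprintf("condition(s) with fewer than 3 timepoints: %s",
                    paste(conds[counts < 3], collapse = ", ")))
  mats <- lapply(conds, function(cc) {
    X <- ts$samples[ts$condition_labels == cc, , drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    flat <- sds == 0
    if (any(flat)) {
      warning(sprintf(
        "zero-variance node(s) in condition '%s': %s; correlations set to 0",
        cc, paste(colnames(X)[flat], collapse = ", ")))
      X[, flat] <- 0
    }
    r <- suppressWarnings(stats::cor(X))
    r[is.na(r)] <- 0
    diag(r) <- 1
    r <- (r + t(r)) / 2      # guard against last-bit asymmetry
    r
  })
  connectivity_stack(mats, condition_ids = conds, transform = "raw_r")
}

#' Construct a connectivity stack
#'
#' @param matrices ordered list of symmetric N x N matrices, one per
#'   condition.
#' @param condition_ids labels, one per matrix.
#' @param transform `"raw_r"` (correlations in \[-1, 1\]) or
#'   `"fisher_z"`.
#' @param tol symmetry tolerance.
#' @return object of class `connectivity_stack`.
#' @export
connectivity_stack <- function(matrices, condition_ids = NULL,
                               transform = c("raw_r", "fisher_z"),
                               tol = 1e-10) {
  transform <- match.arg(transform)
  if (!is.list(matrices) || length(matrices) == 0)
    fc_stop("'matrices' must be a non-empty list")
  n <- nrow(matrices[[1]])
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      fc_stop(sprintf("matrix %d is not %d x %d", i, n, n))
    if (anyNA(m)) fc_stop(sprintf("matrix %d contains missing values", i))
    check_symmetric(m, tol, sprintf("matrix %d", i))
    if (transform == "raw_r" && (max(m) > 1 + 1e-12 || min(m) < -1 - 1e-12))
      fc_stop(sprintf("matrix %d has correlations outside [-1, 1]", i))
  }
  if (is.null(condition_ids))
    condition_ids <- sprintf("cond_%03d", seq_along(matrices))
  stopifnot(length(condition_ids) == length(matrices))
  structure(list(matrices = matrices,
                 condition_ids = as.character(condition_ids),
                 transform = transform,
                 node_ids = colnames(matrices[[1]]) %||%
                   paste0("n", seq_len(n))),
            class = "connectivity_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.connectivity_stack <- function(x, ...) {
  cat(sprintf("connectivity_stack: %d matrices of %d x %d (%s)\n",
              length(x$matrices), length(x$node_ids), length(x$node_ids),
              x$transform))
  invisible(x)
}

#' Fisher z-transform a connectivity stack
#'
#' Applies `atanh` entrywise to improve normality, clipping `|r|` at
#' `1 - 1e-7` so that perfect correlations stay finite. The diagonal is
#' set to 0: self-weights are meaningless for community structure and are
#' dropped before modularity evaluation.
#'
#' @param stack a `connectivity_stack` with `transform = "raw_r"`.
#' @return the stack with `transform = "fisher_z"`.
#' @export
fisher_z <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  if (stack$transform != "raw_r")
    fc_stop("fisher_z expects a raw correlation stack")
  clip <- 1 - 1e-7
  stack$matrices <- lapply(stack$matrices, function(m) {
    z <- atanh(pmin(pmax(m, -clip), clip))
    diag(z) <- 0
    z
  })
  stack$transform <- "fisher_z"
  stack
}

#' Window a resting-state series into pseudo-conditions
#'
#' Relabels timepoints into consecutive non-overlapping windows of
#' `window_len` samples (default 11, the approximate duration of a task
#' mini-block), so a continuous rest run can enter the same per-condition
#' pipeline as task data. Trailing timepoints that do not fill a window
#' are dropped: e.g. 300 timepoints at window 11 yield 27 windows with 3
#' timepoints discarded.
#'
#' @param ts a `condition_timeseries` (existing labels are ignored; the
#'   series is treated as one continuous run in input order).
#' @param window_len window length in timepoints.
#' @return a `condition_timeseries` with labels `"win_001" ...`.
#' @export
window_rest <- function(ts, window_len = 11) {
  stopifnot(inherits(ts, "condition_timeseries"), window_len >= 1)
  n <- nrow(ts$samples)
  if (n < window_len)
    fc_stop(sprintf("%d timepoints < window length %d", n, window_len))
  n_win <- n %/% window_len
  keep <- seq_len(n_win * window_len)
  labels <- sprintf("win_%03d", rep(seq_len(n_win), each = window_len))
  condition_timeseries(ts$samples[keep, , drop = FALSE], labels)
}

#' Convert a connectivity stack into a multilayer network
#'
#' @param stack a `connectivity_stack` (typically Fisher-z).
#' @inheritParams multilayer_network
#' @return a `multilayer_network` with one slice per condition.
#' @export
as_multilayer_network <- function(stack, gamma = 1, omega = 0.45,
                                  sign_policy = "truncate_negative") {
  stopifnot(inherits(stack, "connectivity_stack"))
  mats <- lapply(stack$matrices, function(m) { diag(m) <- 0; m })
  multilayer_network(mats, node_ids = stack$node_ids,
                     slice_ids = stack$condition_ids,
                     gamma = gamma, omega = omega, sign_policy = sign_policy)
}
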