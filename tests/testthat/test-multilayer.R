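# Multilayer container, Newman-Girvan null and the quality function.

test_that("newman_girvan_null matches hand-computed small cases", {
  # 2 nodes, single unit edge: k = (1, 1), m = 1 -> V = 0.5 everywhere
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  net <- multilayer_network(list(A), omega = 0)
  expect_equal(unname(newman_girvan_null(net, 1)), matrix(0.5, 2, 2))

  # unweighted 4-ring: k = 2 for all, m = 4 -> V = 4/8 = 0.5
  R <- matrix(0, 4, 4)
  R[cbind(1:4, c(2, 3, 4, 1))] <- 1
  R <- R + t(R)
  net <- multilayer_network(list(R), omega = 0)
  expect_equal(unname(newman_girvan_null(net, 1)), matrix(0.5, 4, 4))
})

test_that("newman_girvan_null satisfies the 2*m_s sum identity", {
  set.seed(11)
  for (i in 1:10) {
    A <- random_slice(7)
    net <- multilayer_network(list(A), omega = 0)
    V <- newman_girvan_null(net, 1)
    expect_equal(sum(V), sum(A), tolerance = 1e-12)
  }
})

test_that("empty slice yields a zero null matrix with a warning", {
  net <- multilayer_network(list(matrix(0, 3, 3)), omega = 0)
  expect_warning(V <- newman_girvan_null(net, 1), "empty")
  expect_equal(V, matrix(0, 3, 3))
})

test_that("modularity of two disconnected equal cliques is 0.5", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  net <- multilayer_network(list(A), gamma = 1, omega = 0)
  good <- partition(matrix(rep(c(1L, 2L), each = 4), ncol = 1))
  expect_equal(multislice_modularity(net, good), 0.5, tolerance = 1e-12)
  # the all-in-one partition scores exactly 0
  expect_equal(multislice_modularity(net, partition(matrix(1L, 8, 1))), 0,
               tolerance = 1e-12)
})

test_that("multislice modularity matches a term-by-term direct sum", {
  set.seed(23)
  for (i in 1:8) {
    net <- random_network(5, 2, gamma = runif(1, 0.5, 1.5),
                          omega = runif(1, 0, 1))
    labels <- matrix(sample(1:3, 10, replace = TRUE), 5, 2)
    expect_equal(multislice_modularity(net, partition(labels)),
                 brute_force_modularity(net, labels),
                 tolerance = 1e-12)
  }
})

test_that("quality is invariant under community relabeling", {
  set.seed(31)
  net <- random_network(6, 3, omega = 0.4)
  labels <- matrix(sample(1:4, 18, replace = TRUE), 6, 3)
  remap <- sample(100, 4)    # arbitrary bijective relabeling
  q1 <- multislice_modularity(net, partition(labels))
  q2 <- multislice_modularity(net, partition(matrix(remap[labels], 6, 3)))
  q3 <- multislice_modularity(net, canonicalize_partition(labels))
  expect_equal(q1, q2, tolerance = 1e-12)
  expect_equal(q1, q3, tolerance = 1e-12)
})

test_that("with omega = 0, Q decomposes into weighted per-slice modularities", {
  set.seed(47)
  for (i in 1:5) {
    net <- random_network(6, 3, omega = 0)
    labels <- matrix(sample(1:3, 18, replace = TRUE), 6, 3)
    q <- multislice_modularity(net, partition(labels))
    # independent single-slice route: per-slice Newman-Girvan modularity,
    # recombined with weights 2*m_s / 2*mu
    mu <- quality_context(net)$mu
    per_slice <- vapply(seq_len(3), function(s) {
      A <- net$slices[[s]]
      k <- rowSums(A); m <- sum(k) / 2
      g <- labels[, s]
      sum((A - outer(k, k) / (2 * m))[outer(g, g, "==")]) / (2 * m)
    }, numeric(1))
    m_s <- quality_context(net)$slice_totals
    expect_equal(q, sum(per_slice * m_s / mu), tolerance = 1e-9)
  }
})

test_that("all-singletons quality with omega = 0 matches the closed form", {
  set.seed(53)
  net <- random_network(5, 2, omega = 0)
  singletons <- matrix(seq_len(10), 5, 2)
  q <- multislice_modularity(net, partition(singletons))
  ctx <- quality_context(net)
  expected <- -sum(vapply(1:2, function(s) {
    k <- ctx$strengths[, s]
    net$gamma[s] * sum(k^2) / (2 * ctx$slice_totals[s])
  }, numeric(1))) / (2 * ctx$mu)
  expect_equal(q, expected, tolerance = 1e-12)
})

test_that("sign policy truncates negatives and never increases slice totals", {
  A <- matrix(c(0, -0.3, -0.3, 0), 2, 2)
  B <- matrix(c(0, 0.2, 0.2, 0), 2, 2)
  net <- multilayer_network(list(A, B), sign_policy = "truncate_negative")
  expect_equal(net$slices[[1]], matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(net$slices[[2]], B, ignore_attr = TRUE)
  keep <- multilayer_network(list(A, B), sign_policy = "keep")
  expect_equal(keep$slices[[1]], A, ignore_attr = TRUE)
  set.seed(7)
  for (i in 1:5) {
    M <- random_slice(6) - 0.5
    kept <- multilayer_network(list(M), sign_policy = "keep")
    trunc <- multilayer_network(list(M), sign_policy = "truncate_negative")
    expect_true(all(trunc$slices[[1]] >= 0))
    # truncated total equals the positive part's total, never less than
    # the signed total, and a second application changes nothing
    pos <- kept$slices[[1]]; pos[pos < 0] <- 0
    expect_equal(trunc$slices[[1]], pos, ignore_attr = TRUE)
    expect_gte(sum(trunc$slices[[1]]), sum(kept$slices[[1]]))
    expect_identical(apply_sign_policy(trunc)$slices, trunc$slices)
  }
})

test_that("network validation rejects malformed slices", {
  expect_error(multilayer_network(list(matrix(1:6, 2, 3))), "square")
  M <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(multilayer_network(list(M)), "symmetric")
  expect_error(multilayer_network(list(matrix(NA_real_, 2, 2))), "missing")
  expect_error(
    multilayer_network(list(matrix(0, 2, 2), matrix(0, 3, 3))),
    "dimensions")
})
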