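# Allegiance, coefficients, permutation null, roles and edge flags.

test_that("module allegiance handles unanimous and split ensembles", {
  lab <- matrix(c(1, 1, 2, 2), 4, 3)      # identical in all slices
  ens <- ensemble_from_labels(list(lab, lab))
  P <- module_allegiance(ens)$P
  expect_equal(unname(P), rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                c(0, 0, 1, 1), c(0, 0, 1, 1)))
  # pair together in all slices of run 1, never in run 2 -> 0.5
  lab2 <- matrix(c(1, 2, 3, 4), 4, 3)
  P2 <- module_allegiance(ensemble_from_labels(list(lab, lab2)))$P
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[3, 4], 0.5)
  expect_equal(P2[1, 3], 0)
})

test_that("module allegiance matches a direct double-loop count", {
  set.seed(61)
  labs <- replicate(4, matrix(sample(1:3, 15, TRUE), 5, 3),
                    simplify = FALSE)
  P <- module_allegiance(ensemble_from_labels(labs))$P
  # independent counting oracle
  for (i in 1:5) for (j in 1:5) {
    count <- 0
    for (o in 1:4) for (t in 1:3)
      if (labs[[o]][i, t] == labs[[o]][j, t]) count <- count + 1
    expect_equal(P[i, j], count / 12)
  }
})

test_that("allegiance invariants hold on random ensembles", {
  set.seed(71)
  for (rep in 1:5) {
    labs <- replicate(6, matrix(sample(1:4, 24, TRUE), 8, 3),
                      simplify = FALSE)
    P <- module_allegiance(ensemble_from_labels(labs))$P
    expect_equal(P, t(P))
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(unname(diag(P)), rep(1, 8))
  }
})

test_that("flexibility counts label transitions", {
  expect_equal(flexibility(matrix(1L, 4, 5))$f, rep(0, 4))
  alternating <- matrix(rep(c(1L, 2L), 3)[1:5], 1, 5, byrow = TRUE)
  expect_equal(flexibility(alternating)$f, 1)
  expect_equal(flexibility(matrix(c(1, 1, 2, 2, 3), 1, 5))$f, 0.5)
  expect_error(flexibility(matrix(1L, 3, 1)), "2 slices")
  # ensemble flexibility averages runs
  e <- ensemble_from_labels(list(matrix(1L, 2, 3),
                                 matrix(c(1, 1, 2, 1, 1, 2), 2, 3,
                                        byrow = TRUE)))
  expect_equal(flexibility(e)$f, c(0.25, 0.25))  # mean of runs (0, 0.5)
})

test_that("region coefficients: degenerate P and the conservation identity", {
  sys <- system_map(stats::setNames(c("A", "A", "B", "B", "B"),
                                    paste0("n", 1:5)))
  ones <- matrix(1, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  rc <- region_coefficients(ones, sys)
  expect_equal(rc$recruitment, rep(1, 5))
  expect_equal(rc$integration, rep(1, 5))
  eye <- diag(5); dimnames(eye) <- dimnames(ones)
  rc <- region_coefficients(eye, sys)
  expect_equal(rc$recruitment, 1 / c(2, 2, 3, 3, 3))
  expect_equal(rc$integration, rep(0, 5))
  # conservation: n_S R_i + (N - n_S) I_i = row sum of P, exactly
  set.seed(83)
  P <- random_slice(5); diag(P) <- 1
  dimnames(P) <- dimnames(ones)
  rc <- region_coefficients(P, sys)
  nS <- sys$sizes[rc$system]
  expect_equal(unname(nS * rc$recruitment + (5 - nS) * rc$integration),
               unname(rowSums(P)), tolerance = 1e-12)
  # equivalent identity: the weighted mean recovers the row mean
  expect_equal(unname((nS * rc$recruitment + (5 - nS) * rc$integration) / 5),
               unname(rowMeans(P)), tolerance = 1e-12)
})

test_that("exclude-self recruitment averages over the other members", {
  sys <- system_map(stats::setNames(c("A", "A", "B", "B"), paste0("n", 1:4)))
  P <- diag(4); P[1, 2] <- P[2, 1] <- 0.5
  dimnames(P) <- list(paste0("n", 1:4), paste0("n", 1:4))
  rc <- region_coefficients(P, sys, include_self = FALSE)
  expect_equal(rc$recruitment, c(0.5, 0.5, 0, 0))
})

test_that("system coefficients: block structure and weighted-average identity", {
  sys <- system_map(stats::setNames(rep(c("A", "B", "C"), times = c(2, 3, 4)),
                                    paste0("n", 1:9)))
  ones <- matrix(1, 9, 9, dimnames = list(paste0("n", 1:9), paste0("n", 1:9)))
  sc <- system_coefficients(ones, sys)
  expect_equal(unname(sc$recruitment), rep(1, 3))
  expect_equal(unname(sc$integration), rep(1, 3))
  # block-diagonal binary P aligned with the systems
  blockP <- (outer(sys$assignment, sys$assignment, "==")) * 1
  dimnames(blockP) <- dimnames(ones)
  sc <- system_coefficients(blockP, sys)
  expect_equal(unname(sc$recruitment), rep(1, 3))
  expect_equal(unname(sc$integration), rep(0, 3))
  # I_S is the size-weighted average of pairwise integrations
  set.seed(97)
  P <- random_slice(9); diag(P) <- 1
  dimnames(P) <- dimnames(ones)
  sc <- system_coefficients(P, sys)
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    w <- sys$sizes[others]
    expect_equal(unname(sc$integration[k]),
                 unname(sum(sc$pairwise_integration[k, others] * w) / sum(w)),
                 tolerance = 1e-12)
  }
})

test_that("permutation null matches the exhaustive assignment average", {
  # 4 nodes, 2 systems of 2: only 3 distinct unordered splits; the null
  # mean must equal the average over all 4!  relabelings
  ids <- paste0("n", 1:4)
  sys <- system_map(stats::setNames(c("A", "A", "B", "B"), ids))
  set.seed(113)
  P <- random_slice(4); diag(P) <- 1
  dimnames(P) <- list(ids, ids)
  null <- permutation_null(P, sys, n_perm = 4000, seed = 5) |>
    suppressWarnings()
  # exhaustive oracle: every permutation of the labels
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_perms(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  vals_R <- vals_I <- c()
  for (pm in all_perms(1:4)) {
    s2 <- system_map(stats::setNames(c("A", "A", "B", "B")[pm], ids))
    s2$systems <- sys$systems; s2$sizes <- sys$sizes
    sc <- system_coefficients(P, s2)
    vals_R <- c(vals_R, sc$recruitment["A"])
    vals_I <- c(vals_I, sc$integration["A"])
  }
  expect_equal(mean(null$recruitment[, "A"]), mean(vals_R),
               tolerance = 0.02)
  expect_equal(mean(null$integration[, "A"]), mean(vals_I),
               tolerance = 0.02)
})

test_that("permutation null is deterministic and degenerate P gives flat CIs", {
  ids <- paste0("n", 1:6)
  sys <- system_map(stats::setNames(rep(c("A", "B"), each = 3), ids))
  ones <- matrix(1, 6, 6, dimnames = list(ids, ids))
  n1 <- permutation_null(ones, sys, n_perm = 200, seed = 3)
  n2 <- permutation_null(ones, sys, n_perm = 200, seed = 3)
  expect_identical(n1$recruitment, n2$recruitment)
  expect_true(all(n1$recruitment == 1) && all(n1$integration == 1))
  expect_true(all(n1$ci$recruitment == 1))
  expect_warning(permutation_null(ones, sys, n_perm = 50, seed = 1),
                 "replicates")
})

test_that("null distributions of equal-size systems are exchangeable", {
  set.seed(131)
  sys <- four_system_map(3, 4)
  P <- random_slice(12); diag(P) <- 1
  dimnames(P) <- list(names(sys$assignment), names(sys$assignment))
  null <- permutation_null(P, sys, n_perm = 2000, seed = 7)
  means_R <- colMeans(null$recruitment)
  means_I <- colMeans(null$integration)
  expect_lt(max(means_R) - min(means_R), 0.02)
  expect_lt(max(means_I) - min(means_I), 0.02)
})

test_that("role classification covers the nine-cell grid", {
  coeffs <- list(recruitment = c(A = 0.9, B = 0.5, C = 0.9),
                 integration = c(A = 0.1, B = 0.5, C = 0.9))
  fake_band <- function(lo, hi, systems)
    matrix(rep(c(lo, hi), length(systems)), 2,
           dimnames = list(c("2.5%", "97.5%"), systems))
  null <- list(ci = list(recruitment = fake_band(0.4, 0.6, c("A", "B", "C")),
                         integration = fake_band(0.4, 0.6, c("A", "B", "C"))))
  roles <- classify_roles(coeffs, null)
  expect_equal(unname(roles["A"]), "stable loner")
  expect_equal(unname(roles["B"]), "unstable connector")
  expect_equal(unname(roles["C"]), "stable integrator")
  low <- list(recruitment = c(A = 0.1, B = 0.1, C = 0.1),
              integration = c(A = 0.1, B = 0.5, C = 0.9))
  roles <- classify_roles(low, null)
  expect_equal(unname(roles),
               c("ephemeral loner", "ephemeral connector",
                 "ephemeral integrator"))
})

test_that("edge flags mark uniform pairwise integration as ns", {
  ids <- paste0("n", 1:9)
  sys <- system_map(stats::setNames(rep(c("A", "B", "C"), each = 3), ids))
  # constant off-diagonal allegiance: permutations cannot change anything
  P <- matrix(0.4, 9, 9); diag(P) <- 1
  dimnames(P) <- list(ids, ids)
  sc <- system_coefficients(P, sys)
  null <- permutation_null(P, sys, n_perm = 200, seed = 11)
  flags <- flag_integration_edges(sc, null)
  expect_true(all(flags[upper.tri(flags)] == "ns"))
})
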