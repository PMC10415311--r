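test_that("single slice with omega = 0 reduces to Newman-Girvan modularity", {
  # two disconnected 2-cliques: Q = 0.5 under the matching partition
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[3, 4] <- A[4, 3] <- 1
  part <- matrix(c(1, 1, 2, 2), 4, 1)
  expect_equal(multislice_q(list(A), part, omega = 0), 0.5)
  # hand-computed 4-node toy with asymmetric weights
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- 2
  B[2, 3] <- B[3, 2] <- 1
  B[3, 4] <- B[4, 3] <- 3
  g <- c(1, 1, 2, 2)
  two_m <- sum(B)
  k <- rowSums(B)
  hand <- sum((B - outer(k, k) / two_m)[outer(g, g, "==")]) / two_m
  expect_equal(multislice_q(list(B), matrix(g), omega = 0), hand)
})

test_that("one community leaves only the coupling term", {
  set.seed(1)
  sl <- list(random_block_slice(5), random_block_slice(5))
  part <- matrix(1L, 5, 2)
  # intra-slice sum of (A - kk'/2m) over all pairs is 0 per slice
  sup <- mitonet:::supra_modularity(sl, 1, 0.1)
  q <- multislice_q(sl, part, omega = 0.1)
  expect_equal(q, 0.1 * 5 * 2 * 1 / sup$two_mu)
})

test_that("multislice_q equals the brute-force oracle on all partitions", {
  # 4 areas x 2 slices: all 4140 set partitions of the 8 node-layers
  set.seed(21)
  sl <- list(random_block_slice(4), random_block_slice(4))
  parts <- all_partitions(8)
  or <- oracle_supra_B(sl, 1, 0.1)
  for (g in parts[seq(1, length(parts), by = 7)]) { # every 7th: 592 checks
    gm <- matrix(g, 4, 2)
    expect_equal(multislice_q(sl, gm, omega = 0.1),
                 oracle_multislice_q(sl, gm, omega = 0.1))
  }
  # and the vectorized oracle agrees with the loop oracle
  g0 <- matrix(parts[[123]], 4, 2)
  expect_equal(sum(or$B[outer(as.vector(g0), as.vector(g0), "==")]) / or$two_mu,
               oracle_multislice_q(sl, g0, omega = 0.1))
})

test_that("Q is invariant under community label permutation", {
  set.seed(2)
  sl <- list(random_block_slice(6), random_block_slice(6))
  g <- matrix(sample(1:3, 12, replace = TRUE), 6, 2)
  relab <- c(2L, 3L, 1L)
  expect_equal(multislice_q(sl, g), multislice_q(sl, matrix(relab[g], 6, 2)))
})

test_that("omega = 0 decouples into independent per-slice optima", {
  set.seed(3)
  sl <- list(random_block_slice(8, within = 0.9, between = 0, noise = 0.02),
             random_block_slice(8, within = 0.9, between = 0, noise = 0.02))
  p <- optimize_communities(sl, omega = 0, seed = 5)
  for (s in 1:2) {
    single <- optimize_communities(sl[s], omega = 0, seed = 5)
    expect_equal(mitonet:::canonical_labels(p$assignment[, s]),
                 mitonet:::canonical_labels(single$assignment[, 1]))
  }
})

test_that("ideal block structure is recovered exactly and coherently", {
  blocks <- rep(1:2, each = 4)
  A <- ifelse(outer(blocks, blocks, "=="), 0.9, 0)
  diag(A) <- 0
  sl <- list(A, A)
  p <- optimize_communities(sl, omega = 0.1, seed = 2)
  expect_equal(adjusted_rand_index(p$assignment[, 1], blocks), 1)
  expect_equal(p$assignment[, 1], p$assignment[, 2])
  # huge coupling forces slice-coherent labels even on differing slices
  set.seed(9)
  sl2 <- list(random_block_slice(6), random_block_slice(6, within = 0.2))
  p2 <- optimize_communities(sl2, omega = 50, seed = 1)
  expect_equal(p2$assignment[, 1], p2$assignment[, 2])
})

test_that("optimizer attains the exhaustive maximum on small toys", {
  parts <- all_partitions(10)
  set.seed(33)
  hits <- logical(0)
  for (trial in 1:5) {
    sl <- list(random_block_slice(5), random_block_slice(5))
    or <- oracle_supra_B(sl, 1, 0.1)
    qmax <- max(vapply(parts, function(g)
      sum(or$B[outer(g, g, "==")]) / or$two_mu, 0))
    hits <- c(hits, vapply(1:20, function(s)
      abs(optimize_communities(sl, seed = s)$q - qmax) < 1e-10, TRUE))
  }
  expect_gte(mean(hits), 0.95)
})

test_that("module allegiance counts co-assignment fractions", {
  mk_part <- function(m) structure(list(assignment = m, q = 0,
                                        params = list()),
                                   class = "multilayer_partition")
  # identical labels in every slice: within 1, between 0
  a <- mk_part(matrix(c(1, 1, 2, 2), 4, 3))
  al <- module_allegiance(a)
  expect_equal(al[1, 2], 1)
  expect_equal(al[1, 3], 0)
  expect_equal(diag(al), rep(1, 4), ignore_attr = TRUE)
  # together in 3 of 6 slices -> 0.5
  m <- cbind(matrix(c(1, 1), 2, 3), matrix(c(1, 2), 2, 3))
  expect_equal(module_allegiance(mk_part(m))[1, 2], 0.5)
  # symmetric on random partitions
  set.seed(4)
  r <- mk_part(matrix(sample(1:3, 12, TRUE), 4, 3))
  expect_identical(module_allegiance(r), t(module_allegiance(r)))
})

test_that("consensus converges on clean structure and is run-order invariant", {
  blocks <- rep(1:3, times = c(6, 7, 4))
  A <- ifelse(outer(blocks, blocks, "=="), 0.8, 0.05)
  diag(A) <- 0
  dimnames(A) <- list(mito_areas(), mito_areas())
  sl <- structure(list(A, A, A), areas = mito_areas(),
                  class = "multilayer_network")
  p <- consensus_communities(sl, n_runs = 10, seed = 7)
  expect_true(attr(p, "converged"))
  expect_equal(attr(p, "n_iter"), 1L)
  expect_equal(adjusted_rand_index(p, blocks), 1)
  # same seed, same result; allegiance averaging is order-free
  p2 <- consensus_communities(sl, n_runs = 10, seed = 7)
  expect_identical(unclass(p), unclass(p2))
})

test_that("structureless cohorts do not reproduce the planted partition", {
  cf <- synthetic_config(within_block_r = 0.101, between_block_r = 0.1,
                         seed = 13)
  co <- generate_cohort(cf)
  sl <- per_feature_slices(co)
  p <- suppressWarnings(consensus_communities(sl, n_runs = 15, seed = 2))
  expect_lt(adjusted_rand_index(p, cf$planted_partition[names(p)]), 1)
})
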