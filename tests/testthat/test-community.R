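test_that("signed Louvain recovers obvious block structure", {
  # two 4-node all-positive cliques, no inter-clique edges
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 0.9
  w[5:8, 5:8] <- 0.9
  diag(w) <- 0
  p <- louvainSigned(w, gamma = 1, seed = 1)
  expect_equal(nCommunities(p), 2L)
  m <- membership(p)
  expect_length(unique(m[1:4]), 1L)
  expect_length(unique(m[5:8]), 1L)
  expect_false(m[1] == m[5])
  # exhaustive search confirms this is the optimum
  oracle <- exhaustive_best_modularity(w, gamma = 1)
  expect_equal(signedModularity(w, p, gamma = 1), oracle$q,
               tolerance = 1e-12)

  # complete uniform all-positive network: no internal structure
  u <- matrix(0.5, 6, 6); diag(u) <- 0
  expect_equal(nCommunities(louvainSigned(u, gamma = 1, seed = 2)), 1L)

  # all-zero network: single community with a warning
  expect_warning(p0 <- louvainSigned(matrix(0, 5, 5), seed = 3),
                 "all-zero")
  expect_equal(nCommunities(p0), 1L)
})

test_that("Louvain Q is never below the trivial partitions and matches exhaustive search", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:8, 1)
    w <- random_signed_matrix(n)
    if (all(w == 0)) next
    gamma <- sample(c(0.5, 1, 1.5), 1)
    p <- louvainSigned(w, gamma = gamma, seed = rep, restarts = 10)
    q <- signedModularity(w, p, gamma = gamma)
    expect_gte(q, signedModularity(w, seq_len(n), gamma) - 1e-12)
    expect_gte(q, signedModularity(w, rep(1L, n), gamma) - 1e-12)
    oracle <- exhaustive_best_modularity(w, gamma = gamma)
    expect_equal(q, oracle$q, tolerance = 1e-9)
  }
})

test_that("AMI matches reference values and its invariances", {
  # frozen reference values (scikit-learn adjusted_mutual_info_score,
  # arithmetic averaging)
  expect_equal(ami(c(1, 1, 2, 2, 3, 3), c(1, 1, 2, 2, 3, 3)), 1)
  expect_equal(ami(c(1, 1, 2, 2, 3, 3), c(3, 3, 1, 1, 2, 2)), 1)
  expect_equal(ami(c(1, 1, 1, 2, 2, 2), c(1, 2, 1, 2, 1, 2)),
               -0.1111111111111109, tolerance = 1e-12)
  expect_equal(ami(c(1, 1, 2, 2, 2, 3, 3, 3, 3), c(1, 1, 1, 2, 2, 2, 3, 3, 3)),
               0.4086705097217218, tolerance = 1e-12)
  expect_equal(ami(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1), c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)),
               -0.35118577459781486, tolerance = 1e-12)
  expect_equal(ami(c(1, 1, 1, 1, 2, 2, 2, 2), c(1, 1, 2, 2, 3, 3, 4, 4)),
               0.533333333333334, tolerance = 1e-12)

  # symmetry on random partitions
  set.seed(5)
  for (rep in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ami(a, b), ami(b, a), tolerance = 1e-12)
  }

  # chance adjustment: independent partitions of many nodes score near 0
  set.seed(6)
  a <- sample(1:4, 1000, replace = TRUE)
  b <- sample(1:4, 1000, replace = TRUE)
  expect_lt(abs(ami(a, b)), 0.05)

  expect_error(ami(c(1, 2), c(1, 2, 3)), "length mismatch")
})

test_that("coclassification counts shared assignments pair by pair", {
  regions <- paste0("R", 1:4)
  p1 <- partition(c(1, 1, 2, 2), regions)
  p2 <- partition(c(1, 1, 2, 2), regions)
  cc <- coclassification(list(p1, p2))
  expect_true(all(cc$matrix %in% c(0, 1)))
  expect_equal(diag(cc$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cc$matrix, t(cc$matrix))

  # two partitions differing in one region's membership: direct count
  p3 <- partition(c(1, 2, 2, 2), regions)
  cc2 <- coclassification(list(p1, p3))
  expect_equal(cc2$matrix["R1", "R2"], 0.5)
  expect_equal(cc2$matrix["R3", "R4"], 1)
  expect_equal(cc2$matrix["R1", "R3"], 0)
  expect_equal(cc2$matrix["R2", "R3"], 0.5)
  expect_equal(unname(cc2$region_mean["R4"]), mean(c(0, 0.5, 1)))

  expect_error(coclassification(list(p1)), "at least two")
})

test_that("mrcc handles degenerate and unanimous inputs", {
  expect_warning(res0 <- mrcc(matrix(0, 6, 6), n_partitions = 100, seed = 1),
                 "degenerate")
  expect_equal(nCommunities(res0), 1L)

  # strongly-modular toy: consensus equals the obvious two blocks and the
  # coassignment of within-block pairs is high
  w <- matrix(-0.2, 10, 10)
  w[1:5, 1:5] <- 0.9
  w[6:10, 6:10] <- 0.9
  diag(w) <- 0
  res <- mrcc(w, n_partitions = 100, seed = 4, n_animals = 20)
  m <- membership(consensusPartition(res))
  expect_equal(nCommunities(res), 2L)
  expect_length(unique(m[1:5]), 1L)
  A <- coassignment(res)
  expect_equal(diag(A), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(A >= 0 & A <= 1))
  expect_gt(mean(A[1:5, 1:5][upper.tri(diag(5))]),
            mean(A[1:5, 6:10]))

  # deterministic given the seed
  res2 <- mrcc(w, n_partitions = 100, seed = 4, n_animals = 20)
  expect_identical(membership(consensusPartition(res)),
                   membership(consensusPartition(res2)))
  expect_identical(coassignment(res), coassignment(res2))

  # community count always within [1, number of regions]
  expect_gte(nCommunities(res), 1L)
  expect_lte(nCommunities(res), 10L)
})

test_that("mrcc recovers a planted three-module structure from group data", {
  planted <- partition(plantedPartition(27, 3), defaultRegionLabels())
  hits <- vapply(1:5, function(s) {
    tab <- generateGroup(groupSimSpec(12, rho_within = 0.8, rho_between = 0,
                                      seed = s))
    res <- mrcc(covarianceNetwork(tab), n_partitions = 200, seed = s)
    ami(consensusPartition(res), planted) >= 0.9
  }, logical(1))
  expect_gte(sum(hits), 4L)
})

test_that("partition canonical labelling and hierarchy are coherent", {
  p <- partition(c(5, 5, 9, 9, 7), paste0("R", 1:5))
  expect_equal(unname(membership(p)), c(1L, 1L, 2L, 2L, 3L))

  w <- matrix(-0.2, 10, 10)
  w[1:5, 1:5] <- 0.9; w[6:10, 6:10] <- 0.9; diag(w) <- 0
  res <- mrcc(w, n_partitions = 100, seed = 9, n_animals = 20)
  h <- hierarchyPartitions(res)
  expect_identical(membership(h[[length(h)]]),
                   membership(consensusPartition(res)))
  # hierarchy is coarse to fine
  ks <- vapply(h, nCommunities, integer(1))
  expect_true(all(diff(ks) >= 0))
})
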