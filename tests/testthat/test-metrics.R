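make_net <- function(w) {
  labs <- paste0("R", seq_len(nrow(w)))
  dimnames(w) <- list(labs, labs)
  new("CovarianceNetwork", groupId = "toy", regionLabels = labs,
      weights = w, nAnimals = 10L)
}

test_that("density, degree and signed strengths satisfy their identities", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.5; w[1, 3] <- -0.3; w[2, 3] <- 0.2
  w <- w + t(w)
  net <- make_net(w)

  d <- networkDensity(net)
  expect_equal(d$edge_count, 3L)
  expect_equal(d$fraction, 3 / 6)

  deg <- nodalDegree(net)
  expect_equal(unname(deg), c(2L, 2L, 2L, 0L))
  expect_equal(sum(deg), 2L * d$edge_count)        # handshake identity

  s <- nodalStrength(net)
  expect_equal(s$strength_pos[1], 0.5)
  expect_equal(s$strength_neg[1], 0.3)
  # s+ - s- equals the plain weighted strength
  expect_equal(s$strength_pos - s$strength_neg, rowSums(w),
               ignore_attr = TRUE)

  empty <- make_net(matrix(0, 4, 4))
  expect_equal(networkDensity(empty)$edge_count, 0L)
  expect_equal(networkDensity(empty)$fraction, 0)
})

test_that("signed clustering matches the spec cases", {
  # perfect positive triangle at the network maximum weight
  w <- matrix(0.7, 3, 3); diag(w) <- 0
  expect_equal(unname(signedClustering(w)), rep(1, 3))

  # star graph: no triangles anywhere
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- c(0.4, -0.6, 0.8, 0.1)
  star <- star + t(star)
  expect_equal(unname(signedClustering(star)), rep(0, 5))

  # all-zero network: defined as 0
  expect_equal(unname(signedClustering(matrix(0, 4, 4))), rep(0, 4))
})

test_that("signed clustering equals brute-force enumeration on random networks", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    w <- random_signed_matrix(n)
    expect_equal(unname(signedClustering(w)), brute_signed_clustering(w),
                 tolerance = 1e-12)
  }
})

test_that("hub identification returns the top quartile with deterministic ties", {
  # 27 metric values: exactly 7 hubs
  metric <- setNames(as.numeric(1:27), paste0("R", 1:27))
  hubs <- identifyHubs(metric)
  expect_length(hubs, 7L)
  expect_identical(hubs, paste0("R", 27:21))

  # all-equal metric: first 7 regions by index order
  flat <- setNames(rep(1, 27), paste0("R", 1:27))
  expect_identical(identifyHubs(flat), paste0("R", 1:7))

  # strength mode uses cumulative absolute strength
  tab <- generateGroup(groupSimSpec(12, seed = 8))
  net <- covarianceNetwork(tab)
  s <- nodalStrength(net)
  manual <- identifyHubs(setNames(s$strength_pos + s$strength_neg,
                                  s$region))
  expect_identical(identifyHubs(net, mode = "strength"), manual)
})

test_that("degree and strength are monotone under stricter thresholds", {
  tab <- generateGroup(groupSimSpec(12, rho_within = 0.7, rho_between = 0.1,
                                    seed = 21))
  net <- covarianceNetwork(tab)
  net <- withEdgeSignificance(net, tab, n_perm = 400, seed = 22)
  t05 <- thresholdNetwork(net, 0.05)
  t01 <- thresholdNetwork(net, 0.01)
  expect_true(all(nodalDegree(t01) <= nodalDegree(t05)))
  s05 <- nodalStrength(t05); s01 <- nodalStrength(t01)
  expect_true(all(s01$strength_pos <= s05$strength_pos + 1e-12))
  expect_true(all(s01$strength_neg <= s05$strength_neg + 1e-12))
})
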