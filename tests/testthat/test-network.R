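test_that("computeSUVR is the activity ratio with a guarded reference", {
  expect_equal(computeSUVR(2.4, 1.2), 2)
  x <- runif(10, 0.5, 3)
  expect_equal(computeSUVR(x, x), rep(1, 10))
  expect_error(computeSUVR(1.0, 0.0), "reference")
})

test_that("zscore normalizes every region to mean 0 and sample SD 1", {
  tab <- toy_table(cbind(c(1, 2, 3), c(2, 4, 9), c(1, 5, 6)))
  z <- t(SummarizedExperiment::assay(zscoreByRegion(tab), "zscore"))
  expect_equal(z[, 1], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(apply(z, 2, sd), rep(1, 3), ignore_attr = TRUE)

  # idempotence: z-scoring an already z-scored table changes nothing
  z2 <- SummarizedExperiment::assay(
    zscoreByRegion(zscoreByRegion(tab)), "zscore")
  expect_equal(t(z2), z, tolerance = 1e-12)

  const <- toy_table(cbind(c(1, 1, 1), c(1, 2, 3)))
  expect_error(zscoreByRegion(const), "R1")
})

test_that("covariance network is Pearson r with zero diagonal, 351 edges at 27 regions", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  net <- covarianceNetwork(toy_table(x))
  w <- edgeWeights(net)
  expect_equal(w["R1", "R2"], 1)
  expect_equal(w["R1", "R3"], -1)
  expect_equal(diag(w), rep(0, 3), ignore_attr = TRUE)

  tab <- generateGroup(groupSimSpec(12, seed = 5))
  net27 <- covarianceNetwork(tab)
  expect_equal(sum(upper.tri(edgeWeights(net27))), 351L)
  expect_equal(edgeWeights(net27), t(edgeWeights(net27)))

  # Pearson is affine-invariant: same network from z-scored values
  z <- t(SummarizedExperiment::assay(zscoreByRegion(tab), "zscore"))
  expect_equal(edgeWeights(covarianceNetwork(z)),
               unname(edgeWeights(net27)), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("edge significance p-values respect the add-one bound and null center", {
  tab <- generateGroup(groupSimSpec(10, rho_within = 0.9, rho_between = 0,
                                    n_regions = 8,
                                    planted_partition = plantedPartition(8, 2),
                                    seed = 11))
  n_perm <- 200
  p <- edgeSignificance(tab, n_perm = n_perm, seed = 2)
  off <- p[upper.tri(p)]
  expect_true(all(off >= 1 / (n_perm + 1)))
  expect_true(all(off <= 1))
  expect_equal(p, t(p))
  # strongly coupled within-module edges are significant
  expect_lt(p[1, 2], 0.05)
})

test_that("thresholding keeps signed weights, nests across levels, flags fragmentation", {
  tab <- generateGroup(groupSimSpec(12, rho_within = 0.8, rho_between = 0,
                                    seed = 3))
  net <- covarianceNetwork(tab)
  expect_error(thresholdNetwork(net, 0.05), "edge p-values")
  net <- withEdgeSignificance(net, tab, n_perm = 400, seed = 9)

  t_all <- thresholdNetwork(net, 1.0)
  expect_equal(networkDensity(t_all)$edge_count, 351L)

  t05 <- thresholdNetwork(net, 0.05)
  t01 <- thresholdNetwork(net, 0.01)
  e05 <- edgeWeights(t05) != 0
  e01 <- edgeWeights(t01) != 0
  expect_true(all(e05[e01]))                      # 0.01 edges nested in 0.05
  kept <- edgeWeights(t05) != 0
  expect_equal(edgeWeights(t05)[kept], edgeWeights(net)[kept])  # signed weights retained

  # a network with an isolated node is fragmented
  w <- edgeWeights(net)
  ep <- edgePValues(net)
  ep[1, ] <- 1; ep[, 1] <- 1                       # cut node 1 loose
  net2 <- net; net2@edgeP <- ep
  expect_true(isFragmented(thresholdNetwork(net2, 0.05)))
})

test_that("random-shift null is calibrated near the nominal level", {
  # null tables: no planted covariance at all; fraction of edges declared
  # significant at 0.05 should track 0.05
  rates <- vapply(1:6, function(s) {
    tab <- generateGroup(groupSimSpec(12, rho_within = 0, rho_between = 0,
                                      n_regions = 15,
                                      planted_partition = plantedPartition(15, 3),
                                      seed = 100 + s))
    p <- edgeSignificance(tab, n_perm = 400, seed = 200 + s)
    mean(p[upper.tri(p)] < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.08)
})
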