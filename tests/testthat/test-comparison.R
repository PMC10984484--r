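test_that("two-sample KS statistic matches direct ECDF enumeration", {
  same <- ksTwoSample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)

  disjoint <- ksTwoSample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disjoint$statistic, 1)

  # x = {1,2}, y = {1.5,2.5}: sup |ECDF difference| = 0.5
  expect_equal(ksTwoSample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)

  expect_error(ksTwoSample(numeric(0), 1:3), "nonempty")
})

test_that("edgewise permutation test is symmetric and null on identical groups", {
  tab <- generateGroup(groupSimSpec(8, n_regions = 10,
                                    planted_partition = plantedPartition(10, 2),
                                    seed = 31))
  x <- suvrMatrix(tab)
  tabA <- toy_table(x, group_id = "A")
  tabB <- toy_table(x, group_id = "B")    # same animals relabeled
  tabB <- uptakeTable(x, region_labels = paste0("R", 1:10),
                      animal_ids = paste0("B", 1:8), group_id = "B")
  p <- edgewisePermutationTest(tabA, tabB, n_perm = 200, seed = 1)
  expect_true(all(p[upper.tri(p)] > 0.9))   # observed difference is exactly 0

  # swapping the groups leaves the two-sided p matrix unchanged
  tabC <- generateGroup(groupSimSpec(8, n_regions = 10,
                                     planted_partition = plantedPartition(10, 2),
                                     seed = 32))
  p1 <- edgewisePermutationTest(tabA, tabC, n_perm = 150, seed = 5)
  p2 <- edgewisePermutationTest(tabC, tabA, n_perm = 150, seed = 5)
  expect_equal(p1, p2)
})

test_that("edgewise permutation test type-I error is near nominal", {
  rates <- vapply(1:5, function(s) {
    spec <- function(seed) groupSimSpec(10, n_regions = 12,
                                        planted_partition = plantedPartition(12, 3),
                                        rho_within = 0.5, rho_between = 0.1,
                                        seed = seed)
    a <- generateGroup(spec(400 + s), group_id = "a")
    b <- generateGroup(spec(500 + s), group_id = "b")
    p <- edgewisePermutationTest(a, b, n_perm = 300, seed = 600 + s)
    mean(p[upper.tri(p)] < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.08)
})

test_that("BH adjustment matches an independent step-up implementation", {
  # worked example: all three pass the step-up rule p(k) <= k q / m
  ex <- fdrBH(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(ex$rejected))

  expect_false(any(fdrBH(rep(1, 10))$rejected))
  expect_true(fdrBH(0.04, q = 0.05)$rejected)

  set.seed(9)
  for (rep in 1:20) {
    p <- runif(351)^sample(1:3, 1)
    mine <- fdrBH(p, q = 0.05)
    oracle <- bh_stepup(p, q = 0.05)
    expect_equal(mine$adjusted, oracle$adjusted, tolerance = 1e-12)
    expect_identical(mine$rejected, oracle$rejected)
  }
  # adjusted values are monotone nondecreasing in p-value rank
  p <- runif(100)
  adj <- fdrBH(p)$adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("compareGroups bundles KS, edgewise permutation and FDR coherently", {
  cfg <- pipelineConfig(n_null_permutations = 150, rng_seed = 7)
  a <- generateGroup(groupSimSpec(10, rho_within = 0.8, rho_between = 0,
                                  seed = 71), group_id = "a")
  b <- generateGroup(groupSimSpec(10, rho_within = 0.0, rho_between = 0,
                                  seed = 72), group_id = "b")
  cmp <- compareGroups(a, b, cfg)
  expect_s4_class(cmp, "GroupComparison")
  expect_gte(cmp@ksStat, 0)
  expect_lte(cmp@ksStat, 1)
  # FDR-significant edges are always a subset of uncorrected ones
  expect_true(all(cmp@sigUncorrected[cmp@sigFdr]))
  expect_equal(nrow(cmp@ksNodal), 2L * 4L)   # 2 levels x 4 metrics
})

test_that("KS on edge weights detects a strong planted difference", {
  # power check at a deliberately strong contrast in covariance structure
  hits <- vapply(1:20, function(s) {
    a <- generateGroup(groupSimSpec(12, rho_within = 0.8, rho_between = 0,
                                    seed = 800 + s))
    b <- generateGroup(groupSimSpec(12, rho_within = 0.0, rho_between = 0,
                                    seed = 900 + s))
    wa <- edgeWeights(covarianceNetwork(a))
    wb <- edgeWeights(covarianceNetwork(b))
    ksTwoSample(wa[upper.tri(wa)], wb[upper.tri(wb)])$p.value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})
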