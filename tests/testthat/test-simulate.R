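test_that("implied correlation has the planted block structure", {
  spec <- groupSimSpec(12, n_regions = 9,
                       planted_partition = plantedPartition(9, 3),
                       rho_within = 0.8, rho_between = 0, seed = 1)
  R <- impliedCorrelation(spec)
  expect_equal(diag(R), rep(1, 9))
  expect_true(all(R[1:3, 1:3][upper.tri(diag(3))] == 0.8))
  expect_true(all(R[1:3, 4:9] == 0))

  ident <- impliedCorrelation(groupSimSpec(5, n_regions = 6,
                                           planted_partition = plantedPartition(6, 2),
                                           rho_within = 0, rho_between = 0))
  expect_equal(ident, diag(6))

  expect_error(groupSimSpec(10, rho_within = 0.3, rho_between = 0.5),
               "rhoBetween")
})

test_that("generateGroup is seed-stable with the requested dimensions", {
  spec <- groupSimSpec(12, seed = 42)
  t1 <- generateGroup(spec)
  t2 <- generateGroup(spec)
  expect_identical(suvrMatrix(t1), suvrMatrix(t2))
  expect_equal(dim(suvrMatrix(t1)), c(12L, 27L))
  expect_true(all(suvrMatrix(t1) > 0))
})

test_that("sample correlations converge to the implied correlation", {
  spec <- groupSimSpec(5000, n_regions = 12,
                       planted_partition = plantedPartition(12, 3),
                       rho_within = 0.8, rho_between = 0.1, seed = 7)
  x <- suvrMatrix(generateGroup(spec))
  r <- cor(x)
  R <- impliedCorrelation(spec)
  off <- upper.tri(r)
  expect_lt(mean(abs(r[off] - R[off])), 0.02)
  expect_lt(max(abs(r[off] - R[off])), 0.05)
  within <- outer(spec@plantedPartition, spec@plantedPartition, "==") & off
  expect_gte(mean(r[within]), 0.78)
  expect_lte(mean(r[within]), 0.82)
})

test_that("generateCohort produces the twelve study groups", {
  cohort <- generateCohort(seed = 3)
  expect_length(cohort, 12L)
  sizes <- defaultGroupSizes()
  expect_identical(unname(vapply(cohort, nAnimals, integer(1))), sizes$n)
  expect_identical(vapply(cohort, function(t) metadata(t)$genotype,
                          character(1)),
                   setNames(sizes$genotype, names(cohort)))
  labs <- lapply(cohort, regionLabels)
  for (l in labs) expect_identical(l, defaultRegionLabels())
  # deterministic as a whole
  cohort2 <- generateCohort(seed = 3)
  expect_identical(suvrMatrix(cohort[[5]]), suvrMatrix(cohort2[[5]]))
})
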