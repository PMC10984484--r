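make_cohort <- function(seed = 1, effects = NULL) {
  generateCohort(effects = effects, seed = seed)
}

test_that("module-mean SUVR extracts the reference-module average per animal", {
  cohort <- make_cohort(seed = 2)
  ref <- partition(plantedPartition(27, 2), defaultRegionLabels())

  vals <- moduleMeanSUVR(cohort, ref, 1)
  expect_equal(nrow(vals), sum(defaultGroupSizes()$n))
  regions <- defaultRegionLabels()[plantedPartition(27, 2) == 1]
  manual <- rowMeans(suvrMatrix(cohort[[1]])[, regions])
  expect_equal(vals$value[vals$group_id == names(cohort)[1]], manual,
               ignore_attr = TRUE)

  # single-region module returns that region's SUVR per animal
  one <- partition(c(1, rep(2, 26)), defaultRegionLabels())
  v1 <- moduleMeanSUVR(cohort[1], one, 1)
  expect_equal(v1$value, suvrMatrix(cohort[[1]])[, 1], ignore_attr = TRUE)

  expect_error(moduleMeanSUVR(cohort, ref, 99), "unknown module")
})

test_that("nwayAnova fits main effects and two-way interactions with type II SS", {
  cohort <- make_cohort(seed = 3)
  ref <- partition(plantedPartition(27, 2), defaultRegionLabels())
  vals <- moduleMeanSUVR(cohort, ref, 1)
  res <- nwayAnova(vals)
  expect_s4_class(res, "AnovaResult")
  terms <- res@table$term
  expect_true(all(c("age", "sex", "genotype", "age:sex", "age:genotype",
                    "sex:genotype") %in% terms))
  expect_false("age:sex:genotype" %in% terms)
  expect_true(all(res@table$statistic >= 0, na.rm = TRUE))

  # balanced one-factor two-level sub-design: F equals the squared t
  set.seed(4)
  y <- rnorm(20)
  g <- rep(c("WT", "5XFAD"), each = 10)
  tt <- t.test(y ~ g, var.equal = TRUE)
  f <- anova(lm(y ~ g))[["F value"]][1]
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-12)

  # empty two-way cell is a hard error naming the cell
  bad <- vals[!(vals$age_months == 4 & vals$sex == "M"), ]
  expect_error(nwayAnova(bad), "empty design cell")
})

test_that("type II SS is order-invariant and reduces to classical SS when balanced", {
  set.seed(8)
  dat <- expand.grid(age_months = c(4, 6, 12), sex = c("M", "F"),
                     genotype = c("WT", "5XFAD"))
  dat <- dat[rep(seq_len(nrow(dat)), each = 4), ]
  dat$value <- rnorm(nrow(dat)) + as.numeric(dat$age_months) / 10
  res <- nwayAnova(dat)
  # balanced: type II SS equal the sequential (classical) decomposition
  fit <- lm(value ~ age + sex + genotype + age:sex + age:genotype +
              sex:genotype,
            data = transform(dat, age = factor(age_months),
                             sex = factor(sex),
                             genotype = factor(genotype)))
  seq_tab <- anova(fit)
  for (term in c("age", "sex", "genotype")) {
    expect_equal(res@table$sumsq[res@table$term == term],
                 seq_tab[term, "Sum Sq"], tolerance = 1e-9)
  }
})

test_that("anova detects a planted age effect on module means", {
  hits <- vapply(1:25, function(s) {
    effects <- list()
    module1 <- plantedPartition(27, 2) == 1
    for (age in c(4, 6, 12)) {
      shift <- 0.1 * (age - 4) / 8 * ifelse(module1, 1, 0)  # 1 SD at 12 mo
      for (g in c("WT", "5XFAD")) for (sx in c("M", "F")) {
        effects[[sprintf("%s_%s_%d", g, sx, age)]] <- list(mean_shift = shift)
      }
    }
    cohort <- generateCohort(effects = effects, seed = 7000 + s)
    ref <- partition(plantedPartition(27, 2), defaultRegionLabels())
    vals <- moduleMeanSUVR(cohort, ref, 1)
    res <- nwayAnova(vals)
    res@table$p.value[res@table$term == "age"] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("anova p-values are calibrated under the null cohort", {
  pvals <- vapply(1:40, function(s) {
    cohort <- generateCohort(seed = 9000 + s, wt_modules = 2, tg_modules = 2)
    ref <- partition(plantedPartition(27, 2), defaultRegionLabels())
    vals <- moduleMeanSUVR(cohort, ref, 1)
    res <- nwayAnova(vals)
    res@table$p.value[res@table$term == "genotype"]
  }, numeric(1))
  # uniformity of the null p-values (coarse check at modest replicate count)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("tukeyKramer agrees with TukeyHSD on a one-factor design and is conservative", {
  set.seed(10)
  dat <- expand.grid(age_months = c(4, 6, 12), sex = c("M", "F"),
                     genotype = c("WT", "5XFAD"),
                     stringsAsFactors = FALSE)
  dat <- dat[rep(seq_len(nrow(dat)), times = rep(c(2, 3), 6)), ]
  dat$value <- rnorm(nrow(dat)) +
    c(`4` = 0, `6` = 0.1, `12` = 1.5)[as.character(dat$age_months)]

  # one-factor reference: our Kramer p against stats::TukeyHSD
  fit1 <- aov(value ~ factor(age_months), data = dat)
  ref <- TukeyHSD(fit1)[[1]]
  av <- nwayAnova(dat)
  # refit with only age to compare against the single-factor reference
  av1 <- new("AnovaResult",
             table = av@table, model = lm(value ~ factor(age_months), dat),
             data = transform(dat, age = factor(age_months)), ssType = "II")
  av1@model$df.residual <- fit1$df.residual
  tk <- tukeyKramer(av1, "age")
  for (i in seq_len(nrow(tk))) {
    key <- grep(tk$level1[i], rownames(ref))
    key <- intersect(key, grep(tk$level2[i], rownames(ref)))
    expect_equal(tk$p.adj[i], ref[key, "p adj"], tolerance = 1e-8)
  }

  # equal means: adjusted p near 1; conservativeness vs plain t-test
  set.seed(11)
  dat2 <- data.frame(value = rnorm(30),
                     age_months = rep(c(4, 6, 12), each = 10),
                     sex = "M", genotype = "WT")
  dat2$value <- dat2$value - ave(dat2$value, dat2$age_months)
  fit2 <- lm(value ~ factor(age_months), dat2)
  av2 <- new("AnovaResult", table = data.frame(), model = fit2,
             data = transform(dat2, age = factor(age_months)), ssType = "II")
  tk2 <- tukeyKramer(av2, "age")
  expect_true(all(tk2$p.adj > 0.95))

  set.seed(12)
  dat3 <- data.frame(value = rnorm(24, rep(c(0, 0.5), each = 12)),
                     age_months = rep(c(4, 12), each = 12),
                     sex = "M", genotype = "WT")
  fit3 <- lm(value ~ factor(age_months), dat3)
  av3 <- new("AnovaResult", table = data.frame(), model = fit3,
             data = transform(dat3, age = factor(age_months)), ssType = "II")
  tk3 <- tukeyKramer(av3, "age")
  praw <- t.test(value ~ age_months, dat3, var.equal = TRUE)$p.value
  expect_gte(tk3$p.adj[1] + 1e-9, praw)

  expect_error(tukeyKramer(av3, "sex"), "fewer than 2 levels")
})
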