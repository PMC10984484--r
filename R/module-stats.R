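#' @include accessors.R
NULL

#' Module-mean SUVR against a reference partition
#'
#' Extracts, for every animal of every group, the mean SUVR over the
#' regions of one module of a single reference partition. Using one
#' group's partition as the common reference guarantees that the same
#' regions are averaged for all groups (the study uses the 4-month male WT
#' consensus partition).
#'
#' @param tables list of \linkS4class{UptakeTable}s (all groups).
#' @param reference a \linkS4class{Partition} covering all regions.
#' @param module_id which module of the reference to average.
#' @return data.frame with one row per animal: animal_id, group_id,
#'   genotype, sex, age_months, module, value.
#' @export
moduleMeanSUVR <- function(tables, reference, module_id) {
  stopifnot(is(reference, "Partition"))
  if (!module_id %in% seq_len(max(reference@labels)))
    stop("unknown module id ", module_id, "; reference partition has ",
         max(reference@labels), " modules")
  regions <- reference@regionLabels[reference@labels == module_id]
  out <- lapply(tables, function(tab) {
    .check_same_regions(sort(regionLabels(tab)), sort(reference@regionLabels),
                        "tables")
    v <- suvrMatrix(tab)[, regions, drop = FALSE]
    md <- metadata(tab)
    data.frame(animal_id = rownames(suvrMatrix(tab)),
               group_id = md$group_id,
               genotype = md$genotype,
               sex = md$sex,
               age_months = md$age_months,
               module = module_id,
               value = rowMeans(v),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Factorial ANOVA of module-mean SUVR
#'
#' Linear-model ANOVA with age, sex and genotype as factors, testing the
#' three main effects and all three two-way interactions (no three-way
#' term). Group sizes are mildly unbalanced, so type II sums of squares
#' are the default (order-invariant for main effects and identical to the
#' classical decomposition when the design is balanced); type III is
#' available via \code{ss_type}.
#'
#' @param values data.frame as returned by [moduleMeanSUVR()] (needs
#'   columns value, age_months, sex, genotype), or a numeric vector
#'   accompanied by \code{factors}.
#' @param factors optional data.frame with columns age_months, sex,
#'   genotype when \code{values} is a numeric vector.
#' @param ss_type sums-of-squares type, "II" (default) or "III".
#' @return an \linkS4class{AnovaResult}.
#' @export
nwayAnova <- function(values, factors = NULL, ss_type = c("II", "III")) {
  ss_type <- match.arg(ss_type)
  if (is.numeric(values)) {
    stopifnot(!is.null(factors))
    dat <- data.frame(value = values, factors, stringsAsFactors = FALSE)
  } else dat <- values
  dat$age <- factor(dat$age_months)
  dat$sex <- factor(dat$sex)
  dat$genotype <- factor(dat$genotype)
  for (f in c("age", "sex", "genotype"))
    if (nlevels(dat[[f]]) < 2L)
      stop("factor '", f, "' needs at least 2 levels")
  ## interactions are estimable only if every two-way cell is populated
  for (pair in list(c("age", "sex"), c("age", "genotype"),
                    c("sex", "genotype"))) {
    cells <- table(dat[[pair[1]]], dat[[pair[2]]])
    if (any(cells == 0L)) {
      bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
      stop(sprintf("empty design cell: %s = %s, %s = %s",
                   pair[1], rownames(cells)[bad[1]],
                   pair[2], colnames(cells)[bad[2]]))
    }
  }
  contr <- if (ss_type == "III") {
    list(age = "contr.sum", sex = "contr.sum", genotype = "contr.sum")
  } else NULL
  fit <- lm(value ~ age + sex + genotype + age:sex + age:genotype +
              sex:genotype, data = dat, contrasts = contr)
  a <- car::Anova(fit, type = ss_type)
  tab <- data.frame(term = rownames(a),
                    sumsq = a[["Sum Sq"]],
                    df = a[["Df"]],
                    statistic = a[["F value"]],
                    p.value = a[["Pr(>F)"]],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (ss_type == "III")
    tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  new("AnovaResult", table = tab, model = fit, data = dat, ssType = ss_type)
}

#' Tukey-Kramer post hoc comparisons
#'
#' All pairwise comparisons of the levels of one factor using the
#' studentized range distribution, with the Kramer correction for unequal
#' group sizes. The standard error uses the full-model residual mean
#' square and residual degrees of freedom of the fitted ANOVA.
#'
#' @param anova an \linkS4class{AnovaResult}.
#' @param factor one of "age", "sex", "genotype".
#' @return data.frame with columns level1, level2, estimate (difference of
#'   level means), p.adj.
#' @export
tukeyKramer <- function(anova, factor = c("age", "sex", "genotype")) {
  factor <- match.arg(factor)
  dat <- anova@data
  f <- droplevels(factor(dat[[factor]]))
  if (nlevels(f) < 2L)
    stop("factor '", factor, "' has fewer than 2 levels")
  fit <- anova@model
  df_res <- fit$df.residual
  mse <- sum(fit$residuals^2) / df_res
  means <- tapply(dat$value, f, mean)
  ns <- tapply(dat$value, f, length)
  k <- length(means)
  combos <- combn(names(means), 2L)
  res <- apply(combos, 2L, function(pr) {
    diff <- means[pr[1]] - means[pr[2]]
    se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(diff) / se
    p <- ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    c(estimate = unname(diff), p.adj = unname(p))
  })
  data.frame(level1 = combos[1L, ], level2 = combos[2L, ],
             estimate = res["estimate", ], p.adj = res["p.adj", ],
             row.names = NULL, stringsAsFactors = FALSE)
}
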