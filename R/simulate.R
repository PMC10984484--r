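#' @include accessors.R
NULL

#' Default region labels for the synthetic cohort
#'
#' 27 bilateral mouse brain region labels used by the synthetic-data
#' generator. They name structures typically quantified in murine FDG-PET
#' atlases; the analysis itself never interprets them, it only requires a
#' fixed, unique labelling.
#'
#' @return character(27).
#' @export
defaultRegionLabels <- function() {
  c("Amygdala", "AuditoryCtx", "BasalForebrainSeptum", "CaudatePutamen",
    "CingulateCtx", "Claustrum", "EntorhinalCtx", "Fornix",
    "FrontalAssocCtx", "GlobusPallidus", "Hippocampus", "Hypothalamus",
    "InsularCtxAgranular", "InsularCtxDysgranular", "LateralOrbitalCtx",
    "MedialOrbitalCtx", "MotorCtx1", "MotorCtx2", "ParietalCtx",
    "PerirhinalCtx", "PrelimbicCtx", "RetrosplenialCtx",
    "SomatosensoryCtx1", "SomatosensoryCtx2", "Thalamus",
    "VentralOrbitalCtx", "VisualCtx")
}

#' Study-design group sizes
#'
#' Animals per group in the 2 genotype x 2 sex x 3 age factorial design:
#' WT males 12, 11, 9 and females 12, 11, 10 at 4, 6 and 12 months;
#' 5XFAD males 11, 10, 9 and females 12, 12, 10.
#'
#' @return data.frame with columns genotype, sex, age_months, n.
#' @export
defaultGroupSizes <- function() {
  data.frame(
    genotype = rep(c("WT", "5XFAD"), each = 6L),
    sex = rep(rep(c("M", "F"), each = 3L), 2L),
    age_months = rep(c(4, 6, 12), 4L),
    n = c(12L, 11L, 9L,   # WT M
          12L, 11L, 10L,  # WT F
          11L, 10L, 9L,   # 5XFAD M
          12L, 12L, 10L), # 5XFAD F
    stringsAsFactors = FALSE
  )
}

#' Planted partition with near-equal contiguous modules
#'
#' @param n_regions number of regions.
#' @param k number of modules.
#' @return integer vector of module labels (1..k), contiguous blocks.
#' @export
plantedPartition <- function(n_regions = 27, k = 3) {
  sort(rep_len(seq_len(k), n_regions))
}

#' Simulation settings for one synthetic group
#'
#' @param n_animals animals in the group (>= 3).
#' @param n_regions regions (default 27).
#' @param planted_partition integer module label per region (default: 3
#'   near-equal contiguous modules).
#' @param rho_within within-module correlation in [0, 1).
#' @param rho_between between-module correlation in [0, rho_within].
#' @param mean_suvr baseline mean SUVR, length 1 or n_regions (default 1).
#' @param mean_shift additive group effect, length 1 or n_regions
#'   (default 0).
#' @param noise_sd marginal SD of the SUVR values (default 0.1).
#' @param seed RNG seed (NA to draw from the current RNG state).
#' @return a \linkS4class{GroupSimSpec}.
#' @examples
#' spec <- groupSimSpec(12, rho_within = 0.8, rho_between = 0, seed = 1)
#' impliedCorrelation(spec)[1:4, 1:4]
#' @export
groupSimSpec <- function(n_animals, n_regions = 27,
                         planted_partition = plantedPartition(n_regions, 3),
                         rho_within = 0.6, rho_between = 0.1,
                         mean_suvr = 1, mean_shift = 0, noise_sd = 0.1,
                         seed = NA) {
  new("GroupSimSpec",
      nAnimals = as.integer(n_animals),
      nRegions = as.integer(n_regions),
      plantedPartition = .canonical_labels(planted_partition),
      rhoWithin = as.numeric(rho_within),
      rhoBetween = as.numeric(rho_between),
      meanSuvr = as.numeric(mean_suvr),
      meanShift = as.numeric(mean_shift),
      noiseSd = as.numeric(noise_sd),
      seed = as.integer(seed))
}

#' Correlation matrix implied by a simulation spec
#'
#' Analytic population correlation of the generator: 1 on the diagonal,
#' \code{rho_within} for same-module pairs, \code{rho_between} otherwise.
#' Positive semidefiniteness is guaranteed by the shared-global-factor
#' construction for \code{0 <= rho_between <= rho_within < 1} and verified
#' numerically at construction.
#'
#' @param spec a \linkS4class{GroupSimSpec}.
#' @return n_regions x n_regions correlation matrix.
#' @export
impliedCorrelation <- function(spec) {
  stopifnot(is(spec, "GroupSimSpec"))
  validObject(spec)
  same <- outer(spec@plantedPartition, spec@plantedPartition, "==")
  R <- ifelse(same, spec@rhoWithin, spec@rhoBetween)
  diag(R) <- 1
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("implied correlation matrix is not positive semidefinite; ",
         "choose a smaller rho_between")
  R
}

## Draw the standardized (mean 0, unit variance) regional scores:
## sqrt(rho_b) * global factor + sqrt(rho_w - rho_b) * module factor +
## sqrt(1 - rho_w) * idiosyncratic noise. Exactly reproduces
## impliedCorrelation(spec) in population.
.draw_scores <- function(spec) {
  n <- spec@nAnimals
  p <- spec@nRegions
  k <- max(spec@plantedPartition)
  g <- rnorm(n)
  fm <- matrix(rnorm(n * k), n, k)
  e <- matrix(rnorm(n * p), n, p)
  a <- sqrt(spec@rhoBetween)
  b <- sqrt(spec@rhoWithin - spec@rhoBetween)
  c0 <- sqrt(1 - spec@rhoWithin)
  a * g + b * fm[, spec@plantedPartition, drop = FALSE] + c0 * e
}

#' Generate one synthetic group of regional SUVR values
#'
#' Rows are i.i.d. multivariate-normal draws with mean
#' \code{mean_suvr + mean_shift} and covariance
#' \code{noise_sd^2 * impliedCorrelation(spec)}, clipped below at 0.01 so
#' SUVR stays strictly positive (the clip probability is negligible at the
#' default mean 1, SD 0.1). The same seed always yields the same table.
#'
#' @param spec a \linkS4class{GroupSimSpec}.
#' @param group_id,genotype,sex,age_months group descriptors attached to the
#'   returned table.
#' @param region_labels region names (default [defaultRegionLabels()] when
#'   \code{n_regions} is 27, generic labels otherwise).
#' @return an \linkS4class{UptakeTable} with \code{n_animals} animals.
#' @examples
#' tab <- generateGroup(groupSimSpec(12, seed = 7))
#' dim(suvrMatrix(tab))
#' @export
generateGroup <- function(spec, group_id = "sim", genotype = "WT", sex = "M",
                          age_months = 4, region_labels = NULL) {
  stopifnot(is(spec, "GroupSimSpec"))
  validObject(spec)
  if (is.null(region_labels)) {
    region_labels <- if (spec@nRegions == 27L) defaultRegionLabels()
                     else paste0("R", seq_len(spec@nRegions))
  }
  z <- .with_seed(if (is.na(spec@seed)) NULL else spec@seed, .draw_scores(spec))
  mu <- rep_len(spec@meanSuvr, spec@nRegions) +
        rep_len(spec@meanShift, spec@nRegions)
  values <- sweep(spec@noiseSd * z, 2L, mu, "+")
  values[values < 0.01] <- 0.01
  uptakeTable(values,
              region_labels = region_labels,
              animal_ids = sprintf("%s_A%02d", group_id, seq_len(spec@nAnimals)),
              group_id = group_id, genotype = genotype, sex = sex,
              age_months = age_months)
}

#' Generate the full 12-group synthetic cohort
#'
#' Builds one \linkS4class{UptakeTable} per cell of the 2 genotype x 2 sex x
#' 3 age design with the study group sizes ([defaultGroupSizes()]). By
#' default WT groups carry a coarse planted structure (2 modules) and 5XFAD
#' groups a finer one (4 modules), mimicking the disease-related increase in
#' community count; mean effects default to zero. Per-cell settings can be
#' overridden through \code{effects}, a named list keyed
#' \code{"<genotype>_<sex>_<age>"} (e.g. \code{"5XFAD_F_12"}), each entry a
#' list with any of \code{n_modules}, \code{rho_within}, \code{rho_between},
#' \code{mean_shift}, \code{noise_sd}.
#'
#' @param effects per-cell overrides (see Details); NULL for the defaults.
#' @param seed master seed; per-group seeds are derived from it so the
#'   cohort is reproducible as a whole.
#' @param group_sizes data.frame like [defaultGroupSizes()].
#' @param rho_within,rho_between,noise_sd,mean_suvr cohort-wide defaults.
#' @param wt_modules,tg_modules planted module counts for WT and 5XFAD
#'   groups.
#' @return named list of 12 \linkS4class{UptakeTable}s, keyed
#'   \code{"<genotype>_<sex>_<age>"}.
#' @examples
#' cohort <- generateCohort(seed = 1)
#' sapply(cohort, nAnimals)
#' @export
generateCohort <- function(effects = NULL, seed = 1,
                           group_sizes = defaultGroupSizes(),
                           rho_within = 0.6, rho_between = 0.1,
                           noise_sd = 0.1, mean_suvr = 1,
                           wt_modules = 2, tg_modules = 4) {
  seeds <- .derive_seeds(seed, nrow(group_sizes))
  out <- vector("list", nrow(group_sizes))
  keys <- character(nrow(group_sizes))
  for (i in seq_len(nrow(group_sizes))) {
    gs <- group_sizes[i, ]
    key <- sprintf("%s_%s_%d", gs$genotype, gs$sex, gs$age_months)
    ov <- if (!is.null(effects)) effects[[key]] else NULL
    k <- if (!is.null(ov$n_modules)) ov$n_modules
         else if (gs$genotype == "5XFAD") tg_modules else wt_modules
    spec <- groupSimSpec(
      n_animals = gs$n,
      planted_partition = plantedPartition(27, k),
      rho_within = if (!is.null(ov$rho_within)) ov$rho_within else rho_within,
      rho_between = if (!is.null(ov$rho_between)) ov$rho_between else rho_between,
      mean_suvr = mean_suvr,
      mean_shift = if (!is.null(ov$mean_shift)) ov$mean_shift else 0,
      noise_sd = if (!is.null(ov$noise_sd)) ov$noise_sd else noise_sd,
      seed = seeds[i])
    out[[i]] <- generateGroup(spec, group_id = key, genotype = gs$genotype,
                              sex = gs$sex, age_months = gs$age_months)
    keys[i] <- key
  }
  names(out) <- keys
  out
}
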