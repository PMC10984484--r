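#' @include covnet-package.R
NULL

## ---------------------------------------------------------------------------
## UptakeTable
## ---------------------------------------------------------------------------

#' UptakeTable: regional SUVR values for one animal group
#'
#' An \code{UptakeTable} stores the regional standardized uptake value ratio
#' (SUVR) matrix for one homogeneous group of animals, as a
#' \linkS4class{SummarizedExperiment} with regions as rows and animals as
#' columns (assay \code{"suvr"}). Group descriptors (group id, genotype, sex,
#' age in months) live in \code{metadata()}. SUVR is dimensionless and
#' strictly positive; inter-subject covariance networks are estimated across
#' the animals (columns) of one table.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; assay \code{"suvr"} is
#'   a regions x animals numeric matrix.
#'
#' @section Validity:
#' \itemize{
#'   \item all SUVR values finite and > 0 (no missing entries);
#'   \item region labels and animal ids present and unique;
#'   \item at least 3 animals (Pearson correlation is degenerate below that);
#'   \item genotype in \{WT, 5XFAD\}, sex in \{M, F\}, age in \{4, 6, 12\}.
#' }
#'
#' @seealso [uptakeTable()], [readUptakeTable()], [covarianceNetwork()]
#' @export
setClass("UptakeTable", contains = "SummarizedExperiment")

setValidity("UptakeTable", function(object) {
  msg <- character()
  if (!"suvr" %in% names(assays(object)))
    return("assay 'suvr' is required")
  v <- assay(object, "suvr")
  if (anyNA(v))
    msg <- c(msg, "SUVR matrix contains missing values")
  else if (!all(is.finite(v)))
    msg <- c(msg, "SUVR matrix contains non-finite values")
  else if (any(v <= 0))
    msg <- c(msg, "SUVR values must be strictly positive")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "region labels (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "animal ids (colnames) must be present and unique")
  if (ncol(object) < 3L)
    msg <- c(msg, sprintf(
      "at least 3 animals are required (got %d); Pearson correlation is degenerate below n = 3",
      ncol(object)))
  md <- metadata(object)
  if (!is.null(md$genotype) && !md$genotype %in% c("WT", "5XFAD"))
    msg <- c(msg, "genotype must be 'WT' or '5XFAD'")
  if (!is.null(md$sex) && !md$sex %in% c("M", "F"))
    msg <- c(msg, "sex must be 'M' or 'F'")
  if (!is.null(md$age_months) && !md$age_months %in% c(4, 6, 12))
    msg <- c(msg, "age_months must be one of 4, 6, 12")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CovarianceNetwork / ThresholdedNetwork
## ---------------------------------------------------------------------------

#' CovarianceNetwork: group-level metabolic covariance network
#'
#' Symmetric region-by-region matrix of Pearson correlations of regional
#' SUVR across the animals of one group (an inter-subject covariance
#' network; a group-level construct, not a per-animal graph). The diagonal
#' is fixed at 0: self-edges carry no information and would distort
#' strength sums. Optionally carries per-edge permutation p-values from the
#' random-shift null ([edgeSignificance()]).
#'
#' @slot groupId character(1), group label.
#' @slot regionLabels character, region names (order fixes the node order).
#' @slot weights numeric matrix, symmetric, entries in [-1, 1], zero diagonal.
#' @slot edgeP numeric matrix of permutation p-values in (0, 1], or a 0 x 0
#'   matrix when significance has not been assessed.
#' @slot nAnimals integer(1), number of animals the network was estimated
#'   from.
#'
#' @seealso [covarianceNetwork()], [thresholdNetwork()], [louvainSigned()]
#' @export
setClass("CovarianceNetwork",
  representation(
    groupId = "character",
    regionLabels = "character",
    weights = "matrix",
    edgeP = "matrix",
    nAnimals = "integer"
  ),
  prototype(
    groupId = NA_character_,
    edgeP = matrix(numeric(0), 0, 0),
    nAnimals = NA_integer_
  )
)

.check_net_matrix <- function(w, labels, what = "weights") {
  msg <- character()
  p <- length(labels)
  if (!is.numeric(w) || nrow(w) != p || ncol(w) != p)
    return(sprintf("%s must be a %d x %d numeric matrix", what, p, p))
  if (anyNA(w) || !all(is.finite(w)))
    msg <- c(msg, sprintf("%s contains non-finite values", what))
  else {
    if (max(abs(w - t(w))) > 1e-8)
      msg <- c(msg, sprintf("%s must be symmetric", what))
    if (what == "weights") {
      if (any(abs(diag(w)) > 0))
        msg <- c(msg, "diagonal of weights must be 0")
      if (max(abs(w)) > 1 + 1e-8)
        msg <- c(msg, "weights must lie in [-1, 1]")
    }
  }
  msg
}

setValidity("CovarianceNetwork", function(object) {
  msg <- character()
  labs <- object@regionLabels
  if (anyDuplicated(labs))
    msg <- c(msg, "region labels must be unique")
  msg <- c(msg, .check_net_matrix(object@weights, labs, "weights"))
  if (length(object@edgeP)) {
    msg <- c(msg, .check_net_matrix(object@edgeP, labs, "edgeP"))
    off <- object@edgeP[row(object@edgeP) != col(object@edgeP)]
    if (length(off) && (any(off <= 0) || any(off > 1)))
      msg <- c(msg, "edge p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ThresholdedNetwork: covariance network with non-significant edges zeroed
#'
#' A \linkS4class{CovarianceNetwork} whose \code{weights} retain the signed
#' Pearson correlation only for edges with permutation p below the stated
#' significance level; all other edges are set to 0. The \code{fragmented}
#' flag records whether the surviving edge set leaves any node or node group
#' disconnected from the rest of the network.
#'
#' @slot level numeric(1), the significance level the network was
#'   thresholded at (e.g. 0.05 or 0.01).
#' @slot fragmented logical(1), TRUE when the thresholded graph has more
#'   than one connected component.
#'
#' @seealso [thresholdNetwork()], [networkDensity()]
#' @export
setClass("ThresholdedNetwork",
  contains = "CovarianceNetwork",
  representation(level = "numeric", fragmented = "logical")
)

setValidity("ThresholdedNetwork", function(object) {
  msg <- character()
  if (length(object@level) != 1L || object@level <= 0 || object@level > 1)
    msg <- c(msg, "level must be a single value in (0, 1]")
  if (length(object@fragmented) != 1L)
    msg <- c(msg, "fragmented must be a single logical")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Partition / ConsensusResult
## ---------------------------------------------------------------------------

#' Partition: community labels for the network regions
#'
#' Community assignment of each region, with labels re-coded to consecutive
#' integers starting at 1 (in order of first appearance). \code{gamma}
#' records the resolution parameter when the partition came from a single
#' Louvain run; it is \code{NA} for consensus or externally supplied
#' partitions.
#'
#' @slot regionLabels character, region names.
#' @slot labels integer, community id per region (1-based, contiguous).
#' @slot gamma numeric(1), resolution parameter or NA.
#'
#' @seealso [louvainSigned()], [mrcc()], [ami()]
#' @export
setClass("Partition",
  representation(
    regionLabels = "character",
    labels = "integer",
    gamma = "numeric"
  ),
  prototype(gamma = NA_real_)
)

setValidity("Partition", function(object) {
  msg <- character()
  n <- length(object@regionLabels)
  if (length(object@labels) != n)
    msg <- c(msg, "labels and regionLabels must have the same length")
  else if (n > 0L) {
    k <- max(object@labels)
    if (any(object@labels < 1L) || !setequal(unique(object@labels), seq_len(k)))
      msg <- c(msg, "labels must be contiguous integers starting at 1")
    if (k > n)
      msg <- c(msg, "more communities than regions")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: multiresolution consensus clustering output
#'
#' Output of [mrcc()]: the ensemble co-assignment matrix (probability that a
#' region pair shares a community across the multiresolution Louvain
#' ensemble), the hierarchy of consensus partitions from coarse to fine, and
#' the final consensus partition (the leaves of the hierarchical
#' significance-tested splitting at level \code{alpha}).
#'
#' @slot ensembleSize integer(1), number of ensemble partitions.
#' @slot coassignment numeric matrix in [0, 1], symmetric, unit diagonal.
#' @slot consensus \linkS4class{Partition}, the consensus partition.
#' @slot hierarchy list of \linkS4class{Partition}, coarse to fine; the last
#'   element equals \code{consensus}.
#' @slot alpha numeric(1), significance level of the local null test.
#' @slot gammaRange numeric(2), resolution interval the ensemble sampled.
#'
#' @seealso [mrcc()], [coclassification()]
#' @export
setClass("ConsensusResult",
  representation(
    ensembleSize = "integer",
    coassignment = "matrix",
    consensus = "Partition",
    hierarchy = "list",
    alpha = "numeric",
    gammaRange = "numeric"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  C <- object@coassignment
  n <- length(object@consensus@regionLabels)
  if (nrow(C) != n || ncol(C) != n)
    msg <- c(msg, "coassignment must be regions x regions")
  else {
    if (max(abs(C - t(C))) > 1e-8)
      msg <- c(msg, "coassignment must be symmetric")
    if (any(C < -1e-12) || any(C > 1 + 1e-12))
      msg <- c(msg, "coassignment entries must lie in [0, 1]")
    if (n > 0 && max(abs(diag(C) - 1)) > 1e-12)
      msg <- c(msg, "coassignment diagonal must be 1")
  }
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GroupComparison
## ---------------------------------------------------------------------------

#' GroupComparison: between-group network statistics for one group pair
#'
#' Bundles the Kolmogorov-Smirnov comparison of edge-weight distributions,
#' KS comparisons of nodal-metric distributions per threshold level, and the
#' edgewise group-label permutation test with Benjamini-Hochberg FDR
#' control, for one unordered pair of groups.
#'
#' @slot pair character(2), the two group ids.
#' @slot ksStat numeric(1), KS D for the 351 edge weights.
#' @slot ksP numeric(1), asymptotic KS p-value.
#' @slot ksNodal data.frame, KS tests on nodal metric distributions
#'   (metric, level, D, p).
#' @slot edgeP numeric matrix, edgewise permutation p-values (symmetric,
#'   diagonal 1).
#' @slot edgeQ numeric matrix, BH-adjusted values over the 351 edges.
#' @slot sigUncorrected logical matrix, edges with p < 0.05.
#' @slot sigFdr logical matrix, edges with q < fdr level.
#' @slot nPerm integer(1), permutations used.
#'
#' @seealso [compareGroups()], [edgewisePermutationTest()]
#' @export
setClass("GroupComparison",
  representation(
    pair = "character",
    ksStat = "numeric",
    ksP = "numeric",
    ksNodal = "data.frame",
    edgeP = "matrix",
    edgeQ = "matrix",
    sigUncorrected = "matrix",
    sigFdr = "matrix",
    nPerm = "integer"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (length(object@pair) != 2L)
    msg <- c(msg, "pair must name exactly two groups")
  if (length(object@ksStat) == 1L &&
      (object@ksStat < 0 || object@ksStat > 1))
    msg <- c(msg, "KS statistic must lie in [0, 1]")
  if (length(object@edgeP) && length(object@sigFdr) &&
      any(object@sigFdr & !object@sigUncorrected))
    msg <- c(msg, "FDR-significant edges must be a subset of uncorrected ones")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GroupSimSpec
## ---------------------------------------------------------------------------

#' GroupSimSpec: simulation settings for one synthetic group
#'
#' Settings of the Gaussian equicorrelated-block generator for one group of
#' animals: a planted module partition with correlation \code{rhoWithin}
#' inside modules and \code{rhoBetween} across modules (realised through a
#' shared global factor, which guarantees a positive-semidefinite
#' correlation matrix whenever \code{0 <= rhoBetween <= rhoWithin < 1}),
#' per-region mean SUVR near 1, and i.i.d. Gaussian noise of scale
#' \code{noiseSd}.
#'
#' @slot nAnimals integer(1), animals in the group (>= 3).
#' @slot nRegions integer(1), regions (default 27).
#' @slot plantedPartition integer, module label per region.
#' @slot rhoWithin numeric(1) in [0, 1), within-module correlation.
#' @slot rhoBetween numeric(1) in [0, rhoWithin], between-module correlation.
#' @slot meanSuvr numeric, baseline mean SUVR (length 1 or nRegions, > 0).
#' @slot meanShift numeric, additive group effect (length 1 or nRegions).
#' @slot noiseSd numeric(1) > 0, marginal SD of the SUVR values.
#' @slot seed integer(1), RNG seed (NA to use the current RNG state).
#'
#' @seealso [groupSimSpec()], [impliedCorrelation()], [generateGroup()]
#' @export
setClass("GroupSimSpec",
  representation(
    nAnimals = "integer",
    nRegions = "integer",
    plantedPartition = "integer",
    rhoWithin = "numeric",
    rhoBetween = "numeric",
    meanSuvr = "numeric",
    meanShift = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("GroupSimSpec", function(object) {
  msg <- character()
  if (object@nAnimals < 3L)
    msg <- c(msg, "nAnimals must be >= 3")
  if (length(object@plantedPartition) != object@nRegions)
    msg <- c(msg, "plantedPartition must have one label per region")
  if (object@rhoWithin < 0 || object@rhoWithin >= 1)
    msg <- c(msg, "rhoWithin must lie in [0, 1)")
  if (object@rhoBetween < 0)
    msg <- c(msg, "rhoBetween must be >= 0")
  if (object@rhoBetween > object@rhoWithin)
    msg <- c(msg, paste0(
      "rhoBetween (", object@rhoBetween, ") exceeds rhoWithin (",
      object@rhoWithin, "); the implied correlation matrix would not be ",
      "positive semidefinite under the shared-factor construction - ",
      "choose a smaller rhoBetween"))
  if (!length(object@meanSuvr) %in% c(1L, object@nRegions) ||
      any(object@meanSuvr <= 0))
    msg <- c(msg, "meanSuvr must be positive, length 1 or nRegions")
  if (!length(object@meanShift) %in% c(1L, object@nRegions))
    msg <- c(msg, "meanShift must have length 1 or nRegions")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PipelineConfig
## ---------------------------------------------------------------------------

#' PipelineConfig: settings for the full covariance-network pipeline
#'
#' @slot thresholdPLevels numeric, significance levels for network
#'   thresholding (default 0.05 and 0.01; levels below 0.01 are not offered
#'   because they tend to fragment the networks).
#' @slot nNullPermutations integer(1), permutations for the random-shift
#'   edge-significance null and the edgewise group test (default 10000).
#' @slot nMrccPartitions integer(1), Louvain ensemble size for
#'   multiresolution consensus clustering (default 10000).
#' @slot mrccAlpha numeric(1), significance level of the MRCC local null
#'   test (default 0.05).
#' @slot hubQuantile numeric(1), top fraction of regions labelled hubs
#'   (default 0.25, i.e. 7 of 27 regions).
#' @slot fdrQ numeric(1), FDR level for edgewise comparisons (default 0.05).
#' @slot rngSeed integer(1), master seed; every stochastic stage derives its
#'   seed from it, so a rerun is bit-identical.
#' @slot louvainRestarts integer(1), restarts per standalone Louvain call
#'   (default 10).
#' @slot mrccSampling character(1), \code{"event"} (default) or
#'   \code{"grid"} resolution sampling.
#' @slot ssType character(1), ANOVA sums-of-squares type, \code{"II"}
#'   (default) or \code{"III"}.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
  representation(
    thresholdPLevels = "numeric",
    nNullPermutations = "integer",
    nMrccPartitions = "integer",
    mrccAlpha = "numeric",
    hubQuantile = "numeric",
    fdrQ = "numeric",
    rngSeed = "integer",
    louvainRestarts = "integer",
    mrccSampling = "character",
    ssType = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (any(object@thresholdPLevels <= 0) || any(object@thresholdPLevels > 1))
    msg <- c(msg, "threshold levels must lie in (0, 1]")
  for (nm in c("nNullPermutations", "nMrccPartitions", "louvainRestarts")) {
    if (slot(object, nm) < 1L)
      msg <- c(msg, sprintf("%s must be >= 1", nm))
  }
  for (nm in c("mrccAlpha", "hubQuantile", "fdrQ")) {
    v <- slot(object, nm)
    if (v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must lie in (0, 1)", nm))
  }
  if (!object@mrccSampling %in% c("event", "grid"))
    msg <- c(msg, "mrccSampling must be 'event' or 'grid'")
  if (!object@ssType %in% c("II", "III"))
    msg <- c(msg, "ssType must be 'II' or 'III'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AnovaResult
## ---------------------------------------------------------------------------

#' AnovaResult: factorial ANOVA of module-mean SUVR
#'
#' Result of [nwayAnova()]: the ANOVA table for the three main effects
#' (age, sex, genotype) and all two-way interactions, the fitted linear
#' model, and the per-animal data the model was fitted to.
#'
#' @slot table data.frame with columns term, sumsq, df, statistic (F),
#'   p.value; the last row is the residual.
#' @slot model the fitted \code{lm} object.
#' @slot data data.frame of per-animal module means and factor labels.
#' @slot ssType character(1), sums-of-squares type used ("II" or "III").
#'
#' @seealso [nwayAnova()], [tukeyKramer()]
#' @export
setClass("AnovaResult",
  representation(
    table = "data.frame",
    model = "ANY",
    data = "data.frame",
    ssType = "character"
  )
)
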