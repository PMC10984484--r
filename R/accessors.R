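#' @include AllGenerics.R utils.R
NULL

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Construct an UptakeTable from an animals x regions SUVR matrix
#'
#' @param values numeric matrix, animals in rows, regions in columns, strictly
#'   positive SUVR values.
#' @param region_labels character, region names (defaults to the column names
#'   of \code{values}).
#' @param animal_ids character, animal identifiers (defaults to row names).
#' @param group_id character(1), group label.
#' @param genotype \code{"WT"} or \code{"5XFAD"}.
#' @param sex \code{"M"} or \code{"F"}.
#' @param age_months 4, 6 or 12.
#' @return an \linkS4class{UptakeTable} (regions x animals internally).
#' @examples
#' tab <- uptakeTable(matrix(1 + abs(rnorm(3 * 5, sd = .1)), 3, 5),
#'                    region_labels = paste0("R", 1:5),
#'                    animal_ids = paste0("A", 1:3),
#'                    group_id = "demo", genotype = "WT", sex = "M",
#'                    age_months = 4)
#' suvrMatrix(tab)
#' @export
uptakeTable <- function(values, region_labels = colnames(values),
                        animal_ids = rownames(values),
                        group_id = "group", genotype = "WT", sex = "M",
                        age_months = 4) {
  values <- as.matrix(values)
  if (is.null(region_labels))
    region_labels <- paste0("R", seq_len(ncol(values)))
  if (is.null(animal_ids))
    animal_ids <- paste0("A", seq_len(nrow(values)))
  m <- t(values)
  dimnames(m) <- list(region_labels, animal_ids)
  se <- SummarizedExperiment(
    assays = list(suvr = m),
    colData = DataFrame(animal_id = animal_ids, row.names = animal_ids)
  )
  metadata(se) <- list(group_id = as.character(group_id),
                       genotype = genotype, sex = sex,
                       age_months = as.numeric(age_months))
  new("UptakeTable", se)
}

#' Pipeline configuration
#'
#' All settings of the covariance-network pipeline with the study defaults:
#' thresholds p < 0.05 and p < 0.01, 10000 permutations for both the
#' random-shift edge null and the edgewise group test, 10000 MRCC ensemble
#' partitions at consensus level alpha = 0.05, top-quartile hubs, FDR
#' q < 0.05.
#'
#' @param threshold_p_levels numeric, network thresholding levels.
#' @param n_null_permutations integer, permutations for edge significance and
#'   edgewise group tests.
#' @param n_mrcc_partitions integer, MRCC ensemble size.
#' @param mrcc_alpha numeric, MRCC consensus significance level.
#' @param hub_quantile numeric, top fraction of regions labelled hubs.
#' @param fdr_q numeric, FDR level.
#' @param rng_seed integer, master seed for all stochastic stages.
#' @param louvain_restarts integer, restarts per standalone Louvain call.
#' @param mrcc_sampling "event" or "grid" resolution sampling.
#' @param ss_type ANOVA sums-of-squares type, "II" or "III".
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(threshold_p_levels = c(0.05, 0.01),
                           n_null_permutations = 10000,
                           n_mrcc_partitions = 10000,
                           mrcc_alpha = 0.05,
                           hub_quantile = 0.25,
                           fdr_q = 0.05,
                           rng_seed = 1,
                           louvain_restarts = 10,
                           mrcc_sampling = c("event", "grid"),
                           ss_type = c("II", "III")) {
  new("PipelineConfig",
      thresholdPLevels = as.numeric(threshold_p_levels),
      nNullPermutations = as.integer(n_null_permutations),
      nMrccPartitions = as.integer(n_mrcc_partitions),
      mrccAlpha = as.numeric(mrcc_alpha),
      hubQuantile = as.numeric(hub_quantile),
      fdrQ = as.numeric(fdr_q),
      rngSeed = as.integer(rng_seed),
      louvainRestarts = as.integer(louvain_restarts),
      mrccSampling = match.arg(mrcc_sampling),
      ssType = match.arg(ss_type))
}

#' Construct a Partition from a membership vector
#'
#' Labels are re-coded to contiguous integers starting at 1 in order of
#' first appearance, so two partitions that differ only by a relabelling
#' have identical canonical form.
#'
#' @param labels integer-like community membership, one entry per region.
#' @param region_labels character, region names.
#' @param gamma resolution parameter the partition was obtained at (NA when
#'   not applicable).
#' @return a \linkS4class{Partition}.
#' @export
partition <- function(labels, region_labels = names(labels), gamma = NA_real_) {
  if (is.null(region_labels))
    region_labels <- paste0("R", seq_along(labels))
  new("Partition",
      regionLabels = as.character(region_labels),
      labels = .canonical_labels(labels),
      gamma = as.numeric(gamma))
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' SUVR matrix of an uptake table
#'
#' @param x an \linkS4class{UptakeTable}.
#' @return numeric matrix, animals x regions (the orientation the statistics
#'   are computed in: correlation across animals within a region pair).
#' @export
setMethod("suvrMatrix", "UptakeTable", function(x) t(assay(x, "suvr")))

#' Region labels
#' @param x an UptakeTable, network, Partition or ConsensusResult.
#' @return character vector of region names.
#' @export
setMethod("regionLabels", "UptakeTable", function(x) rownames(x))

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "CovarianceNetwork", function(x) x@regionLabels)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "Partition", function(x) x@regionLabels)

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "ConsensusResult",
          function(x) x@consensus@regionLabels)

#' Group identifier
#' @param x an UptakeTable or CovarianceNetwork.
#' @return character(1).
#' @export
setMethod("groupId", "UptakeTable", function(x) metadata(x)$group_id)

#' @rdname groupId
#' @export
setMethod("groupId", "CovarianceNetwork", function(x) x@groupId)

#' Number of animals
#' @param x an UptakeTable or CovarianceNetwork.
#' @return integer(1).
#' @export
setMethod("nAnimals", "UptakeTable", function(x) ncol(x))

#' @rdname nAnimals
#' @export
setMethod("nAnimals", "CovarianceNetwork", function(x) x@nAnimals)

#' Edge-weight matrix of a network
#' @param x a \linkS4class{CovarianceNetwork} or
#'   \linkS4class{ThresholdedNetwork}.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setMethod("edgeWeights", "CovarianceNetwork", function(x) x@weights)

#' Edge permutation p-values of a network
#' @param x a \linkS4class{CovarianceNetwork}.
#' @return symmetric numeric matrix, or NULL when significance has not been
#'   assessed.
#' @export
setMethod("edgePValues", "CovarianceNetwork", function(x) {
  if (length(x@edgeP)) x@edgeP else NULL
})

#' Threshold level of a thresholded network
#' @param x a \linkS4class{ThresholdedNetwork}.
#' @return numeric(1).
#' @export
setMethod("thresholdLevel", "ThresholdedNetwork", function(x) x@level)

#' Fragmentation flag of a thresholded network
#' @param x a \linkS4class{ThresholdedNetwork}.
#' @return logical(1): TRUE when some node or node group is disconnected
#'   from the rest of the network.
#' @export
setMethod("isFragmented", "ThresholdedNetwork", function(x) x@fragmented)

#' Community membership of a partition
#' @param x a \linkS4class{Partition} or \linkS4class{ConsensusResult}.
#' @return named integer vector of community ids (1-based, contiguous).
#' @export
setMethod("membership", "Partition",
          function(x) setNames(x@labels, x@regionLabels))

#' @rdname membership
#' @export
setMethod("membership", "ConsensusResult",
          function(x) membership(x@consensus))

#' Number of communities
#' @param x a \linkS4class{Partition} or \linkS4class{ConsensusResult}.
#' @return integer(1).
#' @export
setMethod("nCommunities", "Partition", function(x) max(x@labels))

#' @rdname nCommunities
#' @export
setMethod("nCommunities", "ConsensusResult",
          function(x) nCommunities(x@consensus))

#' Co-assignment matrix of an MRCC ensemble
#' @param x a \linkS4class{ConsensusResult}.
#' @return symmetric numeric matrix in [0, 1] with unit diagonal.
#' @export
setMethod("coassignment", "ConsensusResult", function(x) x@coassignment)

#' Consensus partition of an MRCC result
#' @param x a \linkS4class{ConsensusResult}.
#' @return a \linkS4class{Partition}.
#' @export
setMethod("consensusPartition", "ConsensusResult", function(x) x@consensus)

#' Hierarchy of consensus partitions, coarse to fine
#' @param x a \linkS4class{ConsensusResult}.
#' @return list of \linkS4class{Partition}; the last element is the
#'   consensus partition.
#' @export
setMethod("hierarchyPartitions", "ConsensusResult", function(x) x@hierarchy)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "UptakeTable", function(object) {
  md <- metadata(object)
  cat(sprintf(
    "UptakeTable '%s' (%s %s, %g months): %d animals x %d regions\n",
    md$group_id, md$genotype, md$sex, md$age_months,
    ncol(object), nrow(object)))
  v <- assay(object, "suvr")
  cat(sprintf("  SUVR range [%.3f, %.3f]\n", min(v), max(v)))
})

setMethod("show", "CovarianceNetwork", function(object) {
  p <- length(object@regionLabels)
  cat(sprintf("CovarianceNetwork '%s': %d regions, %d unique edges, n = %d animals\n",
              object@groupId, p, p * (p - 1L) / 2L, object@nAnimals))
  cat(sprintf("  edge weights in [%.3f, %.3f]; permutation p-values: %s\n",
              min(.lower_tri(object@weights)), max(.lower_tri(object@weights)),
              if (length(object@edgeP)) "present" else "absent"))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  p <- length(object@regionLabels)
  kept <- sum(.lower_tri(object@weights) != 0)
  cat(sprintf(
    "ThresholdedNetwork '%s' (p < %g): %d/%d edges retained%s\n",
    object@groupId, object@level, kept, p * (p - 1L) / 2L,
    if (object@fragmented) " [fragmented]" else ""))
})

setMethod("show", "Partition", function(object) {
  k <- if (length(object@labels)) max(object@labels) else 0L
  cat(sprintf("Partition: %d regions in %d communities%s\n",
              length(object@labels), k,
              if (is.na(object@gamma)) "" else sprintf(" (gamma = %.4g)",
                                                       object@gamma)))
  cat("  sizes:", paste(tabulate(object@labels), collapse = ", "), "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: ensemble of %d partitions over gamma in [%.3g, %.3g]\n",
    object@ensembleSize, object@gammaRange[1], object@gammaRange[2]))
  cat(sprintf("  consensus: %d communities (alpha = %g); hierarchy depth %d\n",
              nCommunities(object@consensus), object@alpha,
              length(object@hierarchy)))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison %s vs %s\n", object@pair[1], object@pair[2]))
  cat(sprintf("  edge-weight KS: D = %.3f, p = %.4g\n",
              object@ksStat, object@ksP))
  cat(sprintf("  edgewise permutation test (%d permutations): %d/%d edges p < 0.05, %d FDR-significant\n",
              object@nPerm,
              sum(.lower_tri(object@sigUncorrected)),
              length(.lower_tri(object@edgeP)),
              sum(.lower_tri(object@sigFdr))))
})

setMethod("show", "GroupSimSpec", function(object) {
  cat(sprintf(
    "GroupSimSpec: n = %d animals, %d regions, %d planted modules\n",
    object@nAnimals, object@nRegions, max(object@plantedPartition)))
  cat(sprintf("  rho within/between = %.2f/%.2f, noise SD = %.3g, seed = %s\n",
              object@rhoWithin, object@rhoBetween, object@noiseSd,
              ifelse(is.na(object@seed), "none", object@seed)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  cat(sprintf("  thresholds p < {%s}; %d null permutations\n",
              paste(object@thresholdPLevels, collapse = ", "),
              object@nNullPermutations))
  cat(sprintf("  MRCC: %d partitions, alpha = %g, %s sampling\n",
              object@nMrccPartitions, object@mrccAlpha, object@mrccSampling))
  cat(sprintf("  hubs: top %.0f%%; FDR q < %g; ANOVA type %s SS; seed = %d\n",
              100 * object@hubQuantile, object@fdrQ, object@ssType,
              object@rngSeed))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("AnovaResult (type %s sums of squares):\n", object@ssType))
  print(object@table, digits = 4, row.names = FALSE)
})
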