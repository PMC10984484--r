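#' @include AllClasses.R
NULL

#' @rdname edgeWeights
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname edgePValues
#' @export
setGeneric("edgePValues", function(x) standardGeneric("edgePValues"))

#' @rdname regionLabels
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname groupId
#' @export
setGeneric("groupId", function(x) standardGeneric("groupId"))

#' @rdname nAnimals
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname suvrMatrix
#' @export
setGeneric("suvrMatrix", function(x) standardGeneric("suvrMatrix"))

#' @rdname membership
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname nCommunities
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname coassignment
#' @export
setGeneric("coassignment", function(x) standardGeneric("coassignment"))

#' @rdname consensusPartition
#' @export
setGeneric("consensusPartition", function(x) standardGeneric("consensusPartition"))

#' @rdname hierarchyPartitions
#' @export
setGeneric("hierarchyPartitions", function(x) standardGeneric("hierarchyPartitions"))

#' @rdname thresholdLevel
#' @export
setGeneric("thresholdLevel", function(x) standardGeneric("thresholdLevel"))

#' @rdname isFragmented
#' @export
setGeneric("isFragmented", function(x) standardGeneric("isFragmented"))

#' Build the group covariance network from an uptake table
#'
#' @param table an \linkS4class{UptakeTable} (or, for internal use, a plain
#'   animals x regions numeric matrix).
#' @return a \linkS4class{CovarianceNetwork}.
#' @seealso [edgeSignificance()], [thresholdNetwork()]
#' @export
setGeneric("covarianceNetwork", function(table) standardGeneric("covarianceNetwork"))

#' @rdname identifyHubs
#' @export
setGeneric("identifyHubs", function(x, quantile = 0.25,
                                    mode = c("degree", "strength"), ...)
  standardGeneric("identifyHubs"))
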