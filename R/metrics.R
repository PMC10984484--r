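#' @include accessors.R
NULL

#' Network density
#'
#' Number and fraction of region pairs with a nonzero edge.
#'
#' @param net a \linkS4class{CovarianceNetwork} or
#'   \linkS4class{ThresholdedNetwork}.
#' @return list with \code{edge_count} (integer) and \code{fraction}
#'   (edge_count divided by the p(p-1)/2 unique pairs; 351 for 27 regions).
#' @export
networkDensity <- function(net) {
  w <- .lower_tri(edgeWeights(net))
  list(edge_count = sum(w != 0), fraction = sum(w != 0) / length(w))
}

#' Nodal degree
#'
#' Number of nonzero edges incident to each region. Degrees satisfy the
#' handshake identity: their sum is twice the edge count.
#'
#' @param net a network object.
#' @return named integer vector (0..p-1 per region).
#' @export
nodalDegree <- function(net) {
  w <- edgeWeights(net)
  setNames(as.integer(rowSums(w != 0)), regionLabels(net))
}

#' Signed nodal strengths
#'
#' Separate sums of positive edge weights and of magnitudes of negative edge
#' weights at each region. Both are reported as nonnegative quantities;
#' their difference is the plain (net) weighted strength, and their sum is
#' the cumulative absolute strength used for strength-based hubs.
#'
#' @param net a network object.
#' @return data.frame with columns region, strength_pos, strength_neg.
#' @export
nodalStrength <- function(net) {
  w <- edgeWeights(net)
  data.frame(region = regionLabels(net),
             strength_pos = rowSums(pmax(w, 0)),
             strength_neg = rowSums(pmax(-w, 0)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signed weighted clustering coefficient
#'
#' Per-region clustering coefficient for signed weighted networks, the
#' generalization in which triangle products keep their signs so that
#' unbalanced triangles (an odd number of negative edges) reduce
#' clustering. With weights rescaled by the network-wide maximum magnitude,
#' \eqn{\hat w = w / \max|w|}:
#' \deqn{C_i = \frac{\sum_{j \ne i} \sum_{k \ne i,j} \hat w_{ij} \hat w_{jk}
#'   \hat w_{ki}}{\sum_{j \ne i} \sum_{k \ne i,j} |\hat w_{ij} \hat w_{ki}|},}
#' with \eqn{C_i = 0} when the denominator vanishes (fewer than two
#' neighbours). Values lie in [-1, 1]; a triangle of maximal positive
#' weights gives 1.
#'
#' @param net a network object (or a plain symmetric zero-diagonal matrix).
#' @return named numeric vector of per-region coefficients.
#' @export
signedClustering <- function(net) {
  w <- if (is.matrix(net)) net else edgeWeights(net)
  labs <- if (is.matrix(net)) {
    if (is.null(rownames(net))) paste0("R", seq_len(nrow(net))) else rownames(net)
  } else regionLabels(net)
  mx <- max(abs(w))
  if (mx == 0) return(setNames(numeric(nrow(w)), labs))
  wh <- w / mx
  num <- diag(wh %*% wh %*% wh)          # signed 3-cycles through each node
  aw <- abs(wh)
  den <- rowSums(aw)^2 - rowSums(aw^2)   # all (j, k) neighbour pairs, j != k
  ci <- ifelse(den > 0, num / den, 0)
  setNames(ci, labs)
}

#' @rdname identifyHubs
#' @details Hubs are the top-quartile regions by either nodal degree or
#'   cumulative absolute strength (\code{strength_pos + strength_neg});
#'   exactly \code{ceiling(p * quantile)} regions are returned (7 of 27 at
#'   the default quartile rule). Ranking is descending; ties are broken by
#'   region index order, so the result is deterministic.
#' @param x a network object, or a named numeric vector of per-region metric
#'   values.
#' @param quantile top fraction of regions to label as hubs (default 0.25).
#' @param mode \code{"degree"} or \code{"strength"}; ignored when \code{x}
#'   is already a metric vector.
#' @param ... unused.
#' @return character vector of hub region labels, in rank order.
#' @export
setMethod("identifyHubs", "numeric",
  function(x, quantile = 0.25, mode = c("degree", "strength"), ...) {
    n <- length(x)
    n_hubs <- ceiling(n * quantile)
    labs <- if (is.null(names(x))) paste0("R", seq_len(n)) else names(x)
    ord <- order(-x, seq_len(n))
    labs[ord[seq_len(n_hubs)]]
  })

#' @rdname identifyHubs
#' @export
setMethod("identifyHubs", "CovarianceNetwork",
  function(x, quantile = 0.25, mode = c("degree", "strength"), ...) {
    mode <- match.arg(mode)
    metric <- if (mode == "degree") {
      as.numeric(nodalDegree(x))
    } else {
      s <- nodalStrength(x)
      s$strength_pos + s$strength_neg
    }
    identifyHubs(setNames(metric, regionLabels(x)), quantile = quantile)
  })

#' Nodal metrics table
#'
#' Degree, signed strengths and signed clustering coefficient for every
#' region of a network, in one data.frame.
#'
#' @param net a network object.
#' @return data.frame with columns region, degree, strength_pos,
#'   strength_neg, clustering.
#' @export
nodalMetrics <- function(net) {
  s <- nodalStrength(net)
  data.frame(region = s$region,
             degree = as.integer(nodalDegree(net)),
             strength_pos = s$strength_pos,
             strength_neg = s$strength_neg,
             clustering = as.numeric(signedClustering(net)),
             row.names = NULL, stringsAsFactors = FALSE)
}
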