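#' @include accessors.R
NULL

#' Standardized uptake value ratio (SUVR)
#'
#' Ratio of a region of interest's activity to the cerebellar reference
#' region's activity (both in Bq/ml), removing dose and body-mass effects.
#'
#' @param region_activity regional tracer activity, > 0 (vectorised).
#' @param cerebellum_activity reference-region activity, > 0.
#' @return dimensionless SUVR, \code{region_activity / cerebellum_activity}.
#' @examples
#' computeSUVR(2.4, 1.2)  # 2
#' @export
computeSUVR <- function(region_activity, cerebellum_activity) {
  if (any(!is.finite(cerebellum_activity)) || any(cerebellum_activity <= 0))
    stop("cerebellum (reference region) activity must be strictly positive")
  if (any(!is.finite(region_activity)) || any(region_activity <= 0))
    stop("region activity must be strictly positive")
  region_activity / cerebellum_activity
}

#' Z-score each region across the animals of a group
#'
#' Centres and scales every region (column) to mean 0 and sample SD 1
#' (n - 1 denominator) across animals. Pearson correlation is invariant to
#' this affine transform, so the covariance network is unchanged; z-scoring
#' matters only for inspecting the values themselves.
#'
#' @param table an \linkS4class{UptakeTable}.
#' @return a \linkS4class{SummarizedExperiment} with assay \code{"zscore"}
#'   (z-scores can be negative, so the result is not an UptakeTable).
#' @export
zscoreByRegion <- function(table) {
  stopifnot(is(table, "UptakeTable") || is(table, "SummarizedExperiment"))
  m <- assay(table, if ("suvr" %in% names(assays(table))) "suvr" else "zscore")
  s <- apply(m, 1L, sd)
  if (any(s == 0))
    stop("zero-variance region(s): ",
         paste(rownames(m)[s == 0], collapse = ", "))
  z <- (m - rowMeans(m)) / s
  out <- SummarizedExperiment(assays = list(zscore = z),
                              colData = colData(table))
  metadata(out) <- metadata(table)
  out
}

.cor_from_values <- function(values) {
  s <- apply(values, 2L, sd)
  if (any(s == 0))
    stop("zero-variance region(s): ",
         paste(colnames(values)[s == 0], collapse = ", "))
  r <- cor(values)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 0
  (r + t(r)) / 2
}

#' @describeIn covarianceNetwork Pearson covariance network of an uptake
#'   table: weight(i, j) is the Pearson correlation of regions i and j
#'   across the animals of the group; the diagonal is fixed at 0.
#' @export
setMethod("covarianceNetwork", "UptakeTable", function(table) {
  validObject(table)
  w <- .cor_from_values(suvrMatrix(table))
  new("CovarianceNetwork",
      groupId = groupId(table),
      regionLabels = regionLabels(table),
      weights = w,
      nAnimals = nAnimals(table))
})

#' @describeIn covarianceNetwork method for a plain animals x regions matrix
#'   (labels taken from column names).
#' @export
setMethod("covarianceNetwork", "matrix", function(table) {
  labs <- colnames(table)
  if (is.null(labs)) labs <- paste0("R", seq_len(ncol(table)))
  new("CovarianceNetwork",
      groupId = NA_character_,
      regionLabels = labs,
      weights = .cor_from_values(table),
      nAnimals = nrow(table))
})

#' Edge-level significance under the random-shift null
#'
#' Permutation p-values for every edge of the group covariance network.
#' Each null iterate independently permutes every region's SUVR values
#' across animals (a "random shift": marginals are preserved, inter-regional
#' covariance is destroyed) and recomputes the full correlation matrix.
#' Positive and negative correlations are handled separately: an empirical
#' correlation is compared only against null correlations of the same sign,
#' and the p-value is the add-one exceedance proportion among those
#' same-sign nulls,
#' \deqn{p_{ij} = \frac{1 + \#\{|r^{null}_{ij}| \ge |r_{ij}|,\;
#'   \mathrm{sign\ match}\}}{1 + \#\{\mathrm{sign\ match}\}}.}
#' The sign-conditional denominator keeps the test calibrated (empirical
#' type-I error at nominal 0.05 is ~0.05 under the null); the add-one form
#' bounds p away from 0, with minimum attainable value at least
#' \code{1/(n_perm + 1)}. An exactly zero empirical correlation gets p = 1.
#'
#' @param table an \linkS4class{UptakeTable}.
#' @param n_perm number of permutations (>= 100; the study default is
#'   10000).
#' @param seed RNG seed.
#' @return symmetric matrix of p-values in (0, 1], diagonal 1.
#' @seealso [thresholdNetwork()], [covarianceNetwork()]
#' @export
edgeSignificance <- function(table, n_perm = 10000, seed = NULL) {
  stopifnot(is(table, "UptakeTable"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  x <- suvrMatrix(table)
  n <- nrow(x); p <- ncol(x)
  r_emp <- .lower_tri(.cor_from_values(x))
  emp_sign <- sign(r_emp)
  exceed <- integer(length(r_emp))
  same_sign_n <- integer(length(r_emp))
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      xp <- x
      for (j in seq_len(p)) xp[, j] <- x[sample.int(n), j]
      r0 <- cor(xp)[lower.tri(diag(p))]
      match_sign <- sign(r0) == emp_sign
      same_sign_n <- same_sign_n + match_sign
      exceed <- exceed + (match_sign & abs(r0) >= abs(r_emp))
    }
  })
  pvals <- (1 + exceed) / (1 + same_sign_n)
  pvals[emp_sign == 0] <- 1
  .sym_from_lower(pvals, p, diag_value = 1, labels = regionLabels(table))
}

#' Threshold a covariance network at a significance level
#'
#' Edges with permutation p-value below \code{level} keep their signed
#' Pearson weight; all other edges are set to 0. The fragmentation flag is
#' set by a connected-components check on the surviving edges: the network
#' is fragmented when a node or a group of nodes is disconnected from the
#' rest.
#'
#' @param net a \linkS4class{CovarianceNetwork} whose \code{edgeP} has been
#'   filled in (e.g. via [edgeSignificance()]).
#' @param level significance level; edge sets at stricter levels are nested
#'   inside those at looser levels of the same base network.
#' @return a \linkS4class{ThresholdedNetwork}.
#' @export
thresholdNetwork <- function(net, level = 0.05) {
  stopifnot(is(net, "CovarianceNetwork"))
  ep <- edgePValues(net)
  if (is.null(ep))
    stop("network has no edge p-values; run edgeSignificance() first")
  w <- edgeWeights(net)
  if (level < 1) w[ep >= level] <- 0   # at level 1 every edge is retained
  diag(w) <- 0
  g <- graph_from_adjacency_matrix(w != 0, mode = "undirected", diag = FALSE)
  frag <- components(g)$no > 1L
  new("ThresholdedNetwork",
      groupId = net@groupId,
      regionLabels = net@regionLabels,
      weights = w,
      edgeP = ep,
      nAnimals = net@nAnimals,
      level = level,
      fragmented = frag)
}

#' Attach edge p-values to a covariance network
#'
#' Convenience wrapper: computes [edgeSignificance()] for the table and
#' returns the network with its \code{edgeP} slot filled.
#'
#' @param net a \linkS4class{CovarianceNetwork} estimated from \code{table}.
#' @param table the \linkS4class{UptakeTable} the network came from.
#' @param n_perm,seed passed to [edgeSignificance()].
#' @return the network with p-values attached.
#' @export
withEdgeSignificance <- function(net, table, n_perm = 10000, seed = NULL) {
  stopifnot(is(net, "CovarianceNetwork"))
  .check_same_regions(regionLabels(net), regionLabels(table), "networks")
  net@edgeP <- edgeSignificance(table, n_perm = n_perm, seed = seed)
  validObject(net)
  net
}
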