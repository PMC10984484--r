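#' @include network.R metrics.R
NULL

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference between the two empirical CDFs;
#' the p-value uses the asymptotic two-sample KS distribution.
#'
#' @param x,y numeric samples (nonempty).
#' @return list with \code{statistic} (D in [0, 1]) and \code{p.value}.
#' @examples
#' ksTwoSample(c(1, 2), c(1.5, 2.5))$statistic  # 0.5
#' @export
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = as.numeric(kt$statistic), p.value = as.numeric(kt$p.value))
}

#' Edgewise group-label permutation test
#'
#' Tests every edge for a between-group difference in covariance. The
#' statistic is the edge-weight difference
#' \eqn{\Delta r_{ij} = r^A_{ij} - r^B_{ij}} - the covariance networks are
#' group-level constructs, so there is no per-animal edge to t-test; the
#' null is built by randomly reassigning the pooled \eqn{n_A + n_B} animals
#' to two groups of the original sizes and recomputing both covariance
#' networks at each permutation. Two-sided p-values with the add-one
#' correction, \eqn{p = (1 + \#\{|\Delta r^{null}| \ge |\Delta r|\}) /
#' (n_{perm} + 1)}.
#'
#' @param tableA,tableB \linkS4class{UptakeTable}s over the same regions.
#' @param n_perm number of label permutations (study default 10000).
#' @param seed RNG seed.
#' @return symmetric matrix of p-values in (0, 1], diagonal 1.
#' @export
edgewisePermutationTest <- function(tableA, tableB, n_perm = 10000,
                                    seed = NULL) {
  .check_same_regions(regionLabels(tableA), regionLabels(tableB), "tables")
  xa <- suvrMatrix(tableA)
  xb <- suvrMatrix(tableB)
  ## canonical pooling order: the statistic is two-sided, so swapping the
  ## two groups must give the identical p matrix, including the Monte
  ## Carlo stream
  key <- function(x) paste(rownames(x), collapse = "\r")
  if (key(xb) < key(xa)) {
    tmp <- xa; xa <- xb; xb <- tmp
  }
  na <- nrow(xa); nb <- nrow(xb)
  if (na < 3L || nb < 3L) stop("both groups need at least 3 animals")
  p <- ncol(xa)
  lt <- lower.tri(diag(p))
  d_obs <- abs(.cor_from_values(xa)[lt] - .cor_from_values(xb)[lt])
  pooled <- rbind(xa, xb)
  exceed <- integer(sum(lt))
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(na + nb)
      d0 <- cor(pooled[idx[seq_len(na)], , drop = FALSE])[lt] -
        cor(pooled[idx[-seq_len(na)], , drop = FALSE])[lt]
      exceed <- exceed + (abs(d0) >= d_obs)
    }
  })
  pv <- (1 + exceed) / (n_perm + 1)
  .sym_from_lower(pv, p, diag_value = 1, labels = regionLabels(tableA))
}

#' Benjamini-Hochberg FDR over the network edges
#'
#' Step-up false discovery rate control over the m = p(p-1)/2 unique edge
#' tests (351 for 27 regions). Adjusted values are monotone nondecreasing
#' in the p-value rank; edges rejected at level q always include every edge
#' that any smaller q would reject.
#'
#' @param p_values numeric vector of p-values in (0, 1] (e.g. the lower
#'   triangle of an edge p matrix).
#' @param q FDR level (default 0.05).
#' @return list with \code{rejected} (logical) and \code{adjusted}
#'   (BH-adjusted p-values).
#' @export
fdrBH <- function(p_values, q = 0.05) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(rejected = adj < q, adjusted = adj)
}

#' Full between-group comparison of two uptake tables
#'
#' Composes the between-group statistics for one group pair: (1) a KS test
#' on the two 351-edge weight distributions of the unthresholded covariance
#' networks; (2) KS tests on nodal-metric distributions (degree, positive
#' and negative strength, clustering) of the thresholded networks at each
#' configured level; (3) the edgewise group-label permutation test with BH
#' FDR control across edges.
#'
#' @param tableA,tableB \linkS4class{UptakeTable}s over the same regions.
#' @param config a \linkS4class{PipelineConfig}; \code{n_null_permutations}
#'   drives both the edge-significance null (for thresholding) and the
#'   edgewise test, \code{fdr_q} the FDR level.
#' @param seed RNG seed (defaults to the config's).
#' @return a \linkS4class{GroupComparison}.
#' @export
compareGroups <- function(tableA, tableB, config = pipelineConfig(),
                          seed = config@rngSeed) {
  .check_same_regions(regionLabels(tableA), regionLabels(tableB), "tables")
  seeds <- .derive_seeds(seed, 4L)
  netA <- covarianceNetwork(tableA)
  netB <- covarianceNetwork(tableB)
  ks_edges <- ksTwoSample(.lower_tri(edgeWeights(netA)),
                          .lower_tri(edgeWeights(netB)))
  ## nodal metric distributions per threshold level
  netA@edgeP <- edgeSignificance(tableA, config@nNullPermutations, seeds[1])
  netB@edgeP <- edgeSignificance(tableB, config@nNullPermutations, seeds[2])
  nodal <- do.call(rbind, lapply(config@thresholdPLevels, function(lev) {
    tA <- thresholdNetwork(netA, lev)
    tB <- thresholdNetwork(netB, lev)
    mA <- nodalMetrics(tA)
    mB <- nodalMetrics(tB)
    do.call(rbind, lapply(
      c("degree", "strength_pos", "strength_neg", "clustering"),
      function(metric) {
        kt <- ksTwoSample(mA[[metric]], mB[[metric]])
        data.frame(metric = metric, level = lev,
                   D = kt$statistic, p = kt$p.value,
                   stringsAsFactors = FALSE)
      }))
  }))
  edge_p <- edgewisePermutationTest(tableA, tableB,
                                    n_perm = config@nNullPermutations,
                                    seed = seeds[3])
  bh <- fdrBH(.lower_tri(edge_p), q = config@fdrQ)
  p <- length(regionLabels(tableA))
  edge_q <- .sym_from_lower(bh$adjusted, p, diag_value = 1,
                            labels = regionLabels(tableA))
  new("GroupComparison",
      pair = c(groupId(tableA), groupId(tableB)),
      ksStat = ks_edges$statistic,
      ksP = ks_edges$p.value,
      ksNodal = nodal,
      edgeP = edge_p,
      edgeQ = edge_q,
      sigUncorrected = edge_p < 0.05,
      sigFdr = edge_q < config@fdrQ,
      nPerm = config@nNullPermutations)
}
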