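#' @include accessors.R
NULL

## Expected mutual information (natural log) of two label vectors under the
## permutation model with fixed marginal community sizes (hypergeometric
## model). Computed exactly with log-gamma terms; cheap at network sizes.
.expected_mi <- function(a, b, N) {
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) +
        lgamma(N - bj + 1) - lgamma(N + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      emi <- emi + sum(nij / N * log(N * nij / (ai * bj)) * exp(lw))
    }
  }
  emi
}

.entropy <- function(sizes, N) {
  p <- sizes[sizes > 0] / N
  -sum(p * log(p))
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected similarity of two community partitions of the same
#' regions:
#' \deqn{\mathrm{AMI} = \frac{I - E[I]}{\tfrac{1}{2}(H_1 + H_2) - E[I]},}
#' where \eqn{I} is the mutual information of the two labelings, \eqn{E[I]}
#' its expectation under the permutation model with fixed community sizes,
#' and \eqn{H_1, H_2} the label entropies (arithmetic-mean normalization).
#' AMI is 1 exactly when the partitions are identical up to relabelling,
#' and ~0 for independent partitions regardless of community counts.
#'
#' @param p1,p2 \linkS4class{Partition} objects (or plain membership
#'   vectors) over the same regions.
#' @return numeric(1) in (-Inf, 1].
#' @examples
#' a <- partition(c(1, 1, 2, 2), paste0("R", 1:4))
#' b <- partition(c(2, 2, 1, 1), paste0("R", 1:4))
#' ami(a, b)  # 1: identical up to relabelling
#' @export
ami <- function(p1, p2) {
  l1 <- if (is(p1, "Partition")) p1@labels else .canonical_labels(p1)
  l2 <- if (is(p2, "Partition")) p2@labels else .canonical_labels(p2)
  if (is(p1, "Partition") && is(p2, "Partition"))
    .check_same_regions(p1@regionLabels, p2@regionLabels, "networks")
  if (length(l1) != length(l2))
    stop("partitions must cover the same regions (length mismatch: ",
         length(l1), " vs ", length(l2), ")")
  N <- length(l1)
  a <- tabulate(l1)
  b <- tabulate(l2)
  ## the two trivial extremes are perfect matches by convention
  if ((max(l1) == 1L && max(l2) == 1L) || (max(l1) == N && max(l2) == N))
    return(1)
  tab <- table(l1, l2)
  pij <- tab / N
  pi_ <- rowSums(pij); p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  emi <- .expected_mi(a, b, N)
  h1 <- .entropy(a, N)
  h2 <- .entropy(b, N)
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < .Machine$double.eps)
    return(if (abs(mi - emi) < .Machine$double.eps) 1 else 0)
  (mi - emi) / denom
}

#' Co-classification matrix of a set of partitions
#'
#' For every region pair, the fraction of the supplied partitions that
#' assign the pair to the same community; used both for MRCC ensembles and
#' for comparing consensus partitions across groups. The per-region mean
#' co-classification excludes the (always 1) diagonal.
#'
#' @param partitions list of at least two \linkS4class{Partition} objects
#'   over the same regions.
#' @return list with \code{matrix} (symmetric, unit diagonal, entries in
#'   [0, 1]) and \code{region_mean} (named numeric).
#' @export
coclassification <- function(partitions) {
  if (length(partitions) < 2L)
    stop("at least two partitions are required")
  labs <- regionLabels(partitions[[1]])
  for (p in partitions[-1])
    .check_same_regions(labs, regionLabels(p), "networks")
  n <- length(labs)
  A <- matrix(0, n, n)
  for (p in partitions) {
    l <- p@labels
    A <- A + outer(l, l, "==")
  }
  A <- A / length(partitions)
  dimnames(A) <- list(labs, labs)
  rm <- (rowSums(A) - diag(A)) / (n - 1)
  list(matrix = A, region_mean = setNames(rm, labs))
}
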