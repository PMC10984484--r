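#' @include accessors.R
NULL

#' Signed modularity matrix
#'
#' Builds the quality matrix B of the signed modularity used for community
#' detection on correlation-derived networks, with asymmetric treatment of
#' positive and negative weights: positive within-community weight is
#' rewarded relative to its share of total positive weight, negative
#' within-community weight is penalized relative to the combined total
#' (the "negative-asymmetric" convention recommended for signed
#' correlation networks),
#' \deqn{Q(\gamma) = \frac{1}{v^+} \sum_{ij} (w^+_{ij} - \gamma e^+_{ij})
#'   \delta_{c_i c_j} - \frac{1}{v^+ + v^-} \sum_{ij} (w^-_{ij} - \gamma
#'   e^-_{ij}) \delta_{c_i c_j},}
#' with \eqn{e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm}, \eqn{s^\pm} the signed
#' strengths and \eqn{v^\pm} the total positive/negative weight. The
#' partition quality is then \code{sum(B * delta)}.
#'
#' @param w symmetric weight matrix with zero diagonal.
#' @param gamma resolution parameter (> 0); larger values favour more,
#'   smaller communities.
#' @return symmetric matrix B of the same dimension as \code{w}.
#' @seealso [louvainSigned()], [signedModularity()]
#' @export
signedModularityMatrix <- function(w, gamma = 1) {
  if (gamma <= 0) stop("gamma must be > 0")
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  sp <- rowSums(wp); sn <- rowSums(wn)
  vp <- sum(sp); vn <- sum(sn)
  B <- matrix(0, nrow(w), ncol(w))
  if (vp > 0) B <- B + (wp - gamma * outer(sp, sp) / vp) / vp
  if (vn > 0) B <- B - (wn - gamma * outer(sn, sn) / vn) / (vp + vn)
  (B + t(B)) / 2
}

#' Signed modularity of a partition
#'
#' @param w symmetric weight matrix with zero diagonal (or a network
#'   object).
#' @param labels integer membership vector or \linkS4class{Partition}.
#' @param gamma resolution parameter.
#' @return numeric(1), the quality Q (including the constant diagonal
#'   contribution of the null term).
#' @export
signedModularity <- function(w, labels, gamma = 1) {
  if (!is.matrix(w)) w <- edgeWeights(w)
  if (is(labels, "Partition")) labels <- labels@labels
  B <- signedModularityMatrix(w, gamma)
  sum(B[outer(labels, labels, "==")])
}

## One pass of local moves on quality matrix B (diagonal ignored: it is
## invariant under all moves). "greedy" always takes the best-gain move;
## "random" samples among improving moves with probability proportional
## to the gain - the randomized policy recommended for building consensus
## ensembles, where move-to-move variability is wanted so that only
## robust structure survives aggregation. Returns the membership vector.
.louvain_local_moves <- function(B, labels, moves = "greedy") {
  n <- nrow(B)
  Bo <- B
  diag(Bo) <- 0
  ## community indicator matrix, updated in place as nodes move; gains
  ## per community are then a single matrix-vector product
  D <- matrix(0, n, n)
  D[cbind(seq_len(n), labels)] <- 1
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      gains <- as.vector(Bo[i, ] %*% D)
      cur <- labels[i]
      delta <- gains - gains[cur]
      improving <- which(delta > 1e-12)
      if (!length(improving)) next
      pick <- if (moves == "random" && length(improving) > 1L) {
        improving[sample.int(length(improving), 1L,
                             prob = delta[improving])]
      } else {
        improving[which.max(delta[improving])]
      }
      D[i, cur] <- 0
      D[i, pick] <- 1
      labels[i] <- pick
      moved <- TRUE
    }
    if (!moved) break
  }
  labels
}

## Full Louvain on a quality matrix: node-level local moves alternate
## with aggregated-level moves (communities collapsed to supernodes)
## until neither improves the quality. The closing node-level sweep is
## the refinement step that lets single nodes escape communities the
## aggregation phase locked them into.
.louvain_run <- function(B, moves = "greedy") {
  n <- nrow(B)
  final <- .canonical_labels(.louvain_local_moves(B, seq_len(n), moves))
  repeat {
    changed <- FALSE
    k <- max(final)
    if (k > 1L) {
      Bagg <- rowsum(t(rowsum(B, final)), final)
      Bagg <- (Bagg + t(Bagg)) / 2
      agg <- .canonical_labels(.louvain_local_moves(Bagg, seq_len(k), moves))
      if (max(agg) < k) {
        final <- .canonical_labels(agg[final])
        changed <- TRUE
      }
    }
    lab <- .canonical_labels(.louvain_local_moves(B, final, moves))
    if (!identical(lab, final)) {
      final <- lab
      changed <- TRUE
    }
    if (!changed) break
  }
  final
}

#' Signed-modularity Louvain community detection
#'
#' Greedy multilevel (Louvain) maximization of the signed modularity
#' \eqn{Q(\gamma)} (see [signedModularityMatrix()]) on the full weighted
#' network - modularity is maximized on unthresholded networks, which
#' retain the most information. Multiple restarts with shuffled move
#' orders are run and the best-Q partition returned; ties between equal-Q
#' partitions are broken by first found.
#'
#' @param net a \linkS4class{CovarianceNetwork} or a symmetric
#'   zero-diagonal weight matrix.
#' @param gamma resolution parameter (> 0, default 1).
#' @param seed RNG seed for the move-order shuffling.
#' @param restarts number of restarts (default 10).
#' @param moves \code{"mixed"} (default: the first restart takes
#'   best-gain moves, later restarts sample improving moves with
#'   probability proportional to gain, which diversifies the basins the
#'   restarts explore), \code{"greedy"} (best-gain moves in every
#'   restart) or \code{"random"} (randomized moves in every restart; the
#'   policy used for consensus ensembles).
#' @return a \linkS4class{Partition} with \code{gamma} recorded.
#' @examples
#' w <- matrix(0, 8, 8)
#' w[1:4, 1:4] <- 0.9; w[5:8, 5:8] <- 0.9; diag(w) <- 0
#' membership(louvainSigned(w, gamma = 1, seed = 1))
#' @export
louvainSigned <- function(net, gamma = 1, seed = NULL, restarts = 10,
                          moves = c("mixed", "greedy", "random")) {
  moves <- match.arg(moves)
  w <- if (is.matrix(net)) net else edgeWeights(net)
  labs <- if (is.matrix(net)) {
    if (is.null(rownames(net))) paste0("R", seq_len(nrow(net))) else rownames(net)
  } else regionLabels(net)
  if (all(w == 0)) {
    warning("all-zero network; returning a single community")
    return(partition(rep(1L, nrow(w)), labs, gamma = gamma))
  }
  B <- signedModularityMatrix(w, gamma)
  .with_seed(seed, {
    best <- NULL
    best_q <- -Inf
    for (r in seq_len(max(1L, restarts))) {
      policy <- if (moves == "mixed") {
        if (r == 1L) "greedy" else "random"
      } else moves
      lab <- .louvain_run(B, policy)
      q <- sum(B[outer(lab, lab, "==")])
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- lab
      }
    }
    partition(best, labs, gamma = gamma)
  })
}
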