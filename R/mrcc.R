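#' @include louvain.R
NULL

## Number of communities of a seeded Louvain run at resolution gamma.
.ncomm_at <- function(w, gamma, seed) {
  p <- suppressWarnings(louvainSigned(w, gamma = gamma, seed = seed,
                                      restarts = 2))
  nCommunities(p)
}

## Locate the informative resolution interval by bisection: from the
## coarsest partition the quality function can produce (the all-one
## partition when the network admits it; correlation networks with
## negative edges may bottom out above one community) up to the finest
## (all-singletons when attainable; the negative-weight null term can make
## singletons unreachable, in which case the count plateau is used). The
## interval endpoints are the largest gamma still at the coarsest count
## and the smallest gamma already at the finest count.
.gamma_range <- function(w, seed, bisect_iter = 12) {
  seeds <- .derive_seeds(seed, 3L)
  probes <- 2^seq(-10L, 10L)
  k <- vapply(probes, function(g) .ncomm_at(w, g, seeds[1]),
              integer(1))
  k_min <- min(k)
  k_max <- max(k)
  i_lo <- max(which(k == k_min))        # last probe at the coarsest count
  i_hi <- min(which(k == k_max))        # first probe at the finest count
  ## refine the coarse boundary within (probe[i_lo], probe[i_lo + 1])
  a <- probes[i_lo]
  b <- probes[min(i_lo + 1L, length(probes))]
  for (i in seq_len(bisect_iter)) {
    mid <- sqrt(a * b)
    if (.ncomm_at(w, mid, seeds[2]) == k_min) a <- mid else b <- mid
  }
  lo <- a
  ## refine the fine boundary within (probe[i_hi - 1], probe[i_hi])
  a <- probes[max(i_hi - 1L, 1L)]
  b <- probes[i_hi]
  for (i in seq_len(bisect_iter)) {
    mid <- sqrt(a * b)
    if (.ncomm_at(w, mid, seeds[3]) >= k_max) b <- mid else a <- mid
  }
  hi <- b
  if (hi <= lo) {
    lo <- probes[i_lo]
    hi <- probes[max(i_hi, min(i_lo + 1L, length(probes)))]
  }
  ## the coarsest regime extends to gamma -> 0; give it one octave of
  ## headroom below its transition so it is represented in the (log-scale)
  ## ensemble without dominating it
  c(lo / 2, hi)
}

## Sample the Louvain ensemble across the resolution interval. Gamma is a
## ratio of observed to expected weight, so midpoints are taken
## geometrically. "event" sampling recursively bisects the interval,
## always splitting the sub-interval whose endpoint partitions differ
## most in community count (log-width breaking ties). Because refinement
## concentrates wherever the partition is still changing, the ensemble
## covers every scale EVENT - each community-count level and the
## transitions between levels - with roughly even representation,
## instead of weighting scales by the arbitrary stretch of the gamma
## axis they happen to occupy. "grid" is a plain log-spaced grid.
.sample_ensemble <- function(w, n_partitions, range, sampling, seed) {
  run_seeds <- .derive_seeds(seed, n_partitions)
  one <- function(g, s) suppressWarnings(
    louvainSigned(w, gamma = g, seed = s, restarts = 1,
                  moves = "random")@labels)
  if (sampling == "grid") {
    gs <- exp(seq(log(range[1]), log(range[2]), length.out = n_partitions))
    labs <- lapply(seq_len(n_partitions), function(i) one(gs[i], run_seeds[i]))
    return(list(gammas = gs, labels = do.call(rbind, labs)))
  }
  gs <- numeric(n_partitions)
  parts <- vector("list", n_partitions)
  gs[1:2] <- range
  parts[[1]] <- one(range[1], run_seeds[1])
  parts[[2]] <- one(range[2], run_seeds[2])
  ## interval bookkeeping: lo/hi indices into gs/parts
  int_lo <- 1L
  int_hi <- 2L
  used <- 2L
  log_span <- log(range[2] / range[1])
  min_width <- log_span * 1e-7
  priority <- function(i) {
    wdt <- log(gs[int_hi[i]] / gs[int_lo[i]])
    if (wdt <= min_width) return(0)
    kgap <- abs(max(parts[[int_hi[i]]]) - max(parts[[int_lo[i]]]))
    kgap + wdt / log_span
  }
  prio <- vapply(seq_along(int_lo), priority, numeric(1))
  while (used < n_partitions) {
    j <- which.max(prio)
    if (prio[j] <= 0) break
    mid <- sqrt(gs[int_lo[j]] * gs[int_hi[j]])
    used <- used + 1L
    gs[used] <- mid
    parts[[used]] <- one(mid, run_seeds[used])
    hi_old <- int_hi[j]
    int_hi[j] <- used
    int_lo <- c(int_lo, used)
    int_hi <- c(int_hi, hi_old)
    prio[j] <- priority(j)
    prio <- c(prio, priority(length(int_lo)))
  }
  if (used < n_partitions) {
    extra <- .with_seed(run_seeds[used],
                        exp(runif(n_partitions - used,
                                  log(range[1]), log(range[2]))))
    for (k in seq_along(extra)) {
      gs[used + k] <- extra[k]
      parts[[used + k]] <- one(extra[k], run_seeds[used + k])
    }
    used <- n_partitions
  }
  o <- order(gs[seq_len(used)])
  list(gammas = gs[o], labels = do.call(rbind, parts[o]))
}

## Co-assignment matrix of an ensemble given as a partitions x regions
## integer label matrix.
.coassignment_matrix <- function(L) {
  n <- ncol(L)
  A <- matrix(0, n, n)
  for (p in seq_len(nrow(L))) {
    l <- L[p, ]
    A <- A + (outer(l, l, "=="))
  }
  A / nrow(L)
}

## Per-partition chance co-assignment probability for a node subset: with
## community labels permuted uniformly within the subset, a fixed node
## pair lands in one community with probability
## q_p = sum_c n_c (n_c - 1) / (|S| (|S| - 1)), n_c the community sizes
## inside the subset. The null mean co-assignment is mean(q_p).
.null_coassign_probs <- function(L) {
  m <- ncol(L)
  apply(L, 1L, function(l) {
    cnt <- tabulate(l)
    sum(cnt * (cnt - 1)) / (m * (m - 1))
  })
}

## Local refinement of a proposed split against the correlation matrix:
## each region moves to the community it correlates with most strongly
## (mean correlation to the other members; empty/singleton membership
## scores 0), iterated to a fixed point. Used on observed proposals and
## null-draw proposals alike, so the refinement strength cancels in the
## significance comparison.
.refine_split <- function(r, lab, max_iter = 10) {
  n <- length(lab)
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      k <- max(lab)
      scores <- vapply(seq_len(k), function(c) {
        members <- which(lab == c)
        members <- members[members != i]
        if (!length(members)) return(0)
        mean(r[i, members])
      }, numeric(1))
      best <- which.max(scores)
      if (scores[best] > scores[lab[i]] + 1e-12 && best != lab[i]) {
        lab[i] <- best
        lab <- .canonical_labels(lab)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  lab
}

## Within-minus-between correlation contrast of a proposed split.
## Singleton communities contribute no within pairs; with no within pair
## at all the within mean is taken as 0.
.split_contrast <- function(r, lab) {
  same <- outer(lab, lab, "==") & upper.tri(r)
  diff <- outer(lab, lab, "!=") & upper.tri(r)
  w <- if (any(same)) mean(r[same]) else 0
  b <- if (any(diff)) mean(r[diff]) else 0
  w - b
}

## Null distribution of the maximized split contrast under the
## homogeneous-community model: the subset's correlation structure is
## replaced by a single equicorrelated Gaussian block (correlation =
## subset mean, floored at 0) at the group's sample size; each draw
## re-estimates the correlation matrix and searches for its best split
## the same way the observed proposal was found, so the optimization
## bias is present in null and observation alike.
.null_contrast_draws <- function(m, n_animals, rho0, n_draws, seed) {
  rho0 <- min(max(rho0, 0), 0.99)
  .with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      x <- sqrt(rho0) * rnorm(n_animals) +
        sqrt(1 - rho0) * matrix(rnorm(n_animals * m), n_animals, m)
      r <- cor(x)
      b <- r - mean(r[upper.tri(r)])
      diag(b) <- 0
      best <- -Inf
      for (rep in 1:2) {
        lab <- .louvain_run(b)
        if (max(lab) > 1L) {
          lab <- .refine_split(r, lab)
          if (max(lab) > 1L) {
            cc <- .split_contrast(r, lab)
            if (cc > best) best <- cc
          }
        }
      }
      if (is.finite(best)) best else 0
    }, numeric(1))
  })
}

## Recursive hierarchical consensus. At each node subset: (1) build the
## co-assignment matrix over the ensemble restricted to the subset and
## propose a split by Louvain on it centred at the local null mean
## (modularity with a uniform null over the chance co-assignment); (2)
## refine the proposal against the correlations (nearest-community mean
## correlation, iterated); (3) keep only boundaries that individually
## reflect significant substructure in the NETWORK itself: for every
## community pair of the proposal, the within-minus-between correlation
## contrast of separating the pair must exceed the (1 - alpha) quantile
## of the maximized contrast under the pair subset's local
## homogeneous-community null - a single equicorrelated Gaussian block
## fitted to the subset and simulated at the group's sample size; the
## least significant pair is merged and the check repeated. A subset
## whose proposal collapses to one community is a final consensus
## community.
## The model-based local null is what distinguishes genuine module
## boundaries from the sampling noise of the correlations: with n
## animals the sample correlations inside a homogeneous community spread
## widely and produce persistent fine-scale sub-clusters in the
## ensemble, and exactly that spread is reproduced under the null, so
## those sub-clusters are not declared significant.
.consensus_tree <- function(L, S, alpha, n_animals, w, seeds_env,
                            n_draws = 100) {
  if (length(S) == 1L) return(list(members = S, children = NULL))
  Ls <- L[, S, drop = FALSE]
  Ls <- t(apply(Ls, 1L, .canonical_labels))
  if (length(S) == 2L) dim(Ls) <- c(nrow(L), 2L)   # apply() drops dims
  ## a unanimous ensemble leaves nothing to test: the consensus within
  ## the subset is the unanimous partition itself
  if (all(Ls[rep(1L, nrow(Ls)), ] == Ls)) {
    lab0 <- Ls[1L, ]
    if (max(lab0) == 1L) return(list(members = S, children = NULL))
    children <- lapply(seq_len(max(lab0)), function(c)
      .consensus_tree(L, S[lab0 == c], alpha, n_animals, w, seeds_env,
                      n_draws))
    return(list(members = S, children = children))
  }
  A <- .coassignment_matrix(Ls)
  mu <- mean(.null_coassign_probs(Ls))
  B <- A - mu
  diag(B) <- 0
  lab <- .with_seed(seeds_env$take(), {
    best <- NULL; best_q <- -Inf
    for (r in 1:5) {
      cand <- .louvain_run(B)
      q <- sum(B[outer(cand, cand, "==")])
      if (q > best_q + 1e-12) { best_q <- q; best <- cand }
    }
    best
  })
  if (max(lab) == 1L)
    return(list(members = S, children = NULL))
  ## refine the ensemble proposal against the correlations themselves
  ## (the co-assignment matrix can misplace single boundary regions)
  lab <- .refine_split(w[S, S, drop = FALSE], lab)
  if (max(lab) == 1L)
    return(list(members = S, children = NULL))
  ## every remaining boundary must individually reflect significant
  ## substructure: for each community pair, the within-minus-between
  ## correlation contrast of separating them is compared with the
  ## 1 - alpha quantile of the maximized contrast under the pair
  ## subset's homogeneous null; the least significant non-significant
  ## pair is merged and the check repeated. The null critical value
  ## depends only on the subset size and its mean correlation, so it is
  ## memoized (mean correlation rounded to 0.02).
  rS <- w[S, S, drop = FALSE]
  crit_for <- function(m, rho0) {
    rho_key <- round(rho0 / 0.02) * 0.02
    key <- paste(m, rho_key)
    hit <- seeds_env$crit_cache[[key]]
    if (!is.null(hit)) return(hit)
    nulls <- .null_contrast_draws(m, n_animals, rho_key, n_draws,
                                  seeds_env$take())
    crit <- as.numeric(quantile(nulls, 1 - alpha, names = FALSE))
    seeds_env$crit_cache[[key]] <- crit
    crit
  }
  repeat {
    k <- max(lab)
    if (k == 1L) return(list(members = S, children = NULL))
    worst_excess <- Inf
    worst_pair <- NULL
    for (c1 in seq_len(k - 1L)) {
      for (c2 in seq(c1 + 1L, k)) {
        sel <- lab == c1 | lab == c2
        r_cd <- rS[sel, sel, drop = FALSE]
        lab_cd <- .canonical_labels(lab[sel])
        obs <- .split_contrast(r_cd, lab_cd)
        rho0 <- mean(r_cd[upper.tri(r_cd)])
        excess <- obs - crit_for(sum(sel), rho0)
        if (excess < worst_excess) {
          worst_excess <- excess
          worst_pair <- c(c1, c2)
        }
      }
    }
    if (worst_excess > 0) break
    lab[lab == worst_pair[2L]] <- worst_pair[1L]
    lab <- .canonical_labels(lab)
  }
  children <- lapply(seq_len(max(lab)), function(c)
    .consensus_tree(L, S[lab == c], alpha, n_animals, w, seeds_env,
                    n_draws))
  list(members = S, children = children)
}

## Cut a consensus tree at a given depth -> list of member index vectors.
.cut_tree <- function(tree, depth) {
  if (depth == 0L || is.null(tree$children)) return(list(tree$members))
  unlist(lapply(tree$children, .cut_tree, depth = depth - 1L),
         recursive = FALSE)
}

.tree_depth <- function(tree) {
  if (is.null(tree$children)) return(0L)
  1L + max(vapply(tree$children, .tree_depth, integer(1)))
}

.partition_from_groups <- function(groups, n, region_labels) {
  lab <- integer(n)
  for (i in seq_along(groups)) lab[groups[[i]]] <- i
  partition(lab, region_labels)
}

#' Multiresolution consensus clustering (MRCC)
#'
#' Ensemble community detection across resolution scales with a statistical
#' consensus. The procedure: (1) locate by bisection the informative
#' resolution interval, from the coarsest partition the signed quality
#' function can produce (the all-one partition when the network admits it)
#' to the finest (all-singletons when attainable); (2) sample
#' \code{n_partitions} randomized Louvain partitions across that interval
#' (event-style sampling by default: recursive geometric bisection driven
#' by the community-count gap, so every scale event - each community-count
#' level and the transitions between levels - is represented; a log-spaced
#' grid is available); (3) build the co-assignment matrix, the fraction of
#' ensemble partitions placing each region pair in one community; (4)
#' recursively split the regions: at each subset a split is proposed from
#' the co-assignment matrix (Louvain against the chance co-assignment,
#' agglomerated coarse-first) and accepted only when its within- minus
#' between-community correlation contrast exceeds the \code{1 - alpha}
#' quantile of the same maximized statistic under the subset's local
#' homogeneous-community null (an equicorrelated Gaussian block fitted to
#' the subset, simulated at the group's sample size). The leaves of the
#' recursion form the consensus partition; cuts of the recursion tree at
#' increasing depth form a coarse-to-fine hierarchy.
#'
#' The model-based local null is what separates genuine module boundaries
#' from sampling noise: with a dozen animals per group the sample
#' correlations inside a homogeneous community spread widely and create
#' persistent fine-scale sub-clusters in the ensemble; the null reproduces
#' exactly that spread, so such sub-clusters are not declared significant.
#'
#' @param net a \linkS4class{CovarianceNetwork} (unthresholded weighted
#'   networks are the intended input, as they retain the most information)
#'   or a symmetric zero-diagonal weight matrix.
#' @param n_partitions ensemble size (>= 100; study default 10000).
#' @param alpha significance level of the local null test (default 0.05).
#' @param seed RNG seed; the whole procedure is deterministic given it.
#' @param sampling \code{"event"} (default) or \code{"grid"}.
#' @param n_animals sample size behind the correlations, used by the local
#'   null simulations; taken from the network object when available
#'   (plain-matrix input defaults to 12, a typical group size).
#' @return a \linkS4class{ConsensusResult}.
#' @examples
#' tab <- generateGroup(groupSimSpec(12, rho_within = 0.8, rho_between = 0,
#'                                   seed = 3))
#' res <- mrcc(covarianceNetwork(tab), n_partitions = 100, seed = 3)
#' nCommunities(res)
#' @export
mrcc <- function(net, n_partitions = 10000, alpha = 0.05, seed = NULL,
                 sampling = c("event", "grid"), n_animals = NULL) {
  sampling <- match.arg(sampling)
  if (n_partitions < 100) stop("n_partitions must be >= 100")
  w <- if (is.matrix(net)) net else edgeWeights(net)
  labs <- if (is.matrix(net)) {
    if (is.null(rownames(net))) paste0("R", seq_len(nrow(net))) else rownames(net)
  } else regionLabels(net)
  if (is.null(n_animals))
    n_animals <- if (is.matrix(net)) NA_integer_ else nAnimals(net)
  if (is.na(n_animals)) {
    ## no sample size attached (plain matrix input): use the study's
    ## typical group size for the homogeneous-null simulations
    n_animals <- 12L
  }
  n <- nrow(w)
  if (all(w == 0)) {
    warning("degenerate (all-zero) network; returning a single-community consensus")
    cons <- partition(rep(1L, n), labs)
    return(new("ConsensusResult", ensembleSize = 0L,
               coassignment = .sym_from_lower(rep(1, n * (n - 1) / 2), n,
                                              diag_value = 1, labels = labs),
               consensus = cons, hierarchy = list(cons),
               alpha = alpha, gammaRange = c(NA_real_, NA_real_)))
  }
  seeds <- .derive_seeds(seed, 3L)
  range <- .gamma_range(w, seeds[1])
  ens <- .sample_ensemble(w, n_partitions, range, sampling, seeds[2])
  A <- .coassignment_matrix(ens$labels)
  diag(A) <- 1
  dimnames(A) <- list(labs, labs)
  ## deterministic seed stream for the recursive consensus
  pool <- .derive_seeds(seeds[3], 40L * n * n)
  i <- 0L
  seeds_env <- new.env()
  seeds_env$take <- function() {
    i <<- i + 1L
    pool[i]
  }
  seeds_env$crit_cache <- list()
  tree <- .consensus_tree(ens$labels, seq_len(n), alpha,
                          as.integer(n_animals), w, seeds_env)
  depth <- .tree_depth(tree)
  hierarchy <- lapply(seq_len(max(depth, 1L)), function(d)
    .partition_from_groups(.cut_tree(tree, d), n, labs))
  ## final global refinement of the finest cut against the correlations:
  ## the recursive splitting fixes community COUNT and bulk membership,
  ## but a region can end up on the wrong side of a boundary drawn at an
  ## intermediate level; the refinement reassigns each region to the
  ## community it correlates with most strongly
  consensus <- partition(
    .refine_split(w, hierarchy[[length(hierarchy)]]@labels), labs)
  hierarchy[[length(hierarchy)]] <- consensus
  new("ConsensusResult",
      ensembleSize = as.integer(nrow(ens$labels)),
      coassignment = A,
      consensus = consensus,
      hierarchy = hierarchy,
      alpha = alpha,
      gammaRange = range)
}
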