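# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Brute-force signed clustering coefficient: explicit j,k enumeration of
# the normalized triangle products and neighbour-pair magnitudes.
brute_signed_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(abs(w))
  if (mx == 0) return(numeric(n))
  wh <- w / mx
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0
    den <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        num <- num + wh[i, j] * wh[j, k] * wh[k, i]
        den <- den + abs(wh[i, j] * wh[k, i])
      }
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

# Enumerate all set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recur <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (c in seq_len(next_max)) {
      recur(c(labels, c), max(next_max, c + 1L))
    }
  }
  recur(integer(0), 1L)
  out
}

# Exhaustive-search optimum of the signed modularity over every partition.
exhaustive_best_modularity <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  best_q <- -Inf
  best_p <- NULL
  for (p in parts) {
    q <- signedModularity(w, p, gamma = gamma)
    if (q > best_q) {
      best_q <- q
      best_p <- p
    }
  }
  list(q = best_q, partition = best_p)
}

# Independent Benjamini-Hochberg step-up: sort, find the largest k with
# p(k) <= k q / m, reject those; adjusted values by the step-up recursion.
bh_stepup <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- ranked * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out_adj <- numeric(m)
  out_adj[o] <- adj
  crossing <- which(ranked <= seq_len(m) * q / m)
  rejected <- logical(m)
  if (length(crossing)) rejected[o[seq_len(max(crossing))]] <- TRUE
  list(rejected = rejected, adjusted = out_adj)
}

# Random symmetric signed weight matrix with zero diagonal.
random_signed_matrix <- function(n, density = 0.7) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < density, runif(sum(up), -1, 1), 0)
  w[up] <- vals
  w <- w + t(w)
  diag(w) <- 0
  w
}

# Small uptake table with controlled values.
toy_table <- function(values, ...) {
  uptakeTable(values,
              region_labels = paste0("R", seq_len(ncol(values))),
              animal_ids = paste0("A", seq_len(nrow(values))),
              ...)
}
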