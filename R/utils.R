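#' @include AllClasses.R
NULL

## Run `expr` under a temporary RNG state seeded with `seed`; restore the
## caller's RNG afterwards. seed = NULL/NA uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive `n` child seeds from a master seed, deterministically and
## below 2^31 (R integers are 32-bit).
.derive_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Strict lower-triangle vector of a square matrix (the 351 unique edges of
## a 27-node network), in column order.
.lower_tri <- function(m) m[lower.tri(m)]

## Rebuild a symmetric matrix (zero/one diagonal) from its strict lower
## triangle.
.sym_from_lower <- function(v, p, diag_value = 0, labels = NULL) {
  m <- matrix(diag_value, p, p)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- diag_value
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

## Relabel an integer membership vector to contiguous 1..K in order of
## first appearance (canonical form used by Partition).
.canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Shared check that two objects carry the same region set, with an error
## listing the set difference.
.check_same_regions <- function(a, b, what = c("tables", "networks")) {
  what <- match.arg(what)
  if (!identical(a, b)) {
    only_a <- setdiff(a, b)
    only_b <- setdiff(b, a)
    if (length(only_a) || length(only_b))
      stop(sprintf(
        "%s do not share the same region set; only in first: {%s}; only in second: {%s}",
        what, paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")))
    stop(sprintf("%s must list regions in the same order", what))
  }
  invisible(TRUE)
}
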