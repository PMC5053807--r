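# Internal helpers shared across modules.

#' Canonical pair index table
#'
#' Unique unordered object pairs in row-major upper-triangle order:
#' (1,2), (1,3), ..., (1,n), (2,3), ... This is the fixed order used for
#' every 120-entry pair vector in the package.
#'
#' @param n Number of objects.
#' @return Integer matrix with `n*(n-1)/2` rows and columns `i`, `j` (i < j).
#' @export
pair_indices <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  idx <- t(utils::combn(as.integer(n), 2L))
  colnames(idx) <- c("i", "j")
  idx
}

#' Extract the canonical pair vector from a symmetric matrix
#' @param m Square symmetric matrix.
#' @return Numeric vector of the n*(n-1)/2 upper-triangle entries in
#'   canonical order.
#' @export
mat_to_pairvec <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[pair_indices(nrow(m))]
}

#' Rebuild a symmetric matrix from a canonical pair vector
#' @param v Pair vector of length n*(n-1)/2.
#' @param diag Value placed on the diagonal (default `NA`).
#' @return Symmetric matrix.
#' @export
pairvec_to_mat <- function(v, diag = NA_real_) {
  npair <- length(v)
  n <- (1 + sqrt(1 + 8 * npair)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("length of 'v' is not a valid number of unordered pairs")
  }
  n <- as.integer(round(n))
  m <- matrix(diag, n, n)
  idx <- pair_indices(n)
  m[idx] <- v
  m[idx[, 2:1]] <- v
  m
}

# z-score that tolerates a constant vector (returns zeros, flags via attr)
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    out <- rep(0, length(x))
    attr(out, "constant") <- TRUE
    return(out)
  }
  (x - mean(x)) / s
}

is_constant <- function(x, tol = 1e-12) {
  x <- x[is.finite(x)]
  length(x) < 2L || stats::sd(x) < tol
}

#' Derive a stage seed from a master seed
#'
#' Deterministic mixing of a master seed and a stage index, kept within the
#' 32-bit integer range; used so that every stochastic stage of a run has
#' an explicit, reproducible seed.
#'
#' @param seed Master seed.
#' @param k Stage index.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), is.numeric(k))
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483646 + 1)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# A NULL seed means "use the current stream".
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# All permutations of 1..n as an n! x n matrix (exhaustive null modes).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8) # 8! = 40320 rows is the intended ceiling
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# n x m matrix of random permutations of 1..n (one per column), drawn from
# the current RNG stream by ranking iid uniforms.
random_permutations <- function(n, m) {
  keys <- stats::runif(n * m)
  ord <- order(rep(seq_len(m), each = n), keys)
  matrix(ord - rep((seq_len(m) - 1L) * n, each = n), n, m)
}

cap_fisher_z <- function(r, cap = 0.9999) {
  flagged <- abs(r) > cap
  r <- pmin(pmax(r, -cap), cap)
  z <- atanh(r)
  attr(z, "capped") <- flagged
  z
}
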