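#' Cross-correlation matrix with block exclusion
#'
#' Correlates the voxel pattern of every trial with every other trial,
#' excluding combinations of trials from the same block (which share slow
#' noise), and averages the admissible Pearson correlations per object
#' pair. Same-object pairs across blocks populate the diagonal. With B
#' blocks, every cross-object cell averages `B^2 - B` ordered combinations
#' and every diagonal cell `B(B-1)/2` unordered ones.
#'
#' @param patterns A [trial_patterns()] object.
#' @param session Optional label (`"pre"` / `"post"`).
#' @param average `"raw"` to average correlation coefficients directly (the
#'   default), `"fisher"` to average Fisher-z values and transform back.
#' @return Object of class `crosscorr_matrix`: `values` (object x object),
#'   `session`, `n_included` (per-cell count of averaged correlations;
#'   unordered for diagonal cells) and `n_excluded` (correlations dropped
#'   because a trial pattern had zero variance).
#' @export
crosscorr_matrix <- function(patterns, session = NULL,
                             average = c("raw", "fisher")) {
  average <- match.arg(average)
  stopifnot(inherits(patterns, "trial_patterns"))
  d <- dim(patterns$values)
  n_obj <- d[1]; n_rep <- d[2]; n_vox <- d[3]
  if (n_vox < 2) stop("need at least 2 voxels")
  if (n_rep < 2) stop("need at least 2 blocks")
  # trials stacked object-major: rows (o-1)*n_rep + r
  X <- matrix(aperm(patterns$values, c(3, 2, 1)), n_vox, n_obj * n_rep)
  obj_of <- rep(seq_len(n_obj), each = n_rep)
  blk_of <- as.vector(t(patterns$blocks))
  degenerate <- apply(X, 2, function(v) stats::sd(v) == 0)
  C <- suppressWarnings(stats::cor(X))
  if (average == "fisher") C <- cap_fisher_z(C)
  A <- outer(blk_of, blk_of, "!=")
  valid <- A & is.finite(C) & !outer(degenerate, degenerate, "|")
  Cz <- C
  Cz[!valid] <- 0
  G <- matrix(0, n_obj * n_rep, n_obj)
  G[cbind(seq_along(obj_of), obj_of)] <- 1
  num <- crossprod(G, Cz %*% G)
  den <- crossprod(G, (valid * 1) %*% G)
  vals <- num / den
  if (average == "fisher") vals <- tanh(vals)
  n_inc <- crossprod(G, (valid * 1) %*% G)
  n_exc <- crossprod(G, ((A & !valid) * 1) %*% G)
  diag(n_inc) <- diag(n_inc) / 2 # unordered count for same-object cells
  diag(n_exc) <- diag(n_exc) / 2
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance trial pattern(s) excluded")
  }
  structure(
    list(values = vals, session = session,
         n_included = n_inc, n_excluded = n_exc,
         object_ids = patterns$object_ids),
    class = "crosscorr_matrix"
  )
}

#' @export
print.crosscorr_matrix <- function(x, ...) {
  cat(sprintf("<crosscorr_matrix: %dx%d%s>\n", nrow(x$values),
              ncol(x$values),
              if (!is.null(x$session)) paste0(", session ", x$session) else ""))
  invisible(x)
}

#' Pattern-similarity change (PS')
#'
#' Cell-wise difference of the post- and pre-learning cross-correlation
#' matrices: the change in pattern similarity attributable to learning the
#' spatio-temporal structure.
#'
#' @param pre,post `crosscorr_matrix` objects for the same object set.
#' @return Object of class `ps_change_matrix` with `values` and the
#'   canonical `pair_vector` (self-similarity cells excluded).
#' @export
ps_change <- function(pre, post) {
  stopifnot(inherits(pre, "crosscorr_matrix"),
            inherits(post, "crosscorr_matrix"))
  if (!identical(pre$object_ids, post$object_ids)) {
    stop("pre and post matrices cover different object sets")
  }
  vals <- post$values - pre$values
  structure(
    list(values = vals, pair_vector = mat_to_pairvec(vals),
         object_ids = pre$object_ids),
    class = "ps_change_matrix"
  )
}

#' Combined space-x-time distance model
#'
#' Cell-wise product of the spatial and temporal distance ratings, both on
#' the `[0, 1]` rating scale (min-max normalized first if not): the lowest
#' values mark pairs close in both dimensions, the highest pairs distant in
#' both.
#'
#' @param spatial,temporal [distance_model()]s (or symmetric matrices) with
#'   non-negative entries.
#' @return A `distance_model` with domain `"combined"`.
#' @export
combined_model <- function(spatial, temporal) {
  vs <- if (inherits(spatial, "distance_model")) spatial$values else spatial
  vt <- if (inherits(temporal, "distance_model")) temporal$values else temporal
  stopifnot(all(dim(vs) == dim(vt)))
  norm01 <- function(m) {
    v <- m[is.finite(m)]
    if (any(v < 0)) stop("combined model requires non-negative entries")
    if (max(v) > 1) {
      rng <- range(v)
      if (diff(rng) == 0) stop("cannot min-max normalize a constant matrix")
      m <- (m - rng[1]) / diff(rng)
    }
    m
  }
  distance_model(norm01(vs) * norm01(vt), "combined")
}

#' Spearman fit between PS' and a distance model
#'
#' Spearman rank correlation (average ranks for ties) between the 120
#' off-diagonal pair entries of a pattern-similarity change matrix and a
#' distance model. Negative values mean pairs remembered as closer gained
#' more similarity.
#'
#' @param ps A `ps_change_matrix` (or pair vector).
#' @param model A `distance_model` (or pair vector).
#' @param method Correlation type (default Spearman).
#' @return Numeric rho; `NA` with a warning if either vector is constant.
#' @export
model_correlation <- function(ps, model, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as_pair_vector(ps)
  y <- as_pair_vector(model)
  stopifnot(length(x) == length(y))
  if (is_constant(x) || is_constant(y)) {
    warning("constant pair vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = method)
}

#' First-level shuffle-null z statistic
#'
#' Compares the observed PS'-model Spearman correlation against a surrogate
#' distribution obtained by shuffling the model pair vector against the
#' fixed PS' pair vector. The z statistic is the observed rho standardized
#' by the surrogate mean and sd; an empirical lower-tail p (fraction of
#' surrogates at or below the observed rho) is reported alongside.
#'
#' @param ps A `ps_change_matrix` or pair vector.
#' @param model A `distance_model` or pair vector.
#' @param n_shuffles Number of random shuffles (default 10000).
#' @param seed Integer seed.
#' @param exact If `TRUE`, enumerate all permutations instead of sampling
#'   (only for vectors of length <= 8).
#' @return Object of class `subject_z`: `rho`, `surrogate_mean`,
#'   `surrogate_sd`, `z`, `p_lower`, `n_shuffles`, `exact`, `seed`.
#' @export
subject_shuffle_z <- function(ps, model, n_shuffles = 10000L, seed = NULL,
                              exact = FALSE) {
  x <- as_pair_vector(ps)
  y <- as_pair_vector(model)
  stopifnot(length(x) == length(y))
  if (!exact && n_shuffles < 100) stop("n_shuffles must be at least 100")
  if (is_constant(x) || is_constant(y)) {
    stop("constant pair vector: shuffle null is degenerate")
  }
  n <- length(x)
  s1 <- zscore(rank(x))
  s2 <- zscore(rank(y))
  rho <- sum(s1 * s2) / (n - 1)
  surr <- if (exact) {
    P <- all_permutations(n)
    as.vector((matrix(s2[P], nrow(P)) %*% s1) / (n - 1))
  } else {
    P <- with_seed_or_current(seed, random_permutations(n, n_shuffles))
    as.vector(crossprod(matrix(s2[P], n), s1)) / (n - 1)
  }
  sd_s <- stats::sd(surr)
  if (!is.finite(sd_s) || sd_s == 0) {
    stop("surrogate distribution is degenerate (sd = 0)")
  }
  structure(
    list(rho = rho, surrogate_mean = mean(surr), surrogate_sd = sd_s,
         z = (rho - mean(surr)) / sd_s,
         p_lower = mean(surr <= rho + 1e-10 * max(1, abs(rho))),
         n_shuffles = if (exact) length(surr) else as.integer(n_shuffles),
         exact = exact, seed = seed),
    class = "subject_z"
  )
}

#' @export
print.subject_z <- function(x, ...) {
  cat(sprintf("<subject_z: rho=%.4f z=%.3f (%s, %d surrogates)>\n",
              x$rho, x$z, if (x$exact) "exhaustive" else "shuffled",
              x$n_shuffles))
  invisible(x)
}

#' Residualize PS' on a covariate distance model
#'
#' OLS of the PS' pair vector on an intercept plus the covariate's pair
#' vector; the residuals carry the pattern-similarity change with the
#' covariate's (e.g. the other domain's) linear influence removed and are
#' then correlated with the domain of interest.
#'
#' @param ps A `ps_change_matrix` or pair vector.
#' @param covariate A `distance_model` or pair vector.
#' @return Numeric residual vector in canonical pair order.
#' @export
residualize <- function(ps, covariate) {
  y <- as_pair_vector(ps)
  x <- as_pair_vector(covariate)
  stopifnot(length(x) == length(y))
  if (is_constant(x)) stop("constant covariate: residualization undefined")
  unname(stats::lm.fit(cbind(1, x), y)$residuals)
}
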