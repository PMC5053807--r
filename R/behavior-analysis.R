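#' Distance-judgment accuracy
#'
#' Goodness of fit between remembered and actual pair distances: the
#' correlation between z-scored ratings and z-scored true distances, per
#' domain, with a two-sided p value. Pearson on z-scored values is the
#' default; Spearman is available since ratings are monotone but possibly
#' nonlinear in true distance.
#'
#' @param behavior A [generate_behavior()] dataset (or a ratings data
#'   frame with columns `pair_i`, `pair_j`, `domain`, `rating`).
#' @param truth Named list with [distance_model()]s `spatial` and
#'   `temporal` (objective distances).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame with one row per domain: `domain`, `r`, `p`, `n`,
#'   `defined`. A constant input yields `defined = FALSE` and `NA`
#'   statistics rather than a silent `NaN`.
#' @export
rating_accuracy <- function(behavior, truth,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ratings <- if (inherits(behavior, "behavioral_dataset"))
    behavior$ratings else behavior
  truth_pv <- list(space = as_pair_vector(truth$spatial),
                   time = as_pair_vector(truth$temporal))
  out <- lapply(c("space", "time"), function(dom) {
    sub <- ratings[ratings$domain == dom, ]
    rated <- rating_pair_values(sub)
    actual <- truth_pv[[dom]]
    stopifnot(length(rated) == length(actual))
    if (length(rated) < 3 || is_constant(rated) || is_constant(actual)) {
      return(data.frame(domain = dom, r = NA_real_, p = NA_real_,
                        n = length(rated), defined = FALSE))
    }
    ct <- stats::cor.test(zscore(rated), zscore(actual), method = method,
                          exact = FALSE)
    data.frame(domain = dom, r = unname(ct$estimate), p = ct$p.value,
               n = length(rated), defined = TRUE)
  })
  do.call(rbind, out)
}

# Ratings of one domain in canonical pair order.
rating_pair_values <- function(sub) {
  sub <- sub[order(sub$pair_i, sub$pair_j), ]
  sub$rating
}

#' Two-predictor GLM of distance ratings
#'
#' OLS of one domain's (z-scored) ratings on an intercept plus the z-scored
#' actual spatial and temporal distances, returning standardized betas for
#' both predictors: how much each true domain drives the judgments.
#'
#' @param ratings Ratings of a single domain: a numeric vector in canonical
#'   pair order, or a ratings data frame already filtered to one domain.
#' @param actual_spatial,actual_temporal Objective [distance_model()]s.
#' @return Named numeric vector `c(space = ..., time = ...)`.
#' @export
rating_glm <- function(ratings, actual_spatial, actual_temporal) {
  y <- if (is.data.frame(ratings)) rating_pair_values(ratings) else ratings
  xs <- zscore(as_pair_vector(actual_spatial))
  xt <- zscore(as_pair_vector(actual_temporal))
  stopifnot(length(y) == length(xs), length(y) == length(xt))
  if (abs(stats::cor(xs, xt)) > 0.99) {
    stop("actual spatial and temporal distances are collinear (|r| > 0.99)")
  }
  fit <- stats::lm.fit(cbind(1, space = xs, time = xt), zscore(y))
  fit$coefficients[c("space", "time")]
}

#' Cross-domain error bias of distance judgments
#'
#' The judgment error of a pair is `z(actual) - z(remembered)` in the rated
#' domain. This error is correlated with the other domain's distance
#' (actual or remembered); the coefficient is Fisher z-transformed (capped
#' at |r| = 0.9999, with a flag) for group-level testing. Optionally the
#' pairs are split by which domain was tested first for that pair.
#'
#' @param behavior A `behavioral_dataset`.
#' @param domain Rated domain whose errors are analyzed (`"space"` or
#'   `"time"`).
#' @param truth Objective [distance_model()] of the rated domain.
#' @param other Pair vector (or `distance_model`) of the other domain's
#'   distance, actual or remembered.
#' @param split_by_order If `TRUE`, compute separately for pairs where
#'   space vs time was tested first.
#' @return Data frame with columns `subset`, `r`, `fisher_z`, `n`,
#'   `defined`, `capped`. Subsets with fewer than 3 pairs or a constant
#'   error vector are flagged `defined = FALSE`.
#' @export
error_bias <- function(behavior, domain = c("space", "time"), truth, other,
                       split_by_order = FALSE) {
  domain <- match.arg(domain)
  sub <- behavior$ratings[behavior$ratings$domain == domain, ]
  sub <- sub[order(sub$pair_i, sub$pair_j), ]
  err <- zscore(as_pair_vector(truth)) - zscore(sub$rating)
  other_pv <- as_pair_vector(other)
  stopifnot(length(err) == length(other_pv))
  subsets <- if (split_by_order) {
    split(seq_along(err), paste0(sub$tested_first, "_first"))
  } else {
    list(all = seq_along(err))
  }
  out <- lapply(names(subsets), function(nm) {
    ii <- subsets[[nm]]
    if (length(ii) < 3 || is_constant(err[ii]) || is_constant(other_pv[ii])) {
      return(data.frame(subset = nm, r = NA_real_, fisher_z = NA_real_,
                        n = length(ii), defined = FALSE, capped = FALSE))
    }
    r <- stats::cor(err[ii], other_pv[ii])
    fz <- cap_fisher_z(r)
    data.frame(subset = nm, r = r, fisher_z = as.numeric(fz),
               n = length(ii), defined = TRUE,
               capped = attr(fz, "capped"))
  })
  do.call(rbind, out)
}

#' Group t-test of Fisher-z coefficients against zero
#' @param z Numeric vector of per-subject Fisher-z values (NAs dropped).
#' @param mu Null value (default 0).
#' @return Data frame with `t`, `df`, `p`, `mean_z`, `n`.
#' @export
fisher_z_ttest <- function(z, mu = 0) {
  z <- z[is.finite(z)]
  stopifnot(length(z) >= 2)
  tt <- stats::t.test(z, mu = mu)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, mean_z = mean(z), n = length(z))
}

#' Free-recall order analysis
#'
#' Correlates the recall-order distance of recalled item pairs (absolute
#' difference of their ranks in the recall sequence) with the spatial and
#' temporal task distances: did the spatial layout or the temporal route
#' order organize recall? Only recalled pairs enter.
#'
#' @param recall_sequence Integer vector of recalled object indices.
#' @param spatial,temporal Objective [distance_model()]s.
#' @param method Correlation type (default Pearson).
#' @return One-row data frame: `r_space`, `r_time`, `n_recalled`,
#'   `n_pairs`, `defined`.
#' @export
recall_order_analysis <- function(recall_sequence, spatial, temporal,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  recall_sequence <- as.integer(recall_sequence)
  stopifnot(!anyDuplicated(recall_sequence))
  n_rec <- length(recall_sequence)
  if (n_rec < 3) {
    return(data.frame(r_space = NA_real_, r_time = NA_real_,
                      n_recalled = n_rec, n_pairs = 0L, defined = FALSE))
  }
  pairs <- pair_indices(n_rec)
  a <- recall_sequence[pairs[, 1]]
  b <- recall_sequence[pairs[, 2]]
  order_dist <- abs(pairs[, 1] - pairs[, 2])
  sp <- if (inherits(spatial, "distance_model")) spatial$values else spatial
  tm <- if (inherits(temporal, "distance_model")) temporal$values else temporal
  data.frame(
    r_space = stats::cor(order_dist, sp[cbind(a, b)], method = method),
    r_time = stats::cor(order_dist, tm[cbind(a, b)], method = method),
    n_recalled = n_rec, n_pairs = nrow(pairs), defined = TRUE
  )
}

#' Map-test displacement error
#'
#' Mean over objects of the Euclidean distance between the response and the
#' true location, expressed as a fraction of the map side length.
#'
#' @param map_responses Data frame with columns `object`, `x`, `y` (as in
#'   [generate_behavior()]).
#' @param coords True object coordinates, `n x 2`.
#' @param map_side Map side length.
#' @return Scalar mean displacement ratio.
#' @export
map_error <- function(map_responses, coords, map_side) {
  stopifnot(map_side > 0)
  resp <- as.matrix(map_responses[order(map_responses$object), c("x", "y")])
  coords <- as.matrix(coords)
  stopifnot(nrow(resp) == nrow(coords))
  if (any(resp < 0) || any(resp > map_side)) {
    warning("some responses lie outside the map; scored anyway")
  }
  mean(sqrt(rowSums((resp - coords)^2))) / map_side
}
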