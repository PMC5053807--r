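#' Default behavioral-generation parameters
#'
#' Own- and cross-domain weights emulate the group-mean standardized betas
#' of the distance-judgment GLMs (spatial ratings: 0.50 own / 0.17 cross;
#' temporal ratings: 0.65 own / 0.16 cross). The per-domain noise sd brings
#' the latent rating variance to ~1 so that the rating-accuracy correlation
#' matches the own-domain weight. Recall length (13.08 +- 3.06 of 16 items)
#' and the map-test jitter (expected displacement ratio 0.193) follow the
#' same observed group statistics.
#'
#' @return Named list of parameters accepted by [generate_behavior()].
#' @export
behavior_config <- function() {
  list(
    own_weight = c(space = 0.50, time = 0.65),
    cross_weight = c(space = 0.17, time = 0.16),
    noise_sd = c(space = 0.85, time = 0.74),
    recall_mean = 13.08,
    recall_sd = 3.06,
    recall_adjacency = 0.8,   # exp(-adjacency * route-position gap) bias
    map_jitter = 0.17,        # sd of response jitter, fraction of map_side
    first_domain = c("space", "time"),
    n_rating_blocks = 8L      # alternating 30-trial blocks, 4 per domain
  )
}

# Logistic squashing of the latent rating onto the (0, 1) slider range.
squash_rating <- function(x) stats::plogis(x)

#' Generate a behavioral dataset for one subject
#'
#' Distance ratings are noisy monotone functions of the true distances with
#' cross-domain leakage: the latent rating for a pair in the rated domain is
#' `own_weight * z(own distance) + cross_weight * z(other distance) + noise`,
#' squashed onto `[0, 1]` by the logistic CDF. Trials are arranged in
#' alternating domain blocks (as in the judgment task), which determines for
#' every pair which domain was tested first. The free-recall sequence is a
#' biased walk over route positions; map responses are the true coordinates
#' plus isotropic Gaussian jitter.
#'
#' @param route A [route_design()].
#' @param params Named list overriding [behavior_config()].
#' @param seed Integer seed.
#' @return Object of class `behavioral_dataset` with elements `ratings`
#'   (data frame: `pair_i`, `pair_j`, `domain`, `rating`, `tested_first`),
#'   `recall_sequence` (integer vector) and `map_responses` (data frame:
#'   `object`, `x`, `y`, `confidence`).
#' @export
generate_behavior <- function(route, params = list(), seed = NULL) {
  stopifnot(inherits(route, "route_design"))
  p <- utils::modifyList(behavior_config(), params)
  p$first_domain <- match.arg(p$first_domain, c("space", "time"))
  if (all(p$own_weight == 0) && all(p$cross_weight == 0)) {
    stop("own_weight and cross_weight of zero produce degenerate constant ratings")
  }
  n <- route$n_objects
  idx <- pair_indices(n)
  zs <- zscore(route_distances(route, "spatial")$pair_vector)
  zt <- zscore(route_distances(route, "temporal")$pair_vector)
  own <- list(space = zs, time = zt)
  oth <- list(space = zt, time = zs)

  with_seed_or_current(seed, {
    rate <- function(domain) {
      latent <- p$own_weight[[domain]] * own[[domain]] +
        p$cross_weight[[domain]] * oth[[domain]] +
        stats::rnorm(nrow(idx), 0, p$noise_sd[[domain]])
      squash_rating(latent)
    }
    ratings <- rbind(
      data.frame(pair_i = idx[, 1], pair_j = idx[, 2], domain = "space",
                 rating = rate("space")),
      data.frame(pair_i = idx[, 1], pair_j = idx[, 2], domain = "time",
                 rating = rate("time"))
    )
    if (is_constant(ratings$rating)) {
      stop("generated ratings are degenerate (constant); check weights/noise")
    }
    ratings$tested_first <- rep(pair_test_order(nrow(idx), p), 2L)

    n_recall <- max(3L, min(n, round(stats::rnorm(1, p$recall_mean,
                                                  p$recall_sd))))
    pos <- match(seq_len(n), route$order)
    recall <- sample.int(n, 1L)
    while (length(recall) < n_recall) {
      rem <- setdiff(seq_len(n), recall)
      w <- exp(-p$recall_adjacency * abs(pos[rem] - pos[recall[length(recall)]]))
      recall <- c(recall,
                  if (length(rem) == 1L) rem else sample(rem, 1L, prob = w))
    }

    mapresp <- route$coords +
      matrix(stats::rnorm(2 * n, 0, p$map_jitter * route$map_side), n)
    mapresp <- pmin(pmax(mapresp, 0), route$map_side) # clicks stay on the map
    map_responses <- data.frame(object = seq_len(n),
                                x = mapresp[, 1], y = mapresp[, 2],
                                confidence = stats::runif(n))

    structure(
      list(ratings = ratings, recall_sequence = recall,
           map_responses = map_responses, params = p),
      class = "behavioral_dataset"
    )
  })
}

# Assign each pair to a trial slot in each domain's alternating blocks and
# report which domain was probed first for that pair.
pair_test_order <- function(npair, p) {
  slots <- function() sample.int(npair) # trial position of each pair, 1..120
  pos_space <- slots()
  pos_time <- slots()
  # blocks alternate domains; block length = npair / (n_rating_blocks / 2)
  per_block <- ceiling(npair / (p$n_rating_blocks / 2))
  blk_space <- (pos_space - 1) %/% per_block  # 0-based within-domain block
  blk_time <- (pos_time - 1) %/% per_block
  # global block index: first domain occupies even slots 0,2,4,..
  g_space <- 2 * blk_space + (p$first_domain != "space")
  g_time <- 2 * blk_time + (p$first_domain != "time")
  first <- ifelse(g_space < g_time, "space",
                  ifelse(g_time < g_space, "time",
                         ifelse(pos_space <= pos_time, "space", "time")))
  first
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  cat(sprintf("<behavioral_dataset: %d rating trials, %d recalled items>\n",
              nrow(x$ratings), length(x$recall_sequence)))
  invisible(x)
}

#' Remembered distance models from a behavioral dataset
#'
#' Turns the `[0, 1]` distance ratings into per-subject remembered distance
#' models, including the combined space-x-time model (the cell-wise product
#' of the two ratings, low values meaning proximity in both dimensions; see
#' [combined_model()]).
#'
#' @param behavior A `behavioral_dataset`.
#' @param n_objects Number of objects (inferred from the ratings by default).
#' @return Named list of [distance_model()]s: `spatial`, `temporal`,
#'   `combined`.
#' @export
remembered_models <- function(behavior, n_objects = NULL) {
  r <- behavior$ratings
  if (is.null(n_objects)) n_objects <- max(r$pair_j)
  build <- function(domain, label) {
    sub <- r[r$domain == domain, ]
    m <- matrix(NA_real_, n_objects, n_objects)
    m[cbind(sub$pair_i, sub$pair_j)] <- sub$rating
    m[cbind(sub$pair_j, sub$pair_i)] <- sub$rating
    distance_model(m, label)
  }
  sp <- build("space", "spatial")
  tm <- build("time", "temporal")
  list(spatial = sp, temporal = tm, combined = combined_model(sp, tm))
}
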