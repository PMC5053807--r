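#' Construct a route design
#'
#' A route design places objects at 2D positions on a square map and orders
#' them along a one-way route. Consecutive objects are connected either by a
#' walked segment (traversal time = length / walking speed) or by a
#' teleporter: an instantaneous jump that covers a large spatial span in a
#' tiny, fixed traversal time. Teleporters are the device that decorrelates
#' spatial (Euclidean) from temporal (along-route time) pair distances.
#'
#' @param coords Numeric matrix `n x 2` of object positions (map units).
#' @param order Route sequence: a permutation of `1:n`. Defaults to `1:n`.
#' @param segment_duration Numeric vector of length `n - 1`; traversal time
#'   in seconds of each route segment.
#' @param teleporter_after Integer set of route positions (segment indices)
#'   followed by a teleporter.
#' @param map_side Side length of the square map, map units.
#' @param teleporter_eps Maximum traversal time (s) of a teleporter segment.
#' @param min_teleport_span Minimum spatial span (fraction of `map_side`)
#'   that a teleporter segment must cover.
#' @return Object of class `route_design`.
#' @export
route_design <- function(coords, order = seq_len(nrow(coords)),
                         segment_duration, teleporter_after = integer(),
                         map_side, teleporter_eps = 2,
                         min_teleport_span = 0.4) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= 2, ncol(coords) == 2,
            length(segment_duration) == n - 1,
            all(segment_duration >= 0),
            map_side > 0)
  if (!setequal(order, seq_len(n)) || length(order) != n) {
    stop("'order' must be a permutation of the object indices")
  }
  if (any(coords < 0) || any(coords > map_side)) {
    stop("all coordinates must lie within [0, map_side]^2")
  }
  teleporter_after <- as.integer(teleporter_after)
  if (length(teleporter_after)) {
    stopifnot(all(teleporter_after >= 1), all(teleporter_after <= n - 1))
    span <- sqrt(rowSums((coords[order[teleporter_after + 1L], , drop = FALSE] -
                          coords[order[teleporter_after], , drop = FALSE])^2))
    if (any(segment_duration[teleporter_after] > teleporter_eps)) {
      stop("teleporter segments must have duration <= teleporter_eps")
    }
    if (any(span < min_teleport_span * map_side)) {
      stop("teleporter segments must span at least min_teleport_span * map_side")
    }
  }
  structure(
    list(n_objects = n, coords = coords, order = as.integer(order),
         segment_duration = as.numeric(segment_duration),
         teleporter_after = teleporter_after, map_side = map_side),
    class = "route_design"
  )
}

#' @export
print.route_design <- function(x, ...) {
  cat(sprintf("<route_design: %d objects, %d teleporters, map side %g>\n",
              x$n_objects, length(x$teleporter_after), x$map_side))
  invisible(x)
}

#' Objective distance models of a route design
#'
#' Spatial distance is the Euclidean distance between object positions.
#' Temporal distance between two objects is the sum of segment traversal
#' times between their route positions (the one-way route makes this the
#' travel time from the earlier to the later object; with per-repetition
#' duration jitter it is the median over repetitions, see
#' [generate_route()]).
#'
#' @param design A `route_design`.
#' @param domain `"spatial"` or `"temporal"`.
#' @return A [distance_model()] with domain `objective_spatial` or
#'   `objective_temporal`.
#' @export
route_distances <- function(design, domain = c("spatial", "temporal")) {
  domain <- match.arg(domain)
  stopifnot(inherits(design, "route_design"))
  if (domain == "spatial") {
    d <- as.matrix(stats::dist(design$coords))
    return(distance_model(d, "objective_spatial"))
  }
  pos <- match(seq_len(design$n_objects), design$order)
  cum <- c(0, cumsum(design$segment_duration))
  d <- abs(outer(cum[pos], cum[pos], "-"))
  distance_model(d, "objective_temporal")
}

#' High/low factorial cell of every object pair
#'
#' Pairs are median-split into high/low per domain, yielding the 2 x 2
#' factorial (space high/low x time high/low) used by the objective-distance
#' repeated-measures analysis.
#'
#' @param design A `route_design`.
#' @return Factor of length `n*(n-1)/2` (canonical pair order) with levels
#'   `"space_high.time_high"`, `"space_high.time_low"`,
#'   `"space_low.time_high"`, `"space_low.time_low"`.
#' @export
route_pair_cells <- function(design) {
  sp <- route_distances(design, "spatial")$pair_vector
  tm <- route_distances(design, "temporal")$pair_vector
  s <- ifelse(sp > stats::median(sp), "space_high", "space_low")
  t <- ifelse(tm > stats::median(tm), "time_high", "time_low")
  factor(paste(s, t, sep = "."),
         levels = c("space_high.time_high", "space_high.time_low",
                    "space_low.time_high", "space_low.time_low"))
}

# Pearson correlation between z-scored spatial and temporal pair distances.
route_domain_correlation <- function(design) {
  sp <- route_distances(design, "spatial")$pair_vector
  tm <- route_distances(design, "temporal")$pair_vector
  stats::cor(zscore(sp), zscore(tm))
}

# One candidate layout: a random walk in the map with bounded walked-segment
# lengths; teleporter segments jump at least `teleport_jump * map_side`.
sample_layout <- function(cfg) {
  n <- cfg$n_objects
  coords <- matrix(NA_real_, n, 2)
  coords[1, ] <- stats::runif(2, 0.05 * cfg$map_side, 0.95 * cfg$map_side)
  tel <- if (cfg$n_teleporters > 0) {
    sort(sample(seq_len(n - 1L), cfg$n_teleporters))
  } else integer()
  dur <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    accepted <- FALSE
    for (draw in seq_len(10000L)) {
      cand <- stats::runif(2, 0, cfg$map_side)
      d <- sqrt(sum((cand - coords[k, ])^2))
      ok <- if (k %in% tel) d >= cfg$teleport_jump * cfg$map_side else
        d >= cfg$walk_min * cfg$map_side && d <= cfg$walk_max * cfg$map_side
      if (ok) { accepted <- TRUE; break }
    }
    if (!accepted) {
      stop("could not place an object satisfying the segment-length bounds; ",
           "check walk_min/walk_max/teleport_jump against map_side")
    }
    coords[k + 1, ] <- cand
    d <- sqrt(sum((coords[k + 1, ] - coords[k, ])^2))
    dur[k] <- if (k %in% tel) cfg$teleporter_eps else d / cfg$speed
  }
  if (cfg$n_repetitions > 1 && cfg$rep_jitter_sd > 0) {
    # median traversal time across repeated route traversals
    reps <- matrix(stats::rnorm(length(dur) * cfg$n_repetitions, 0,
                                cfg$rep_jitter_sd),
                   length(dur))
    dur <- apply(pmax(dur + reps, 0.1), 1, stats::median)
    dur[tel] <- cfg$teleporter_eps
  }
  route_design(coords, seq_len(n), dur, tel, cfg$map_side,
               teleporter_eps = cfg$teleporter_eps,
               min_teleport_span = cfg$teleport_jump)
}

#' Default route-generation parameters
#' @return Named list of parameters accepted by [generate_route()].
#' @export
route_config <- function() {
  list(
    n_objects = 16L,
    n_teleporters = 3L,
    map_side = 100,
    speed = 1.4,            # walking speed, map units / s
    walk_min = 0.10,        # walked segment length, fraction of map_side
    walk_max = 0.30,
    teleport_jump = 0.55,   # minimum teleporter span, fraction of map_side
    teleporter_eps = 2,     # teleporter traversal time, s
    theta = 0.1,            # max |r| between z-scored domain distances
    n_repetitions = 1L,     # route traversals; >1 enables duration jitter
    rep_jitter_sd = 0,      # per-repetition duration jitter, s
    max_retries = 1000L
  )
}

#' Generate a decorrelated route design
#'
#' Samples random layouts until the pair-level Pearson correlation between
#' z-scored spatial and temporal distances is below `theta` in magnitude and
#' all four high/low factorial cells are non-empty, or fails after
#' `max_retries` attempts (a signal that the configuration is infeasible,
#' e.g. no teleporters on a line).
#'
#' @param config Named list overriding entries of [route_config()].
#' @param seed Integer seed; the accepted design is a pure function of
#'   `(config, seed)`.
#' @return A `route_design` with attributes `domain_correlation` (the
#'   achieved r) and `n_retries`.
#' @export
generate_route <- function(config = list(), seed = NULL) {
  cfg <- utils::modifyList(route_config(), config)
  stopifnot(cfg$n_objects >= 4, cfg$n_teleporters >= 0,
            cfg$theta > 0, cfg$theta <= 1)
  with_seed_or_current(seed, {
    for (attempt in seq_len(cfg$max_retries)) {
      design <- sample_layout(cfg)
      r <- route_domain_correlation(design)
      cells <- route_pair_cells(design)
      if (abs(r) < cfg$theta && all(table(cells) > 0)) {
        attr(design, "domain_correlation") <- r
        attr(design, "n_retries") <- attempt
        return(design)
      }
    }
    stop(sprintf(paste("no route satisfying |r| < %g between spatial and",
                       "temporal distances found in %d retries;",
                       "the configuration appears infeasible"),
                 cfg$theta, cfg$max_retries))
  })
}
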