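#' Searchlight specification
#'
#' @param radius Sphere radius in mm (default 9, i.e. 6 voxels at 1.5 mm).
#' @param min_voxels Minimum grey-matter voxels for a sphere to be analysed
#'   (default 30).
#' @param voxel_size Voxel edge lengths in mm.
#' @return Object of class `searchlight_spec`.
#' @export
searchlight_spec <- function(radius = 9, min_voxels = 30L,
                             voxel_size = c(1.5, 1.5, 1.5)) {
  stopifnot(radius > 0, min_voxels >= 2, all(voxel_size > 0))
  structure(list(radius = radius, min_voxels = as.integer(min_voxels),
                 voxel_size = as.numeric(voxel_size)),
            class = "searchlight_spec")
}

# Integer voxel offsets whose center distance is within the radius,
# honoring anisotropic voxel sizes.
sphere_offsets <- function(radius, voxel_size) {
  lim <- floor(radius / voxel_size)
  g <- as.matrix(expand.grid(x = -lim[1]:lim[1], y = -lim[2]:lim[2],
                             z = -lim[3]:lim[3]))
  d2 <- (g[, 1] * voxel_size[1])^2 + (g[, 2] * voxel_size[2])^2 +
    (g[, 3] * voxel_size[3])^2
  g[d2 <= radius^2 + 1e-9, , drop = FALSE]
}

#' Build searchlight spheres over a mask
#'
#' Around every voxel of `mask` a sphere of the configured radius is formed
#' (distances between voxel centers, in mm); member voxels are restricted
#' to `grey` (if given) and to the volume bounds. Centers whose sphere
#' retains fewer than `min_voxels` members are dropped.
#'
#' @param mask 3D logical array of candidate centers.
#' @param spec A [searchlight_spec()].
#' @param grey Optional 3D logical grey-matter mask restricting members.
#' @return Object of class `searchlight_set`: `centers` (linear indices),
#'   `members` (list of linear index vectors), `dim`, `spec`.
#' @export
build_spheres <- function(mask, spec = searchlight_spec(), grey = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3,
            inherits(spec, "searchlight_spec"))
  dm <- dim(mask)
  if (is.null(grey)) grey <- mask
  stopifnot(all(dim(grey) == dm))
  off <- sphere_offsets(spec$radius, spec$voxel_size)
  centers <- which(mask)
  cxyz <- arrayInd(centers, dm)
  members <- vector("list", length(centers))
  keep <- logical(length(centers))
  for (k in seq_along(centers)) {
    pts <- cbind(off[, 1] + cxyz[k, 1], off[, 2] + cxyz[k, 2],
                 off[, 3] + cxyz[k, 3])
    inb <- pts[, 1] >= 1 & pts[, 1] <= dm[1] &
      pts[, 2] >= 1 & pts[, 2] <= dm[2] &
      pts[, 3] >= 1 & pts[, 3] <= dm[3]
    lin <- pts[inb, 1] + (pts[inb, 2] - 1) * dm[1] +
      (pts[inb, 3] - 1) * dm[1] * dm[2]
    lin <- lin[grey[lin]]
    if (length(lin) >= spec$min_voxels) {
      members[[k]] <- sort(lin)
      keep[k] <- TRUE
    }
  }
  if (!any(keep)) {
    stop("no searchlight retains at least ", spec$min_voxels,
         " voxels; radius/mask too small")
  }
  structure(list(centers = centers[keep], members = members[keep],
                 dim = dm, spec = spec),
            class = "searchlight_set")
}

#' @export
print.searchlight_set <- function(x, ...) {
  cat(sprintf("<searchlight_set: %d centers, radius %g mm, >=%d voxels>\n",
              length(x$centers), x$spec$radius, x$spec$min_voxels))
  invisible(x)
}

# Restrict trial patterns to a voxel subset given by linear grid indices.
subset_patterns <- function(patterns, lin_idx) {
  pos <- match(lin_idx, patterns$voxel_index)
  if (any(is.na(pos))) stop("sphere voxels missing from extracted patterns")
  trial_patterns(patterns$values[, , pos, drop = FALSE],
                 patterns$object_ids, patterns$blocks,
                 patterns$voxel_index[pos], patterns$grid_dim,
                 patterns$voxel_size)
}

#' Per-subject searchlight map
#'
#' Moves a sphere over the volume; within each sphere the ROI computation
#' is replayed (cross-correlation with block exclusion, PS', optional
#' residualization, Spearman fit with the model) and the correlation
#' coefficient is written at the sphere's center voxel.
#'
#' @param patterns_pre,patterns_post Full-volume [trial_patterns()] from
#'   the two sessions (identical masks).
#' @param model A [distance_model()] (or pair vector).
#' @param spheres A [build_spheres()] set.
#' @param remove Optional covariate [distance_model()] residualized out of
#'   PS' before the fit.
#' @return Object of class `stat_map`: `values` (3D array, `NA` off
#'   centers), `valid` (3D logical of analysed centers), `dim`.
#' @export
searchlight_map <- function(patterns_pre, patterns_post, model, spheres,
                            remove = NULL) {
  stopifnot(inherits(spheres, "searchlight_set"),
            identical(patterns_pre$voxel_index, patterns_post$voxel_index))
  dm <- spheres$dim
  vals <- array(NA_real_, dm)
  valid <- array(FALSE, dm)
  model_pv <- as_pair_vector(model)
  remove_pv <- if (is.null(remove)) NULL else as_pair_vector(remove)
  for (k in seq_along(spheres$centers)) {
    psc <- ps_change(
      crosscorr_matrix(subset_patterns(patterns_pre, spheres$members[[k]]),
                       "pre"),
      crosscorr_matrix(subset_patterns(patterns_post, spheres$members[[k]]),
                       "post"))
    target <- if (is.null(remove_pv)) psc$pair_vector else
      residualize(psc, remove_pv)
    rho <- suppressWarnings(model_correlation(target, model_pv))
    if (is.finite(rho)) {
      vals[spheres$centers[k]] <- rho
      valid[spheres$centers[k]] <- TRUE
    }
  }
  structure(list(values = vals, valid = valid, dim = dm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map: %s grid, %d analysed voxels>\n",
              paste(x$dim, collapse = "x"), sum(x$valid)))
  invisible(x)
}

#' Group-level searchlight inference with max-statistic correction
#'
#' Computes a per-voxel one-sample T over the subject maps and controls the
#' family-wise error by the sign-flip max-statistic method: for every flip
#' the most extreme T over the correction mask is recorded, and a voxel's
#' corrected p is the fraction of flips whose extreme statistic is at least
#' as extreme as that voxel's observed T. With `svc_mask` the correction is
#' a small-volume correction restricted to an a-priori region.
#'
#' @param maps List of per-subject [searchlight_map()] `stat_map`s on one
#'   grid.
#' @param n_flips Number of sign-flips (default 5000).
#' @param seed Integer seed.
#' @param svc_mask Optional 3D logical small-volume-correction mask; default
#'   is every voxel analysed in all subjects.
#' @param tail `"negative"` (default) or `"positive"`.
#' @param exact If `TRUE`, enumerate all `2^n` sign patterns instead of
#'   sampling (only for small cohorts, `n <= 14`); the corrected p is then
#'   exact, with minimum `1 / 2^n`.
#' @return List with `t_map` (3D T values, `NA` where not analysed in all
#'   subjects), `p_corr_map` (corrected p over the correction mask),
#'   `valid` (3D logical), `n_excluded` (voxels dropped for incomplete
#'   subject coverage).
#' @export
group_searchlight <- function(maps, n_flips = 5000L, seed = NULL,
                              svc_mask = NULL,
                              tail = c("negative", "positive"),
                              exact = FALSE) {
  tail <- match.arg(tail)
  stopifnot(length(maps) >= 2)
  dm <- maps[[1]]$dim
  for (m in maps) stopifnot(identical(m$dim, dm))
  valid <- Reduce(`&`, lapply(maps, function(m) m$valid))
  n_excluded <- sum(Reduce(`|`, lapply(maps, function(m) m$valid)) & !valid)
  if (!is.null(svc_mask)) {
    stopifnot(all(dim(svc_mask) == dm))
    corr_mask <- valid & svc_mask
  } else {
    corr_mask <- valid
  }
  if (!any(corr_mask)) stop("empty correction mask")
  vox <- which(corr_mask)
  M <- matrix(vapply(maps, function(m) m$values[vox], numeric(length(vox))),
              nrow = length(vox))
  n <- ncol(M)
  tstat <- function(X) {
    mu <- rowMeans(X)
    ss <- rowSums(X^2)
    sd <- sqrt(pmax(ss - n * mu^2, 0) / (n - 1))
    # zero spread with a nonzero mean is infinitely extreme evidence
    ifelse(sd > 0, mu / (sd / sqrt(n)),
           ifelse(mu == 0, 0, sign(mu) * Inf))
  }
  t_obs <- tstat(M)
  flip_extreme <- function(s) {
    tf <- tstat(sweep(M, 2, s, `*`))
    if (tail == "negative") min(tf) else max(tf)
  }
  if (exact) {
    stopifnot(n <= 14)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    extreme <- apply(signs, 1, flip_extreme)
    n_flips <- nrow(signs)
    count0 <- 0L
  } else {
    extreme <- with_seed_or_current(seed, {
      vapply(seq_len(n_flips), function(f)
        flip_extreme(sample(c(-1, 1), n, replace = TRUE)), numeric(1))
    })
    count0 <- 1L # add-one Monte-Carlo correction
  }
  p_corr <- if (tail == "negative") {
    (count0 + vapply(t_obs, function(t0) sum(extreme <= t0), numeric(1))) /
      (count0 + n_flips)
  } else {
    (count0 + vapply(t_obs, function(t0) sum(extreme >= t0), numeric(1))) /
      (count0 + n_flips)
  }
  t_map <- array(NA_real_, dm)
  allvox <- which(valid)
  Mall <- matrix(vapply(maps, function(m) m$values[allvox],
                        numeric(length(allvox))), nrow = length(allvox))
  t_map[allvox] <- tstat(Mall)
  p_map <- array(NA_real_, dm)
  p_map[vox] <- p_corr
  list(t_map = t_map, p_corr_map = p_map, valid = valid,
       n_excluded = n_excluded, n_flips = as.integer(n_flips), tail = tail)
}
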