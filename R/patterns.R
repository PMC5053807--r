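#' Regress motion parameters out of a volume series
#'
#' Fits, for every voxel, an OLS model of the voxel time series on an
#' intercept plus the six motion regressors and returns the residual series.
#' Motion columns that are constant carry no information beyond the
#' intercept and are dropped, so an all-zero motion table simply demeans
#' every voxel. Remaining collinear regressors are an error.
#'
#' @param series A [volume_series()].
#' @return A `volume_series` holding the residuals (same mask; motion table
#'   replaced by zeros since its contribution has been removed).
#' @export
regress_motion <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  M <- as.matrix(series$motion)
  keep <- apply(M, 2, function(col) stats::sd(col) > 0)
  d <- dim(series$data)
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  if (!any(keep)) {
    # intercept-only design: residuals are the demeaned series
    res <- flat - rowMeans(flat)
  } else {
    X <- cbind(intercept = 1, M[, keep, drop = FALSE])
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1L, ncol(X))]]
      stop("motion design is rank deficient; offending regressors: ",
           paste(bad, collapse = ", "))
    }
    res <- t(qr.resid(qrx, t(flat)))
  }
  volume_series(array(res, d), series$voxel_size, series$mask, motion = NULL)
}

#' Trial pattern container
#'
#' Object x repetition x voxel activity values extracted from one session,
#' with the block of every repetition and the voxel coordinates of the
#' analysis mask.
#'
#' @param values 3D array `(object, repetition, voxel)`.
#' @param object_ids Integer ids of the rows.
#' @param blocks Integer matrix `(object, repetition)`: block of each
#'   repetition.
#' @param voxel_index Linear indices of the mask voxels in the source grid.
#' @param grid_dim Spatial dimensions of the source grid.
#' @param voxel_size Voxel size in mm.
#' @return Object of class `trial_patterns`.
#' @export
trial_patterns <- function(values, object_ids, blocks, voxel_index,
                           grid_dim, voxel_size = c(1.5, 1.5, 1.5)) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(object_ids),
            all(dim(blocks) == dim(values)[1:2]),
            dim(values)[3] == length(voxel_index))
  for (o in seq_len(nrow(blocks))) {
    if (anyDuplicated(blocks[o, ])) {
      stop("two repetitions of one object share a block")
    }
  }
  structure(
    list(values = values, object_ids = as.integer(object_ids),
         blocks = blocks, voxel_index = as.integer(voxel_index),
         grid_dim = as.integer(grid_dim),
         voxel_size = as.numeric(voxel_size)),
    class = "trial_patterns"
  )
}

#' @export
print.trial_patterns <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<trial_patterns: %d objects x %d repetitions x %d voxels>\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Extract trial patterns from a session
#'
#' Stimulus presentation is locked to the start of a volume, and the
#' analysis volume of a trial is the third volume after image onset
#' (0-based onset index + 2; with a 2.27 s TR this covers 4.54-6.81 s after
#' stimulus onset, the plateau of the hemodynamic response). Target-object
#' trials are discarded. The result is sorted by object id and block.
#'
#' @param series A [volume_series()] (typically motion-residualized).
#' @param recipe The session's [generate_pvt_recipe()] recipe.
#' @param mask 3D logical analysis mask (e.g. from [intersect_masks()]).
#' @return A [trial_patterns()] with `n_objects - 1` rows (target removed).
#' @export
select_trial_volumes <- function(series, recipe, mask = series$mask) {
  stopifnot(inherits(series, "volume_series"),
            inherits(recipe, "pvt_recipe"))
  d <- dim(series$data)
  stopifnot(all(dim(mask) == d[1:3]))
  trials <- recipe$trials[recipe$trials$object != recipe$target_object, ]
  vsel <- trials$onset_volume + 2L + 1L # 0-based onset -> 1-based R index
  if (any(vsel > d[4])) {
    stop("analysis volume beyond end of series for trials: ",
         paste(trials$trial[vsel > d[4]], collapse = ", "))
  }
  trials <- trials[order(trials$object, trials$block), ]
  vsel <- trials$onset_volume + 2L + 1L
  mask_idx <- which(mask)
  flat <- matrix(series$data, prod(d[1:3]), d[4])
  objs <- sort(unique(trials$object))
  n_rep <- nrow(trials) / length(objs)
  vals <- array(t(flat[mask_idx, vsel, drop = FALSE]),
                c(n_rep, length(objs), length(mask_idx)))
  vals <- aperm(vals, c(2, 1, 3))
  blocks <- matrix(trials$block, n_rep, length(objs))
  trial_patterns(vals, objs, t(blocks), mask_idx, d[1:3], series$voxel_size)
}

#' Intersect session and grey-matter masks
#'
#' Voxelwise AND of the pre-session, post-session and grey-matter masks:
#' only voxels covered in both sessions and classified as grey matter enter
#' the analysis.
#'
#' @param mask_pre,mask_post,grey 3D logical arrays on one grid.
#' @return 3D logical array.
#' @export
intersect_masks <- function(mask_pre, mask_post, grey = NULL) {
  stopifnot(all(dim(mask_pre) == dim(mask_post)))
  out <- mask_pre & mask_post
  if (!is.null(grey)) {
    stopifnot(all(dim(grey) == dim(mask_pre)))
    out <- out & grey
  }
  if (!any(out)) stop("mask intersection is empty")
  out
}
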