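#' Effect specification for synthetic volume generation
#'
#' Describes the ground truth implanted into a synthetic pre/post session
#' pair: inside `effect_roi`, the post-learning object patterns are drawn
#' with a target correlation structure whose pairwise increments follow a
#' mixture `-|effect_size| * z(rank(model)) + sqrt(1 - effect_size^2) * z_g`
#' (with `z_g` an orthogonal random profile), so the expected
#' pattern-similarity change has Spearman correlation ~ `effect_size`
#' (negative: closer pairs gain more similarity) with the model pair vector.
#' Outside the ROI the pre and post patterns share one base, so the expected
#' change is zero.
#'
#' @param effect_roi 3D logical array marking the effect region.
#' @param effect_size Target Spearman correlation in `[-1, 0]`.
#' @param noise_sd Voxelwise noise sd added to every volume.
#' @param seed Integer seed for the subject's volume generation.
#' @param baseline Baseline post-session inter-object correlation added
#'   inside the ROI (keeps increments inside a plausible range).
#' @param gain Scale of the pairwise correlation increments.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(effect_roi, effect_size = -0.6, noise_sd = 1,
                        seed = NULL, baseline = 0.25, gain = 0.12) {
  stopifnot(is.array(effect_roi), length(dim(effect_roi)) == 3,
            is.logical(effect_roi),
            effect_size >= -1, effect_size <= 0,
            noise_sd >= 0, gain >= 0)
  structure(
    list(effect_roi = effect_roi, effect_size = effect_size,
         noise_sd = noise_sd, seed = seed, baseline = baseline, gain = gain),
    class = "effect_spec"
  )
}

#' 4D volume series container
#'
#' @param data 4D numeric array `(x, y, z, volume)`.
#' @param voxel_size Voxel edge lengths in mm, length 3.
#' @param mask 3D logical array matching the spatial grid.
#' @param motion Data frame of 6 nuisance regressors, one row per volume.
#' @return Object of class `volume_series`.
#' @export
volume_series <- function(data, voxel_size = c(1.5, 1.5, 1.5), mask = NULL,
                          motion = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  spatial <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spatial)
  stopifnot(is.logical(mask), all(dim(mask) == spatial))
  n_vol <- dim(data)[4]
  if (is.null(motion)) {
    motion <- as.data.frame(matrix(0, n_vol, 6))
    names(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  }
  if (nrow(motion) != n_vol) {
    stop("motion table must have one row per volume")
  }
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size), mask = mask,
         motion = motion),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series: %dx%dx%d voxels x %d volumes, %d in mask>\n",
              d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

# Project a symmetric matrix to the nearest correlation-like PD matrix:
# eigenvalue clipping followed by rescaling to unit diagonal.
project_correlation <- function(C, min_eig = 1e-6) {
  e <- eigen(C, symmetric = TRUE)
  if (all(e$values > 0)) return(C)
  ev <- pmax(e$values, min_eig)
  Cp <- e$vectors %*% (ev * t(e$vectors))
  d <- diag(Cp)
  if (any(d <= 0)) stop("target correlation matrix is not projectable")
  Cp / tcrossprod(sqrt(d))
}

# Base patterns (objects x voxels) with a target inter-object correlation
# structure, via the Cholesky factor of the PD-projected target matrix.
implant_base_patterns <- function(model_pv, n_objects, n_voxels, effect_size,
                                  baseline, gain) {
  npair <- length(model_pv)
  alpha <- abs(effect_size)
  zm <- zscore(rank(model_pv))
  zg <- stats::rnorm(npair)
  zg <- zscore(stats::lm.fit(cbind(1, zm), zg)$residuals)
  mix <- -alpha * zm + sqrt(1 - alpha^2) * zg
  C <- pairvec_to_mat(baseline + gain * mix, diag = 1)
  L <- chol(project_correlation(C))
  Z <- matrix(stats::rnorm(n_objects * n_voxels), n_objects)
  crossprod(L, Z)
}

#' Generate a synthetic pre/post session pair
#'
#' Builds two [volume_series()] realizing one subject's picture-viewing
#' sessions. Every volume is filled with iid Gaussian noise of sd
#' `noise_sd`; at each trial's analysis volume (onset + 2) the base pattern
#' of the shown object is added over the mask voxels. Pre-session object
#' patterns are mutually uncorrelated; post-session patterns inside
#' `effect_roi` carry the implanted correlation structure of `effect` (see
#' [effect_spec()]), while outside the ROI the post base equals the pre
#' base. The target object gets its own pattern in both sessions and is
#' discarded at extraction.
#'
#' @param recipe A [generate_pvt_recipe()] recipe (shared pre/post).
#' @param model A [distance_model()] whose pair vector defines the implanted
#'   gradient (typically a remembered distance model).
#' @param effect An [effect_spec()].
#' @param mask Optional 3D logical analysis mask (default: all voxels).
#' @param voxel_size Voxel size in mm.
#' @param motion `"zero"` for all-zero motion tables, `"sinusoidal"` for
#'   slow sinusoidal nuisance regressors whose effect is also added to the
#'   voxel series.
#' @return List with elements `pre` and `post` (both `volume_series`).
#' @export
generate_volumes <- function(recipe, model, effect, mask = NULL,
                             voxel_size = c(1.5, 1.5, 1.5),
                             motion = c("zero", "sinusoidal")) {
  stopifnot(inherits(recipe, "pvt_recipe"), inherits(effect, "effect_spec"))
  motion <- match.arg(motion)
  model_pv <- as_pair_vector(model)
  if (!all(is.finite(model_pv))) stop("model pair vector must be finite")
  spatial <- dim(effect$effect_roi)
  if (is.null(mask)) mask <- array(TRUE, spatial)
  stopifnot(all(dim(mask) == spatial))
  if (any(effect$effect_roi & !mask)) {
    stop("effect_roi must be contained in the mask")
  }
  n_all <- recipe$n_objects           # includes the target
  n_obj <- n_all - 1L
  mask_idx <- which(mask)
  roi_in_mask <- which(effect$effect_roi[mask_idx]) # ROI cols within mask
  n_vox <- length(mask_idx)
  n_vol <- recipe$n_volumes

  with_seed_or_current(effect$seed, {
    base_pre <- matrix(stats::rnorm(n_all * n_vox), n_all)
    base_post <- base_pre
    if (effect$effect_size < 0 && length(roi_in_mask) > 0) {
      base_post[seq_len(n_obj), roi_in_mask] <-
        implant_base_patterns(model_pv, n_obj, length(roi_in_mask),
                              effect$effect_size, effect$baseline,
                              effect$gain)
    } else if (length(roi_in_mask) > 0) {
      # zero effect: fresh independent draws, no structure
      base_post[seq_len(n_obj), roi_in_mask] <-
        matrix(stats::rnorm(n_obj * length(roi_in_mask)), n_obj)
    }
    sessions <- lapply(list(pre = base_pre, post = base_post), function(base) {
      dat <- array(stats::rnorm(prod(spatial) * n_vol, 0, effect$noise_sd),
                   c(spatial, n_vol))
      flat <- matrix(dat, prod(spatial), n_vol)
      vsel <- recipe$trials$onset_volume + 2L + 1L # 0-based onset -> R index
      for (t in seq_len(nrow(recipe$trials))) {
        flat[mask_idx, vsel[t]] <- flat[mask_idx, vsel[t]] +
          base[recipe$trials$object[t], ]
      }
      mot <- NULL
      if (motion == "sinusoidal") {
        tt <- seq_len(n_vol)
        mot <- as.data.frame(
          vapply(seq_len(6), function(k)
            0.5 * sin(2 * pi * tt / (40 + 15 * k) + k), numeric(n_vol)))
        names(mot) <- c("tx", "ty", "tz", "rx", "ry", "rz")
        load <- matrix(stats::rnorm(prod(spatial) * 6, 0, 0.5), ncol = 6)
        flat <- flat + load %*% t(as.matrix(mot))
      }
      volume_series(array(flat, c(spatial, n_vol)), voxel_size, mask, mot)
    })
    sessions
  })
}

#' Write / read a volume series as NIfTI plus a motion TSV
#'
#' The 4D data go to `<path>.nii` (uncompressed, so regeneration with the
#' same seed is byte-identical), the mask to `<path>_mask.nii`, and the
#' motion table to `<path>_motion.tsv`.
#'
#' @param series A `volume_series`.
#' @param path Output path prefix (no extension).
#' @return `write_volume_series` returns the prefix invisibly;
#'   `read_volume_series` returns a `volume_series`.
#' @export
write_volume_series <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, 1)
  RNifti::writeNifti(img, paste0(path, ".nii"))
  msk <- RNifti::asNifti(array(as.integer(series$mask), dim(series$mask)))
  RNifti::pixdim(msk) <- series$voxel_size
  RNifti::writeNifti(msk, paste0(path, "_mask.nii"))
  utils::write.table(series$motion, paste0(path, "_motion.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  img <- RNifti::readNifti(paste0(path, ".nii"))
  mask <- RNifti::readNifti(paste0(path, "_mask.nii"))
  motion <- utils::read.delim(paste0(path, "_motion.tsv"))
  vs <- RNifti::pixdim(img)[1:3]
  volume_series(array(as.numeric(img), dim(img)), voxel_size = vs,
                mask = array(as.numeric(mask) > 0.5, dim(mask)),
                motion = motion)
}

#' Box-shaped 3D mask helper
#'
#' @param dim Grid dimensions, length 3.
#' @param from,to Inclusive voxel index ranges per axis (length 3).
#' @return 3D logical array.
#' @export
box_mask <- function(dim, from, to) {
  stopifnot(length(dim) == 3, length(from) == 3, length(to) == 3,
            all(from >= 1), all(to <= dim), all(from <= to))
  m <- array(FALSE, dim)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}
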