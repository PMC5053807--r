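#' Write / read a similarity or change matrix as TSV
#'
#' Serializes the object x object matrix of a [crosscorr_matrix()] or
#' [ps_change()] result (or a plain symmetric matrix) with object ids as
#' header and first column.
#'
#' @param x A `crosscorr_matrix`, `ps_change_matrix`, or matrix.
#' @param path Output file path.
#' @return `path` invisibly; `read_matrix_tsv` returns the matrix with
#'   object ids as dimnames.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (is.matrix(x)) x else x$values
  ids <- if (is.matrix(x)) seq_len(nrow(m)) else x$object_ids
  df <- data.frame(object = ids, m)
  names(df) <- c("object", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df$object, names(df)[-1])
  m
}

#' Write / read a first-level shuffle-null result as JSON
#'
#' Stores every field of a [subject_shuffle_z()] result, including the seed
#' and shuffle count, so the statistic is exactly reproducible.
#'
#' @param sz A `subject_z` object.
#' @param path Output file path.
#' @return `path` invisibly; `read_subject_z` returns a `subject_z`.
#' @export
write_subject_z <- function(sz, path) {
  stopifnot(inherits(sz, "subject_z"))
  jsonlite::write_json(unclass(sz), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_subject_z
#' @export
read_subject_z <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "subject_z")
}

#' Write / read a searchlight statistic map as NIfTI
#'
#' Centers that were not analysed are stored as `NaN`; reading rebuilds the
#' validity mask from them. Written uncompressed so regeneration under a
#' fixed seed is byte-identical.
#'
#' @param map A `stat_map` (see [searchlight_map()]).
#' @param path Output path (`.nii` appended if absent).
#' @return `write_stat_map` returns the path invisibly; `read_stat_map`
#'   returns a `stat_map`.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  if (!grepl("\\.nii$", path)) path <- paste0(path, ".nii")
  vals <- map$values
  vals[!map$valid] <- NaN
  RNifti::writeNifti(RNifti::asNifti(vals), path)
  invisible(path)
}

#' @rdname write_stat_map
#' @export
read_stat_map <- function(path) {
  if (!grepl("\\.nii$", path)) path <- paste0(path, ".nii")
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  valid <- is.finite(vals)
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, dim = dim(vals)),
            class = "stat_map")
}
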