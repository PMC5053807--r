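#' Pairwise distance model
#'
#' A symmetric object-by-object distance matrix together with its canonical
#' pair vector (row-major upper triangle). Distance models are the "external
#' variables" that pattern-similarity change matrices are compared against:
#' objective spatial (Euclidean) and temporal (along-route travel time)
#' distances, remembered distances from the judgment task, or their
#' combination.
#'
#' @param values Symmetric numeric matrix with non-negative off-diagonal
#'   entries. The diagonal is undefined and stored as `NA`.
#' @param domain One of `"spatial"`, `"temporal"`, `"combined"`,
#'   `"objective_spatial"`, `"objective_temporal"`.
#' @return Object of class `distance_model` with elements `values`, `domain`
#'   and `pair_vector`.
#' @export
distance_model <- function(values,
                           domain = c("spatial", "temporal", "combined",
                                      "objective_spatial",
                                      "objective_temporal")) {
  domain <- match.arg(domain)
  stopifnot(is.matrix(values), nrow(values) == ncol(values), nrow(values) >= 2)
  pv <- mat_to_pairvec(values)
  pv_t <- mat_to_pairvec(t(values))
  if (any(abs(pv - pv_t) > 1e-10, na.rm = TRUE)) {
    stop("'values' must be symmetric")
  }
  if (any(pv < 0, na.rm = TRUE)) {
    stop("distance model entries must be non-negative")
  }
  diag(values) <- NA_real_
  structure(
    list(values = values, domain = domain, pair_vector = pv),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("<distance_model: %s, %d objects, %d pairs>\n",
              x$domain, nrow(x$values), length(x$pair_vector)))
  invisible(x)
}

# Accept a distance_model, a symmetric matrix, or a bare pair vector and
# return the canonical pair vector.
as_pair_vector <- function(x) {
  if (inherits(x, "distance_model")) return(x$pair_vector)
  if (inherits(x, "ps_change_matrix")) return(x$pair_vector)
  if (is.matrix(x)) return(mat_to_pairvec(x))
  if (is.numeric(x)) return(as.numeric(x))
  stop("cannot interpret input as a pair vector")
}
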