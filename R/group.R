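#' Second-level sign-flip test
#'
#' Nonparametric one-sample test of per-subject statistics (typically the
#' first-level shuffle-null z values): the observed mean is compared to a
#' null distribution of means of randomly sign-flipped values, valid under
#' sign symmetry of the null. When `2^n` does not exceed `2^20` the full
#' enumeration is used (exact p, the identity flip included); otherwise
#' random flips are drawn and the add-one Monte-Carlo estimate reported.
#'
#' @param subject_stats Numeric vector of per-subject values (n >= 2).
#' @param n_flips Number of random sign-flips (default 10000).
#' @param seed Integer seed (Monte-Carlo mode).
#' @param tail `"negative"` (default; tests for consistently negative
#'   values, i.e. higher similarity gain at lower distance), `"positive"`,
#'   or `"two"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` auto-selects.
#' @return Object of class `group_result`: `mean_obs`, `group_z`, `p`,
#'   `tail`, `n_subjects`, `n_flips`, `exact`, `seed`.
#' @export
signflip_group_test <- function(subject_stats, n_flips = 10000L, seed = NULL,
                                tail = c("negative", "positive", "two"),
                                exact = NULL) {
  tail <- match.arg(tail)
  x <- as.numeric(subject_stats)
  n <- length(x)
  stopifnot(n >= 2)
  if (all(x == 0)) stop("all subject statistics are zero: test degenerate")
  if (is.null(exact)) exact <- n <= 20
  obs <- mean(x)
  if (exact) {
    sums <- 0
    for (v in x) sums <- c(sums + v, sums - v)
    surr <- sums / n
    # tolerance so the identity flip always counts despite rounding
    tol <- 1e-10 * max(1, abs(obs))
    p <- switch(tail,
                negative = mean(surr <= obs + tol),
                positive = mean(surr >= obs - tol),
                two = mean(abs(surr) >= abs(obs) - tol))
    n_flips <- length(surr)
  } else {
    surr <- with_seed_or_current(seed, {
      S <- matrix(sample(c(-1, 1), n * n_flips, replace = TRUE), n)
      as.vector(crossprod(S, x)) / n
    })
    p <- switch(tail,
                negative = (1 + sum(surr <= obs)) / (1 + n_flips),
                positive = (1 + sum(surr >= obs)) / (1 + n_flips),
                two = (1 + sum(abs(surr) >= abs(obs))) / (1 + n_flips))
  }
  sd_s <- stats::sd(surr)
  structure(
    list(mean_obs = obs,
         group_z = if (sd_s > 0) (obs - mean(surr)) / sd_s else NA_real_,
         p = p, tail = tail, n_subjects = n,
         n_flips = as.integer(n_flips), exact = exact, seed = seed),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result: mean=%.4f z=%.3f p(%s)=%.5g (%s)>\n",
              x$mean_obs, x$group_z, x$tail, x$p,
              if (x$exact) "exhaustive" else sprintf("%d flips", x$n_flips)))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction with enforced monotonicity,
#' applied to the family of ROI x model p values.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values (same length and order).
#' @export
fdr_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), length(pvals) >= 1)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' 2 x 2 repeated-measures ANOVA on PS' cell means
#'
#' Within-subject ANOVA of pattern-similarity change averaged in the four
#' objective-distance design cells (space high/low x time high/low). For a
#' 2 x 2 within design every effect has one numerator df, so each F(1, n-1)
#' equals the squared paired t of the corresponding contrast, which is how
#' it is computed.
#'
#' @param cell_means Numeric matrix or data frame, one row per subject,
#'   columns named `space_high.time_high`, `space_high.time_low`,
#'   `space_low.time_high`, `space_low.time_low`.
#' @return Data frame with rows `space`, `time`, `interaction` and columns
#'   `F`, `df1`, `df2`, `p`.
#' @export
objective_2x2_anova <- function(cell_means) {
  cm <- as.matrix(cell_means)
  need <- c("space_high.time_high", "space_high.time_low",
            "space_low.time_high", "space_low.time_low")
  if (!all(need %in% colnames(cm))) {
    stop("missing design cell(s): ",
         paste(setdiff(need, colnames(cm)), collapse = ", "))
  }
  cm <- cm[, need, drop = FALSE]
  if (any(!is.finite(cm))) stop("missing cell means")
  n <- nrow(cm)
  stopifnot(n >= 2)
  contrasts <- list(
    space = c(1, 1, -1, -1) / 2,
    time = c(1, -1, 1, -1) / 2,
    interaction = c(1, -1, -1, 1)
  )
  out <- lapply(names(contrasts), function(nm) {
    d <- as.vector(cm %*% contrasts[[nm]])
    se <- stats::sd(d) / sqrt(n)
    tval <- if (se > 0) mean(d) / se else 0
    data.frame(effect = nm, F = tval^2, df1 = 1L, df2 = n - 1L,
               p = stats::pf(tval^2, 1, n - 1, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Mean PS' within the objective-distance design cells
#'
#' @param ps A `ps_change_matrix` (or pair vector).
#' @param cells Factor over pairs from [route_pair_cells()].
#' @return Named numeric vector of the four cell means.
#' @export
ps_cell_means <- function(ps, cells) {
  pv <- as_pair_vector(ps)
  stopifnot(length(pv) == length(cells))
  tapply(pv, cells, mean)
}

# Resolve one model specification for a subject: a distance model to
# correlate with PS', plus an optional covariate removed from PS' first.
resolve_model <- function(name, remembered, objective) {
  switch(name,
    spatial = list(model = remembered$spatial, remove = NULL),
    temporal = list(model = remembered$temporal, remove = NULL),
    combined = list(model = remembered$combined, remove = NULL),
    spatial_partial = list(model = remembered$spatial,
                           remove = remembered$temporal),
    temporal_partial = list(model = remembered$temporal,
                            remove = remembered$spatial),
    objective_spatial = list(model = objective$spatial, remove = NULL),
    objective_temporal = list(model = objective$temporal, remove = NULL),
    objective_combined = list(model = objective$combined, remove = NULL),
    stop("unknown model name: ", name)
  )
}

#' Default model list of the remembered-distance ROI analysis
#' @return Character vector of the five effects: spatial, temporal,
#'   combined, and each domain with the other domain's influence removed.
#' @export
default_models <- function() {
  c("spatial", "temporal", "combined", "spatial_partial", "temporal_partial")
}

# First-level analysis of one subject in one ROI: extraction ->
# cross-correlation -> PS' -> per-model (residualize ->) Spearman ->
# shuffle-null z.
subject_roi_z <- function(subject, roi_mask, models, n_shuffles, seed,
                          demean_motion = TRUE) {
  pre <- subject$pre
  post <- subject$post
  if (demean_motion) {
    pre <- regress_motion(pre)
    post <- regress_motion(post)
  }
  amask <- intersect_masks(subject$pre$mask, subject$post$mask, roi_mask)
  pat_pre <- select_trial_volumes(pre, subject$recipe, amask)
  pat_post <- select_trial_volumes(post, subject$recipe, amask)
  psc <- ps_change(crosscorr_matrix(pat_pre, "pre"),
                   crosscorr_matrix(pat_post, "post"))
  remembered <- remembered_models(subject$behavior)
  objective <- subject_objective_models(subject)
  out <- numeric(length(models))
  names(out) <- models
  for (k in seq_along(models)) {
    spec <- resolve_model(models[k], remembered, objective)
    target <- if (is.null(spec$remove)) psc$pair_vector else
      residualize(psc, spec$remove)
    sz <- subject_shuffle_z(target, spec$model, n_shuffles = n_shuffles,
                            seed = derive_seed(seed, k))
    out[k] <- sz$z
  }
  list(z = out, ps = psc)
}

subject_objective_models <- function(subject) {
  if (is.null(subject$route)) return(NULL)
  sp <- route_distances(subject$route, "spatial")
  tm <- route_distances(subject$route, "temporal")
  list(spatial = sp, temporal = tm, combined = combined_model(sp, tm))
}

#' ROI pipeline: first and second level over a cohort
#'
#' For every ROI and model, runs extraction, cross-correlation, PS', model
#' correlation and the first-level shuffle-null z per subject, then the
#' second-level sign-flip test, and finally FDR correction over the full
#' ROI x model family.
#'
#' @param cohort List of subjects; each subject is a list with elements
#'   `pre`, `post` ([volume_series()]), `recipe` ([generate_pvt_recipe()]),
#'   `behavior` ([generate_behavior()]) and `route` ([route_design()],
#'   needed for objective models).
#' @param rois Named list of 3D logical ROI masks.
#' @param models Character vector of model names (see [default_models()];
#'   objective variants: `objective_spatial`, `objective_temporal`,
#'   `objective_combined`).
#' @param n_shuffles First-level shuffles (default 10000).
#' @param n_flips Second-level sign-flips (default 10000).
#' @param seed Integer seed driving all shuffles and flips.
#' @param tail Second-level tail (default `"negative"`).
#' @return Object of class `roi_result`: `table` (data frame with one row
#'   per ROI x model: `roi`, `model`, `mean_z`, `group_z`, `p`, `p_fdr`)
#'   and `subject_z` (named list of subject-by-model z matrices per ROI).
#' @export
roi_pipeline <- function(cohort, rois, models = default_models(),
                         n_shuffles = 10000L, n_flips = 10000L, seed = NULL,
                         tail = "negative") {
  stopifnot(length(cohort) >= 2, length(rois) >= 1, !is.null(names(rois)))
  if (is.null(seed)) seed <- stats::runif(1, 1, 2^31 - 2)
  rows <- list()
  zmats <- list()
  for (r in names(rois)) {
    Z <- matrix(NA_real_, length(cohort), length(models),
                dimnames = list(NULL, models))
    for (s in seq_along(cohort)) {
      res <- tryCatch(
        subject_roi_z(cohort[[s]], rois[[r]], models, n_shuffles,
                      seed = derive_seed(seed, s * 1000L + match(r, names(rois)))),
        error = function(e) stop("ROI '", r, "', subject ", s, ": ",
                                 conditionMessage(e), call. = FALSE)
      )
      Z[s, ] <- res$z
    }
    zmats[[r]] <- Z
    for (m in models) {
      gr <- signflip_group_test(Z[, m], n_flips = n_flips,
                                seed = derive_seed(seed, match(r, names(rois)) *
                                                     100L + match(m, models)),
                                tail = tail)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, model = m, mean_z = gr$mean_obs, group_z = gr$group_z,
        p = gr$p)
    }
  }
  table <- do.call(rbind, rows)
  table$p_fdr <- fdr_adjust(table$p)
  structure(list(table = table, subject_z = zmats,
                 models = models, n_shuffles = n_shuffles,
                 n_flips = n_flips, seed = seed, tail = tail),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result: %d ROIs x %d models, FDR family %d>\n",
              length(x$subject_z), length(x$models), nrow(x$table)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Objective-distance 2 x 2 analysis over a cohort
#'
#' Averages every subject's PS' within the four objective design cells of
#' the route and runs the within-subject 2 x 2 ANOVA per ROI.
#'
#' @inheritParams roi_pipeline
#' @return Named list (per ROI) of [objective_2x2_anova()] tables, with the
#'   subject cell-mean matrices attached as attribute `"cell_means"`.
#' @export
roi_objective_anova <- function(cohort, rois, n_shuffles = 1000L,
                                seed = NULL) {
  stopifnot(length(cohort) >= 2)
  out <- list()
  for (r in names(rois)) {
    cm <- t(vapply(cohort, function(subj) {
      pre <- regress_motion(subj$pre)
      post <- regress_motion(subj$post)
      amask <- intersect_masks(subj$pre$mask, subj$post$mask, rois[[r]])
      psc <- ps_change(
        crosscorr_matrix(select_trial_volumes(pre, subj$recipe, amask), "pre"),
        crosscorr_matrix(select_trial_volumes(post, subj$recipe, amask), "post"))
      ps_cell_means(psc, route_pair_cells(subj$route))
    }, numeric(4)))
    tab <- objective_2x2_anova(cm)
    attr(tab, "cell_means") <- cm
    out[[r]] <- tab
  }
  out
}
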