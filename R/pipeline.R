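#' Default run configuration
#'
#' One configuration object drives both dataset simulation and analysis.
#' Every stochastic stage has an explicit seed (derived from `seed` if not
#' given); defaults are materialized into the dataset manifest so a run is
#' a pure function of its config.
#'
#' @param seed Master seed from which unset stage seeds are derived.
#' @return Named list (class `run_config`).
#' @export
run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    seeds = list(design = derive_seed(seed, 11),
                 behavior = derive_seed(seed, 12),
                 volumes = derive_seed(seed, 13),
                 shuffles = derive_seed(seed, 14),
                 flips = derive_seed(seed, 15)),
    n_subjects = 4L,
    n_shuffles = 1000L,
    n_flips = 1000L,
    models = default_models(),
    tail = "negative",
    simulation = list(),            # overrides for simulation_config()
    searchlight = list(radius = 3, min_voxels = 10L),
    run_searchlight = FALSE
  ), class = "run_config")
}

#' Load and validate a run configuration from YAML or JSON
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A validated `run_config` (unset fields filled with defaults
#'   derived from its `seed`).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config validation: 'seed' is required")
  cfg <- utils::modifyList(run_config(raw$seed), raw)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  needed <- c("design", "behavior", "volumes", "shuffles", "flips")
  missing <- setdiff(needed, names(cfg$seeds))
  if (length(missing)) {
    stop("config validation: missing seed(s): ",
         paste(missing, collapse = ", "))
  }
  stopifnot(cfg$n_subjects >= 1, cfg$n_shuffles >= 100, cfg$n_flips >= 100)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulate a dataset directory
#'
#' Generates the cohort described by the config and writes every artifact:
#' `manifest.json` (full materialized config and seeds), the route design
#' (`route.json`), and per subject the recipe, ratings, recall and map
#' TSVs, the pre/post NIfTI series with masks and motion tables, and the
#' effect/control ROI masks.
#'
#' @param config A `run_config` (or path to one).
#' @param out Output directory (created; must not exist or be empty).
#' @return The dataset directory path, invisibly.
#' @export
run_simulate <- function(config, out) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  if (dir.exists(out) && length(dir(out))) {
    stop("output directory exists and is not empty: ", out)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim_cfg <- utils::modifyList(simulation_config(), cfg$simulation)
  sim_cfg$n_subjects <- cfg$n_subjects
  cohort <- simulate_cohort(sim_cfg, seed = cfg$seeds$design)
  route <- cohort$route
  jsonlite::write_json(
    list(config = unclass(cfg),
         route = list(coords = route$coords, order = route$order,
                      segment_duration = route$segment_duration,
                      teleporter_after = route$teleporter_after,
                      map_side = route$map_side,
                      domain_correlation = attr(route, "domain_correlation")),
         n_subjects = length(cohort$subjects),
         n_trials_per_session = nrow(cohort$subjects[[1]]$recipe$trials),
         n_sessions = 2L),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (s in seq_along(cohort$subjects)) {
    subj <- cohort$subjects[[s]]
    sd <- file.path(out, sprintf("sub-%02d", s))
    dir.create(sd)
    write_recipe(subj$recipe, file.path(sd, "recipe.tsv"))
    utils::write.table(subj$behavior$ratings, file.path(sd, "ratings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(subj$behavior$recall_sequence, collapse = "\t"),
               file.path(sd, "recall.tsv"))
    utils::write.table(subj$behavior$map_responses, file.path(sd, "map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_volume_series(subj$pre, file.path(sd, "pre"))
    write_volume_series(subj$post, file.path(sd, "post"))
    if (s == 1L) {
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(subj$effect_roi),
                                               dim(subj$effect_roi))),
                         file.path(out, "effect_roi.nii"))
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(subj$control_roi),
                                               dim(subj$control_roi))),
                         file.path(out, "control_roi.nii"))
    }
  }
  invisible(out)
}

read_subject_dir <- function(sd, route) {
  ratings <- utils::read.delim(file.path(sd, "ratings.tsv"))
  recall <- as.integer(strsplit(readLines(file.path(sd, "recall.tsv")),
                                "\t")[[1]])
  mapresp <- utils::read.delim(file.path(sd, "map.tsv"))
  behavior <- structure(list(ratings = ratings, recall_sequence = recall,
                             map_responses = mapresp,
                             params = behavior_config()),
                        class = "behavioral_dataset")
  list(route = route,
       behavior = behavior,
       recipe = read_recipe(file.path(sd, "recipe.tsv")),
       pre = read_volume_series(file.path(sd, "pre")),
       post = read_volume_series(file.path(sd, "post")))
}

#' Load a simulated dataset directory
#' @param dataset_dir Directory written by [run_simulate()].
#' @return List with `manifest`, `route`, `subjects`, `rois`.
#' @export
read_dataset <- function(dataset_dir) {
  manifest <- jsonlite::read_json(file.path(dataset_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  r <- manifest$route
  route <- route_design(matrix(unlist(r$coords), ncol = 2), r$order,
                        r$segment_duration, r$teleporter_after, r$map_side)
  subs <- sort(dir(dataset_dir, pattern = "^sub-"))
  subjects <- lapply(file.path(dataset_dir, subs), read_subject_dir,
                     route = route)
  read_roi <- function(f) {
    img <- RNifti::readNifti(file.path(dataset_dir, f))
    array(as.numeric(img) > 0.5, dim(img))
  }
  rois <- list(effect = read_roi("effect_roi.nii"),
               control = read_roi("control_roi.nii"))
  list(manifest = manifest, route = route, subjects = subjects, rois = rois)
}

#' Analyze a simulated dataset
#'
#' Runs the behavioral analyses, the ROI pipeline and (optionally) the
#' searchlight over a dataset directory, writing result tables, a JSON
#' summary and a human-readable report with all parameters and seeds.
#'
#' @param config A `run_config` (or path to one); seeds and shuffle/flip
#'   counts are taken from it.
#' @param dataset_dir Directory produced by [run_simulate()].
#' @param out Results directory.
#' @return List with `behavior` (per-subject table), `behavior_group`,
#'   `roi` (the [roi_pipeline()] result) and optionally `searchlight`,
#'   invisibly; everything is also written under `out`.
#' @export
run_analysis <- function(config, dataset_dir, out) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  if (!file.exists(file.path(dataset_dir, "manifest.json"))) {
    stop("not a dataset directory (no manifest.json): ", dataset_dir)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  logline <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  t0 <- proc.time()[3]
  ds <- read_dataset(dataset_dir)
  logline("loaded %d subjects (%.1f s)", length(ds$subjects),
          proc.time()[3] - t0)

  behavior <- analyze_cohort_behavior(ds$subjects, ds$route)
  utils::write.table(behavior$per_subject,
                     file.path(out, "behavior_subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("behavioral analysis done")

  roi <- roi_pipeline(ds$subjects, ds$rois, models = cfg$models,
                      n_shuffles = cfg$n_shuffles, n_flips = cfg$n_flips,
                      seed = cfg$seeds$shuffles, tail = cfg$tail)
  utils::write.table(roi$table, file.path(out, "roi_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("ROI pipeline done (%d ROIs x %d models)", length(ds$rois),
          length(cfg$models))

  searchlight <- NULL
  if (isTRUE(cfg$run_searchlight)) {
    searchlight <- run_searchlight_stage(ds, cfg, out)
    logline("searchlight done")
  }

  summary <- list(
    n_subjects = length(ds$subjects),
    behavior = behavior$group,
    roi = roi$table,
    seeds = cfg$seeds,
    n_shuffles = cfg$n_shuffles, n_flips = cfg$n_flips
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(render_report(cfg, ds, behavior, roi),
             file.path(out, "report.txt"))
  logline("report written (total %.1f s)", proc.time()[3] - t0)
  invisible(list(behavior = behavior$per_subject,
                 behavior_group = behavior$group, roi = roi,
                 searchlight = searchlight))
}

run_searchlight_stage <- function(ds, cfg, out) {
  spec <- do.call(searchlight_spec,
                  c(cfg$searchlight,
                    list(voxel_size = ds$subjects[[1]]$pre$voxel_size)))
  mask0 <- ds$subjects[[1]]$pre$mask
  spheres <- build_spheres(mask0, spec)
  # subject maps are written to disk and the group stage consumes the
  # files, so first and second level can run as separate processes
  map_paths <- vapply(seq_along(ds$subjects), function(s) {
    subj <- ds$subjects[[s]]
    amask <- intersect_masks(subj$pre$mask, subj$post$mask)
    pp <- select_trial_volumes(regress_motion(subj$pre), subj$recipe, amask)
    pq <- select_trial_volumes(regress_motion(subj$post), subj$recipe, amask)
    model <- remembered_models(subj$behavior)$combined
    write_stat_map(searchlight_map(pp, pq, model, spheres),
                   file.path(out, sprintf("searchlight_sub-%02d.nii", s)))
  }, character(1))
  maps <- lapply(map_paths, read_stat_map)
  grp <- group_searchlight(maps, n_flips = cfg$n_flips,
                           seed = cfg$seeds$flips,
                           svc_mask = ds$rois$effect)
  RNifti::writeNifti(RNifti::asNifti(grp$t_map),
                     file.path(out, "searchlight_t.nii"))
  RNifti::writeNifti(RNifti::asNifti(grp$p_corr_map),
                     file.path(out, "searchlight_p_corr.nii"))
  grp
}

#' Behavioral analyses over a cohort
#'
#' Per subject: rating accuracy per domain, two-predictor GLM betas per
#' rated domain, cross-domain error-bias Fisher z, recall-order
#' correlations and map displacement; plus the group-level tests (t tests
#' of Fisher-z coefficients, paired recall-order comparison).
#'
#' @param subjects List of subject objects (see [roi_pipeline()]).
#' @param route The shared [route_design()].
#' @return List with `per_subject` (data frame) and `group` (named list).
#' @export
analyze_cohort_behavior <- function(subjects, route) {
  truth <- list(spatial = route_distances(route, "spatial"),
                temporal = route_distances(route, "temporal"))
  rows <- lapply(seq_along(subjects), function(s) {
    b <- subjects[[s]]$behavior
    acc <- rating_accuracy(b, truth)
    glm_s <- rating_glm(b$ratings[b$ratings$domain == "space", ],
                        truth$spatial, truth$temporal)
    glm_t <- rating_glm(b$ratings[b$ratings$domain == "time", ],
                        truth$spatial, truth$temporal)
    rem <- remembered_models(b)
    eb_s <- error_bias(b, "space", truth$spatial, truth$temporal)
    eb_t <- error_bias(b, "time", truth$temporal, truth$spatial)
    eb_s_rem <- error_bias(b, "space", truth$spatial, rem$temporal)
    eb_t_rem <- error_bias(b, "time", truth$temporal, rem$spatial)
    rec <- recall_order_analysis(b$recall_sequence, truth$spatial,
                                 truth$temporal)
    data.frame(
      subject = s,
      acc_r_space = acc$r[acc$domain == "space"],
      acc_r_time = acc$r[acc$domain == "time"],
      beta_space_own = unname(glm_s["space"]),
      beta_space_cross = unname(glm_s["time"]),
      beta_time_own = unname(glm_t["time"]),
      beta_time_cross = unname(glm_t["space"]),
      errbias_space_z = eb_s$fisher_z[1],
      errbias_time_z = eb_t$fisher_z[1],
      errbias_space_rem_z = eb_s_rem$fisher_z[1],
      errbias_time_rem_z = eb_t_rem$fisher_z[1],
      recall_r_space = rec$r_space,
      recall_r_time = rec$r_time,
      n_recalled = rec$n_recalled,
      map_error = map_error(b$map_responses, route$coords, route$map_side)
    )
  })
  tab <- do.call(rbind, rows)
  rec_z_s <- cap_fisher_z(tab$recall_r_space)
  rec_z_t <- cap_fisher_z(tab$recall_r_time)
  group <- list(
    acc_r_space_mean = mean(tab$acc_r_space),
    acc_r_time_mean = mean(tab$acc_r_time),
    beta_space = list(own = mean(tab$beta_space_own),
                      cross = mean(tab$beta_space_cross)),
    beta_time = list(own = mean(tab$beta_time_own),
                     cross = mean(tab$beta_time_cross)),
    errbias_space = as.list(fisher_z_ttest(tab$errbias_space_z)),
    errbias_time = as.list(fisher_z_ttest(tab$errbias_time_z)),
    recall = if (length(subjects) >= 2) {
      tt <- stats::t.test(rec_z_t, rec_z_s, paired = TRUE)
      list(r_space_mean = mean(tab$recall_r_space),
           r_time_mean = mean(tab$recall_r_time),
           t_time_vs_space = unname(tt$statistic), p = tt$p.value)
    } else NULL,
    map_error_mean = mean(tab$map_error)
  )
  list(per_subject = tab, group = group)
}

render_report <- function(cfg, ds, behavior, roi) {
  c(sprintf("event-map RSA analysis report"),
    sprintf("============================="),
    sprintf("subjects: %d   shuffles: %d   flips: %d   tail: %s",
            length(ds$subjects), cfg$n_shuffles, cfg$n_flips, cfg$tail),
    sprintf("seeds: design=%d behavior=%d volumes=%d shuffles=%d flips=%d",
            cfg$seeds$design, cfg$seeds$behavior, cfg$seeds$volumes,
            cfg$seeds$shuffles, cfg$seeds$flips),
    "",
    "Behavior (group):",
    sprintf("  accuracy r: space %.3f, time %.3f",
            behavior$group$acc_r_space_mean, behavior$group$acc_r_time_mean),
    sprintf("  map displacement ratio: %.3f", behavior$group$map_error_mean),
    "",
    "ROI results (FDR over the full ROI x model family):",
    utils::capture.output(print(roi$table, digits = 4, row.names = FALSE)))
}
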