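# Shared fixture builders; everything is generated in code at test time.

# 4-object route with hand-checkable geometry: a 3-4-3 "U" on a 10x10 map.
toy_route <- function() {
  route_design(
    coords = rbind(c(0, 0), c(3, 0), c(3, 4), c(0, 4)),
    segment_duration = c(3, 4, 3), # unit speed walk along the U
    map_side = 10
  )
}

# Collinear, equally spaced objects at constant speed: time = distance on a
# line, so spatial and temporal pair distances are proportional.
collinear_route <- function(n = 6) {
  route_design(
    coords = cbind(seq(0, 10, length.out = n), rep(5, n)),
    segment_duration = rep(10 / (n - 1), n - 1),
    map_side = 10
  )
}

# Ratings data frame for one domain from a pair vector of ratings.
ratings_df <- function(values, domain = "space", n_objects = NULL) {
  if (is.null(n_objects)) {
    n_objects <- as.integer(round((1 + sqrt(1 + 8 * length(values))) / 2))
  }
  idx <- pair_indices(n_objects)
  data.frame(pair_i = idx[, 1], pair_j = idx[, 2], domain = domain,
             rating = values, tested_first = "space")
}

# Minimal behavioral dataset with prescribed rating pair vectors.
behavior_from_ratings <- function(space_values, time_values,
                                  tested_first = NULL) {
  rs <- ratings_df(space_values, "space")
  rt <- ratings_df(time_values, "time")
  ratings <- rbind(rs, rt)
  if (!is.null(tested_first)) ratings$tested_first <- rep(tested_first, 2)
  structure(list(ratings = ratings, recall_sequence = integer(),
                 map_responses = NULL, params = behavior_config()),
            class = "behavioral_dataset")
}

# Trial patterns built directly from a base object x voxel matrix: every
# repetition repeats the object's base pattern plus optional noise.
patterns_from_base <- function(base, n_rep = 3, noise_sd = 0) {
  n_obj <- nrow(base)
  n_vox <- ncol(base)
  vals <- array(NA_real_, c(n_obj, n_rep, n_vox))
  for (o in seq_len(n_obj)) {
    for (r in seq_len(n_rep)) {
      vals[o, r, ] <- base[o, ] +
        if (noise_sd > 0) rnorm(n_vox, 0, noise_sd) else 0
    }
  }
  blocks <- matrix(rep(seq_len(n_rep), n_obj), n_obj, n_rep, byrow = TRUE)
  trial_patterns(vals, seq_len(n_obj), blocks, seq_len(n_vox),
                 c(n_vox, 1L, 1L))
}

# Small simulation configuration shared by pipeline-level tests: 6^3 grid,
# 27-voxel effect and control boxes in opposite corners.
tiny_sim_config <- function(...) {
  utils::modifyList(
    list(grid_dim = c(6L, 6L, 6L),
         effect_box = list(from = c(1L, 1L, 1L), to = c(3L, 3L, 3L)),
         control_box = list(from = c(4L, 4L, 4L), to = c(6L, 6L, 6L))),
    list(...)
  )
}

# Cohort of null subjects (no implanted effect).
null_cohort <- function(n_subjects, route, seed, ...) {
  cfg <- tiny_sim_config(implant_model = "none", ...)
  lapply(seq_len(n_subjects), function(s) {
    simulate_subject(route, cfg, seed = derive_seed(seed, s))
  })
}

# Cohort with the implanted negative PS'-distance effect.
effect_cohort <- function(n_subjects, route, seed, effect_size = -0.6,
                          noise_sd = 0.3, ...) {
  cfg <- tiny_sim_config(effect_size = effect_size, noise_sd = noise_sd, ...)
  lapply(seq_len(n_subjects), function(s) {
    simulate_subject(route, cfg, seed = derive_seed(seed, s))
  })
}
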