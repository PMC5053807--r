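#' Default cohort simulation parameters
#'
#' The defaults mirror the study conditions the generator emulates: 26
#' subjects, 16 objects + 1 target shown once in each of 12 blocks, and an
#' implanted negative PS'-distance relation of -0.6 carried by the
#' remembered combined space-x-time model inside the effect ROI. Grid sizes
#' are kept small because only the mask/ROI voxel counts matter to the
#' statistics.
#'
#' @return Named list of parameters accepted by [simulate_subject()] and
#'   [simulate_cohort()].
#' @export
simulation_config <- function() {
  list(
    n_subjects = 26L,
    n_objects = 17L,          # incl. target
    n_blocks = 12L,
    grid_dim = c(16L, 16L, 16L),
    voxel_size = c(1.5, 1.5, 1.5),
    effect_box = list(from = c(4L, 4L, 4L), to = c(8L, 8L, 8L)),
    control_box = list(from = c(10L, 10L, 10L), to = c(14L, 14L, 14L)),
    effect_size = -0.6,
    noise_sd = 1,
    implant_model = "combined", # remembered model carrying the implant
    route = list(),             # overrides for route_config()
    behavior = list(),          # overrides for behavior_config()
    motion = "zero"
  )
}

#' Simulate one subject's complete dataset
#'
#' Generates the behavioral dataset, the (pre = post) picture-viewing
#' recipe and the pre/post volume series for one subject. The implanted
#' gradient follows the subject's own remembered distance model named in
#' `implant_model` (`"none"` for a null subject).
#'
#' @param route Cohort-level [route_design()].
#' @param config Named list overriding [simulation_config()].
#' @param seed Integer seed; every stage seed is derived from it.
#' @return List with elements `route`, `behavior`, `recipe`, `pre`, `post`,
#'   `effect_roi`, `control_roi`, `seed` — the subject format consumed by
#'   [roi_pipeline()] and [searchlight_map()].
#' @export
simulate_subject <- function(route, config = list(), seed = 1L) {
  cfg <- utils::modifyList(simulation_config(), config)
  behavior <- generate_behavior(route, cfg$behavior, seed = derive_seed(seed, 1))
  recipe <- generate_pvt_recipe(cfg$n_objects, cfg$n_blocks,
                                seed = derive_seed(seed, 2))
  effect_roi <- box_mask(cfg$grid_dim, cfg$effect_box$from, cfg$effect_box$to)
  control_roi <- box_mask(cfg$grid_dim, cfg$control_box$from,
                          cfg$control_box$to)
  if (identical(cfg$implant_model, "none")) {
    model <- route_distances(route, "spatial") # unused under zero effect
    es <- 0
  } else {
    model <- remembered_models(behavior)[[cfg$implant_model]]
    es <- cfg$effect_size
  }
  eff <- effect_spec(effect_roi, effect_size = es, noise_sd = cfg$noise_sd,
                     seed = derive_seed(seed, 3))
  sessions <- generate_volumes(recipe, model, eff,
                               voxel_size = cfg$voxel_size,
                               motion = cfg$motion)
  list(route = route, behavior = behavior, recipe = recipe,
       pre = sessions$pre, post = sessions$post,
       effect_roi = effect_roi, control_roi = control_roi, seed = seed)
}

#' Simulate a cohort sharing one route design
#'
#' @param config Named list overriding [simulation_config()].
#' @param seed Integer master seed (route and every subject derive from it).
#' @return List with `route`, `subjects` (list of [simulate_subject()]
#'   outputs), `config`.
#' @export
simulate_cohort <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(simulation_config(), config)
  route <- generate_route(cfg$route, seed = derive_seed(seed, 99))
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    simulate_subject(route, cfg, seed = derive_seed(seed, 100 + s))
  })
  list(route = route, subjects = subjects, config = cfg)
}
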