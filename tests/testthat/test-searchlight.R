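test_that("sphere offsets match the brute-force lattice count", {
  # radius 9 mm at 1.5 mm isotropic = 6 voxels
  off <- eventmapr:::sphere_offsets(9, c(1.5, 1.5, 1.5))
  grid <- expand.grid(x = -10:10, y = -10:10, z = -10:10)
  oracle <- sum(grid$x^2 + grid$y^2 + grid$z^2 <= 36)
  expect_equal(nrow(off), oracle)
  # an interior center of an all-true mask keeps the full sphere
  mask <- array(TRUE, c(15L, 15L, 15L))
  spec <- searchlight_spec(radius = 9, min_voxels = 30L)
  sl <- build_spheres(mask, spec)
  center <- which(sl$centers == 8L + 7L * 15L + 7L * 225L)
  expect_equal(length(sl$members[[center]]), oracle)
})

test_that("anisotropic voxel sizes scale the sphere correctly", {
  off <- eventmapr:::sphere_offsets(4, c(1, 2, 4))
  d2 <- off[, 1]^2 + (2 * off[, 2])^2 + (4 * off[, 3])^2
  expect_true(all(d2 <= 16))
  expect_true(any(off[, 3] != 0)) # one voxel step in z = 4 mm is included
})

test_that("a radius below the voxel size leaves only the center", {
  off <- eventmapr:::sphere_offsets(1, c(1.5, 1.5, 1.5))
  expect_equal(nrow(off), 1L)
  mask <- array(TRUE, c(3L, 3L, 3L))
  expect_error(build_spheres(mask, searchlight_spec(radius = 1,
                                                    min_voxels = 2L)),
               "no searchlight")
})

test_that("spheres below the minimum voxel count are dropped", {
  # grey mask with exactly 29 voxels: no sphere can reach 30 members
  mask <- array(FALSE, c(8L, 8L, 8L))
  mask[2:4, 2:4, 2:4] <- TRUE # 27 voxels
  mask[5, 2, 2] <- TRUE
  mask[5, 3, 2] <- TRUE        # 29 voxels total
  expect_error(build_spheres(mask, searchlight_spec(radius = 9,
                                                    min_voxels = 30L)),
               "at least 30")
  sl <- build_spheres(mask, searchlight_spec(radius = 9, min_voxels = 29L))
  expect_true(all(lengths(sl$members) == 29L))
})

test_that("sphere membership is symmetric inside the mask", {
  mask <- array(TRUE, c(6L, 6L, 6L))
  sl <- build_spheres(mask, searchlight_spec(radius = 3, min_voxels = 2L))
  stopifnot(length(sl$centers) == 216L)
  withr::with_seed(7L, picks <- sample(length(sl$centers), 30L))
  for (a in picks) {
    for (b in sl$members[[a]]) {
      bi <- match(b, sl$centers)
      expect_true(sl$centers[a] %in% sl$members[[bi]])
    }
  }
})

test_that("searchlight output at a center equals the ROI pipeline on its voxels", {
  route <- generate_route(seed = 42L)
  cfg <- tiny_sim_config(effect_size = -0.6, noise_sd = 0.3)
  subj <- simulate_subject(route, cfg, seed = 21L)
  model <- remembered_models(subj$behavior)$combined
  amask <- intersect_masks(subj$pre$mask, subj$post$mask)
  pp <- select_trial_volumes(regress_motion(subj$pre), subj$recipe, amask)
  pq <- select_trial_volumes(regress_motion(subj$post), subj$recipe, amask)
  sl <- build_spheres(amask, searchlight_spec(radius = 3, min_voxels = 10L))
  smap <- searchlight_map(pp, pq, model, sl)
  for (k in c(1L, 25L, 100L)) {
    roi_mask <- array(FALSE, dim(amask))
    roi_mask[sl$members[[k]]] <- TRUE
    pat_pre <- select_trial_volumes(regress_motion(subj$pre), subj$recipe,
                                    roi_mask)
    pat_post <- select_trial_volumes(regress_motion(subj$post), subj$recipe,
                                     roi_mask)
    psc <- ps_change(crosscorr_matrix(pat_pre), crosscorr_matrix(pat_post))
    rho <- model_correlation(psc, model)
    expect_identical(smap$values[sl$centers[k]], rho)
  }
})

test_that("the implanted gradient concentrates negative rho inside the effect ROI", {
  route <- generate_route(seed = 42L)
  cfg <- list(grid_dim = c(8L, 8L, 8L),
              effect_box = list(from = c(1L, 1L, 1L), to = c(4L, 4L, 4L)),
              control_box = list(from = c(5L, 5L, 5L), to = c(8L, 8L, 8L)),
              effect_size = -0.6, noise_sd = 0.2)
  subj <- simulate_subject(route, cfg, seed = 31L)
  model <- remembered_models(subj$behavior)$combined
  amask <- intersect_masks(subj$pre$mask, subj$post$mask)
  pp <- select_trial_volumes(regress_motion(subj$pre), subj$recipe, amask)
  pq <- select_trial_volumes(regress_motion(subj$post), subj$recipe, amask)
  sl <- build_spheres(amask, searchlight_spec(radius = 3, min_voxels = 10L))
  smap <- searchlight_map(pp, pq, model, sl)
  inside <- smap$values[subj$effect_roi & smap$valid]
  outside <- smap$values[subj$control_roi & smap$valid]
  expect_lt(mean(inside), mean(outside))
  expect_lt(mean(inside), -0.1)
  expect_lt(abs(mean(outside)), 0.1)
})

test_that("group max-statistic correction attains the exact flip bound", {
  # a voxel consistently and extremely negative in all 8 subjects can reach
  # a corrected p no smaller than 1 / 2^8: only the identity flip ties it
  dm <- c(4L, 4L, 1L)
  withr::with_seed(12L, {
    maps <- lapply(1:8, function(s) {
      vals <- array(rnorm(prod(dm), 0, 1), dm)
      vals[2, 2, 1] <- -3 + rnorm(1, 0, 0.005)
      structure(list(values = vals, valid = array(TRUE, dm), dim = dm),
                class = "stat_map")
    })
  })
  grp <- group_searchlight(maps, exact = TRUE)
  expect_equal(grp$p_corr_map[2, 2, 1], 1 / 256)
  expect_equal(which.min(grp$p_corr_map), 6L)
})

test_that("small-volume correction restricts the corrected map", {
  dm <- c(4L, 4L, 2L)
  withr::with_seed(9L, {
    maps <- lapply(1:6, function(s) {
      structure(list(values = array(rnorm(prod(dm)), dm),
                     valid = array(TRUE, dm), dim = dm),
                class = "stat_map")
    })
  })
  svc <- array(FALSE, dm)
  svc[1:2, 1:2, 1] <- TRUE
  grp <- group_searchlight(maps, n_flips = 200L, seed = 4L, svc_mask = svc)
  expect_equal(sum(!is.na(grp$p_corr_map)), 4L)
  expect_equal(sum(!is.na(grp$t_map)), prod(dm))
})

test_that("voxels not analysed in every subject are excluded and reported", {
  dm <- c(3L, 3L, 1L)
  mk <- function(drop) {
    v <- array(TRUE, dm)
    vals <- array(-0.2, dm)
    if (length(drop)) { v[drop] <- FALSE; vals[drop] <- NA }
    structure(list(values = vals, valid = v, dim = dm), class = "stat_map")
  }
  maps <- list(mk(integer()), mk(5L), mk(integer()))
  grp <- group_searchlight(maps, n_flips = 100L, seed = 1L)
  expect_equal(grp$n_excluded, 1L)
  expect_true(is.na(grp$t_map[5]))
})

test_that("family-wise error of the max-statistic correction is controlled", {
  dm <- c(4L, 4L, 2L)
  withr::with_seed(10L, {
    fw <- replicate(150, {
      maps <- lapply(1:10, function(s) {
        structure(list(values = array(rnorm(prod(dm)), dm),
                       valid = array(TRUE, dm), dim = dm),
                  class = "stat_map")
      })
      grp <- group_searchlight(maps, n_flips = 300L)
      min(grp$p_corr_map, na.rm = TRUE) < 0.05
    })
  })
  ci <- stats::binom.test(sum(fw), length(fw), 0.05)$conf.int
  expect_true(0.05 >= ci[1] && 0.05 <= ci[2])
})
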