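route <- generate_route(seed = 42L)
truth <- list(spatial = route_distances(route, "spatial"),
              temporal = route_distances(route, "temporal"))

test_that("rating accuracy is exact on perfect and reversed memories", {
  sp01 <- truth$spatial$pair_vector / max(truth$spatial$pair_vector)
  tm01 <- truth$temporal$pair_vector / max(truth$temporal$pair_vector)
  b <- behavior_from_ratings(sp01, tm01)
  acc <- rating_accuracy(b, truth)
  expect_equal(acc$r, c(1, 1))
  expect_true(all(acc$defined))
  # perfect anti-monotone linear map
  b2 <- behavior_from_ratings(1 - sp01, 1 - tm01)
  expect_equal(rating_accuracy(b2, truth)$r, c(-1, -1))
  # reversed ranks are negatively related
  b3 <- behavior_from_ratings(rank(-sp01) / 120, rank(-tm01) / 120)
  expect_true(all(rating_accuracy(b3, truth)$r < 0))
})

test_that("rating accuracy equals the closed-form Pearson on a 5-pair table", {
  # 4 objects -> 6 pairs; use a hand table of 6 values
  rated <- c(0.1, 0.3, 0.9, 0.4, 0.6, 0.2)
  actual_s <- c(3, 5, 4, 4, 5, 3)
  actual_t <- c(3, 7, 10, 4, 7, 3)
  r4 <- toy_route()
  tr <- list(spatial = route_distances(r4, "spatial"),
             temporal = route_distances(r4, "temporal"))
  b <- behavior_from_ratings(rated, rated)
  acc <- rating_accuracy(b, tr)
  hand <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      ((n - 1) * stats::sd(x) * stats::sd(y))
  }
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  expect_equal(acc$r[1], hand(zs(rated), zs(actual_s)))
  expect_equal(acc$r[2], hand(zs(rated), zs(actual_t)))
})

test_that("constant ratings are flagged undefined, not NaN", {
  b <- behavior_from_ratings(rep(0.5, 120), rep(0.2, 120))
  acc <- rating_accuracy(b, truth)
  expect_false(any(acc$defined))
  expect_true(all(is.na(acc$r)))
})

test_that("the two-predictor GLM recovers known mixtures exactly", {
  zs <- zscore(truth$spatial$pair_vector)
  zt <- zscore(truth$temporal$pair_vector)
  # orthogonalize the temporal predictor so coefficients read off directly
  zt_o <- zscore(residualize(zt, zs))
  beta <- rating_glm(as.numeric(zs), truth$spatial,
                     distance_model(pairvec_to_mat(zt_o - min(zt_o)),
                                    "temporal"))
  expect_equal(unname(beta), c(1, 0), tolerance = 1e-8)
  mix <- 0.5 * zs + 0.5 * zt_o
  beta2 <- rating_glm(as.numeric(mix), truth$spatial,
                      distance_model(pairvec_to_mat(zt_o - min(zt_o)),
                                     "temporal"))
  expect_equal(unname(beta2 * stats::sd(mix)), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("the GLM matches the normal-equations oracle on a random instance", {
  withr::with_seed(11L, {
    xs <- runif(10); xt <- runif(10); y <- runif(10)
  })
  ms <- distance_model(pairvec_to_mat(xs), "spatial")
  mt <- distance_model(pairvec_to_mat(xt), "temporal")
  beta <- rating_glm(y, ms, mt)
  X <- cbind(1, zscore(xs), zscore(xt))
  oracle <- solve(crossprod(X), crossprod(X, zscore(y)))[2:3]
  expect_equal(unname(beta), oracle)
})

test_that("collinear predictors are rejected", {
  x <- runif(6)
  ms <- distance_model(pairvec_to_mat(x), "spatial")
  mt <- distance_model(pairvec_to_mat(2 * x + 0.1), "temporal")
  expect_error(rating_glm(runif(6), ms, mt), "collinear")
})

test_that("error bias handles exact and degenerate cases", {
  sp01 <- truth$spatial$pair_vector / max(truth$spatial$pair_vector)
  tm <- truth$temporal$pair_vector
  # remembered == actual: errors all zero -> undefined
  b <- behavior_from_ratings(sp01, tm / max(tm))
  eb <- error_bias(b, "space", truth$spatial, truth$temporal)
  expect_false(eb$defined)
  # errors constructed as exactly -z(other distance): constant own-domain
  # truth makes the error -z(rating), and ratings proportional to the other
  # domain's distance give r = -1, which is capped and flagged
  const_truth <- distance_model(pairvec_to_mat(rep(5, 120)), "spatial")
  b2 <- behavior_from_ratings(tm / max(tm), tm / max(tm))
  eb2 <- error_bias(b2, "space", const_truth, truth$temporal)
  expect_equal(eb2$r, -1)
  expect_true(eb2$capped)
  expect_true(is.finite(eb2$fisher_z))
  expect_equal(eb2$fisher_z, atanh(-0.9999))
})

test_that("simulated cross-domain leakage produces a negative group error bias", {
  zs <- t(sapply(1:16, function(s) {
    b <- generate_behavior(route, list(cross_weight = c(space = 0.3,
                                                        time = 0.3)),
                           seed = 300L + s)
    c(error_bias(b, "space", truth$spatial, truth$temporal)$fisher_z,
      error_bias(b, "time", truth$temporal, truth$spatial)$fisher_z)
  }))
  t_space <- fisher_z_ttest(zs[, 1])
  t_time <- fisher_z_ttest(zs[, 2])
  expect_lt(t_space$t, 0)
  expect_lt(t_space$p, 0.05)
  expect_lt(t_time$t, 0)
})

test_that("error bias splits by test order with sufficient pairs per subset", {
  b <- generate_behavior(route, seed = 77L)
  eb <- error_bias(b, "space", truth$spatial, truth$temporal,
                   split_by_order = TRUE)
  expect_setequal(eb$subset, c("space_first", "time_first"))
  expect_true(all(eb$n >= 3))
  expect_true(all(eb$defined))
})

test_that("recall of the route order at equal durations tracks time perfectly", {
  n <- 8
  r <- route_design(cbind(seq(2, 9, 1), c(2, 8, 3, 7, 4, 6, 5, 2)),
                    segment_duration = rep(2, n - 1), map_side = 10)
  res <- recall_order_analysis(seq_len(n), route_distances(r, "spatial"),
                               route_distances(r, "temporal"))
  expect_equal(res$r_time, 1)
})

test_that("random recall orders average to zero correlation", {
  withr::with_seed(13L, {
    rs <- replicate(500, {
      res <- recall_order_analysis(sample(16L), truth$spatial,
                                   truth$temporal)
      c(res$r_space, res$r_time)
    })
  })
  expect_lt(abs(mean(rs[1, ])), 0.03)
  expect_lt(abs(mean(rs[2, ])), 0.03)
})

test_that("partial recall uses only recalled pairs and flags tiny sequences", {
  res <- recall_order_analysis(c(4L, 9L, 1L, 12L), truth$spatial,
                               truth$temporal)
  expect_equal(res$n_pairs, 6L)
  expect_true(res$defined)
  flagged <- recall_order_analysis(c(4L, 9L), truth$spatial, truth$temporal)
  expect_false(flagged$defined)
})

test_that("map error is the mean displacement ratio", {
  coords <- rbind(c(1, 1), c(5, 5), c(9, 1))
  resp <- data.frame(object = 1:3, x = coords[, 1], y = coords[, 2])
  expect_equal(map_error(resp, coords, 10), 0)
  shift <- data.frame(object = 1:3, x = coords[, 1] + 10, y = coords[, 2])
  expect_warning(ratio <- map_error(shift, coords, 10), "outside")
  expect_equal(ratio, 1)
  hand <- data.frame(object = 1:3, x = c(1, 8, 9), y = c(2, 9, 1))
  expect_equal(map_error(hand, coords, 10), mean(c(1, 5, 0)) / 10)
})

test_that("behavioral statistics ignore affine rescaling of raw distances", {
  b <- generate_behavior(route, seed = 55L)
  scaled <- list(
    spatial = distance_model(truth$spatial$values * 3 + 2 -
                               min(truth$spatial$values * 3 + 2, na.rm = TRUE),
                             "spatial"),
    temporal = distance_model(truth$temporal$values * 7, "temporal")
  )
  expect_equal(rating_accuracy(b, truth)$r, rating_accuracy(b, scaled)$r)
  expect_equal(
    unname(rating_glm(b$ratings[b$ratings$domain == "space", ],
                      truth$spatial, truth$temporal)),
    unname(rating_glm(b$ratings[b$ratings$domain == "space", ],
                      scaled$spatial, scaled$temporal)))
})
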