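test_that("block exclusion yields the expected combination counts", {
  withr::with_seed(1L, {
    pat <- patterns_from_base(matrix(rnorm(3 * 8), 3), n_rep = 3,
                              noise_sd = 0.5)
  })
  cc <- crosscorr_matrix(pat)
  # 3 blocks: cross-object ordered combinations 3^2 - 3 = 6, self C(3,2) = 3
  expect_true(all(cc$n_included[upper.tri(cc$n_included)] == 6))
  expect_true(all(diag(cc$n_included) == 3))
  # brute-force enumeration oracle over all trial pairs
  brute <- matrix(0, 3, 3)
  cnt <- matrix(0, 3, 3)
  for (o1 in 1:3) for (r1 in 1:3) for (o2 in 1:3) for (r2 in 1:3) {
    if (pat$blocks[o1, r1] == pat$blocks[o2, r2]) next
    brute[o1, o2] <- brute[o1, o2] + cor(pat$values[o1, r1, ],
                                         pat$values[o2, r2, ])
    cnt[o1, o2] <- cnt[o1, o2] + 1
  }
  expect_equal(cc$values, brute / cnt, ignore_attr = TRUE)
})

test_that("constant orthogonal patterns give unit diagonal and exact off-diagonal correlations", {
  base <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, -1, -1, 1))
  pat <- patterns_from_base(base, n_rep = 3)
  cc <- crosscorr_matrix(pat)
  expect_equal(diag(cc$values), rep(1, 3))
  expect_equal(cc$values[upper.tri(cc$values)], rep(0, 3))
})

test_that("a 16-object session yields a 16x16 matrix with the printed counts", {
  withr::with_seed(2L, {
    pat <- patterns_from_base(matrix(rnorm(16 * 10), 16), n_rep = 12,
                              noise_sd = 1)
  })
  cc <- crosscorr_matrix(pat)
  expect_equal(dim(cc$values), c(16L, 16L))
  expect_true(all(cc$n_included[upper.tri(cc$n_included)] == 132))
  expect_true(all(diag(cc$n_included) == 66))
})

test_that("Fisher-z averaging agrees with raw averaging for weak correlations", {
  withr::with_seed(21L, {
    pat <- patterns_from_base(matrix(rnorm(4 * 40), 4), n_rep = 3,
                              noise_sd = 3)
  })
  raw <- crosscorr_matrix(pat, average = "raw")
  fz <- crosscorr_matrix(pat, average = "fisher")
  off <- row(raw$values) != col(raw$values)
  expect_lt(max(abs(fz$values[off] - raw$values[off])), 0.02)
  # Fisher averaging weights extreme coefficients more strongly
  expect_false(identical(fz$values[off], raw$values[off]))
})

test_that("zero-variance trials are flagged and excluded from cell means", {
  withr::with_seed(3L, {
    pat <- patterns_from_base(matrix(rnorm(3 * 6), 3), n_rep = 3,
                              noise_sd = 0.5)
  })
  pat$values[1, 2, ] <- 7 # constant pattern in object 1, repetition 2
  expect_warning(cc <- crosscorr_matrix(pat), "zero-variance")
  expect_equal(cc$n_included[1, 2], 4) # 6 admissible minus 2 with bad trial
  expect_gt(sum(cc$n_excluded), 0)
  expect_true(all(is.finite(cc$values)))
})

test_that("PS' is the cell-wise post-minus-pre difference", {
  withr::with_seed(4L, {
    p1 <- patterns_from_base(matrix(rnorm(4 * 8), 4), n_rep = 2,
                             noise_sd = 0.5)
    p2 <- patterns_from_base(matrix(rnorm(4 * 8), 4), n_rep = 2,
                             noise_sd = 0.5)
  })
  pre <- crosscorr_matrix(p1, "pre")
  post <- crosscorr_matrix(p2, "post")
  psc <- ps_change(pre, post)
  expect_equal(psc$values, post$values - pre$values)
  expect_equal(psc$pair_vector, mat_to_pairvec(post$values - pre$values))
  same <- ps_change(pre, pre)
  expect_true(all(same$values == 0))
  shifted <- pre
  shifted$values <- pre$values + 0.2
  expect_equal(ps_change(pre, shifted)$values,
               matrix(0.2, 4, 4), ignore_attr = TRUE)
  bad <- post
  bad$object_ids <- c(2L, 3L, 4L, 5L)
  expect_error(ps_change(pre, bad), "different object sets")
})

test_that("the combined model is the cell-wise product on the rating scale", {
  sp <- pairvec_to_mat(c(0, 0.5, 1, 0.2, 0.8, 0.4))
  tm <- pairvec_to_mat(c(0.3, 0.5, 0.1, 1, 0.6, 0.9))
  cm <- combined_model(sp, tm)
  expect_equal(cm$pair_vector, c(0, 0.25, 0.1, 0.2, 0.48, 0.36))
  expect_equal(combined_model(sp, sp)$pair_vector, mat_to_pairvec(sp)^2)
  expect_error(combined_model(-sp, tm), "non-negative")
  # values above 1 are min-max normalized before the product
  big <- combined_model(sp * 10, tm)
  expect_equal(big$pair_vector, combined_model(sp, tm)$pair_vector)
})

test_that("the Spearman model fit has the exact boundary and oracle behavior", {
  withr::with_seed(5L, x <- rnorm(120))
  expect_equal(model_correlation(x, x), 1)
  expect_equal(model_correlation(x, exp(-3 * x)), -1)
  y6 <- c(2.5, 1.0, 4.0, 0.5, 3.0, 2.0)
  x6 <- c(0.1, 0.9, 0.4, 0.8, 0.2, 0.6)
  expect_equal(model_correlation(x6, y6), cor(rank(x6), rank(y6)))
  expect_warning(out <- model_correlation(rep(1, 6), y6), "constant")
  expect_true(is.na(out))
})

test_that("model fits are invariant under strictly monotone transforms", {
  withr::with_seed(6L, {
    for (k in 1:5) {
      x <- rnorm(30)
      y <- rnorm(30)
      r0 <- model_correlation(x, y)
      expect_equal(model_correlation(exp(x), y), r0)
      expect_equal(model_correlation(x, y^3 + 2 * y), r0)
    }
  })
})

test_that("exhaustive shuffle null matches full permutation enumeration", {
  x <- c(0.3, -0.2, 0.8, 0.1)
  y <- c(2, 1, 4, 3)
  sz <- subject_shuffle_z(x, y, exact = TRUE)
  perms <- eventmapr:::all_permutations(4L)
  oracle <- apply(perms, 1, function(p) cor(rank(x), rank(y[p])))
  expect_equal(sz$n_shuffles, 24L)
  expect_equal(sz$surrogate_mean, mean(oracle))
  expect_equal(sz$surrogate_sd, sd(oracle))
  expect_equal(sz$rho, cor(rank(x), rank(y)))
  expect_equal(sz$z, (sz$rho - mean(oracle)) / sd(oracle))
  expect_equal(sz$p_lower, mean(oracle <= sz$rho))
})

test_that("shuffle-null z is calibrated and its p uniform on null data", {
  withr::with_seed(7L, {
    out <- t(replicate(1000, {
      sz <- subject_shuffle_z(rnorm(120), runif(120), n_shuffles = 500L)
      c(sz$z, sz$p_lower)
    }))
  })
  expect_lt(abs(mean(out[, 1])), 0.05)
  expect_gt(sd(out[, 1]), 0.9)
  expect_lt(sd(out[, 1]), 1.1)
  ks <- suppressWarnings(stats::ks.test(out[, 2], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("shuffle-null requires sane inputs and a fixed seed reproduces it", {
  expect_error(subject_shuffle_z(rep(1, 10), 1:10, n_shuffles = 1000L),
               "constant")
  expect_error(subject_shuffle_z(rnorm(10), rnorm(10), n_shuffles = 50L),
               "at least 100")
  a <- subject_shuffle_z(sin(1:120), cos(1:120), n_shuffles = 500L, seed = 3L)
  b <- subject_shuffle_z(sin(1:120), cos(1:120), n_shuffles = 500L, seed = 3L)
  expect_identical(a$z, b$z)
})

test_that("residualization matches the normal-equations oracle", {
  y <- c(2.0, 3.5, 1.0, 4.0, 2.5)
  x <- c(0.5, 1.0, 0.2, 1.4, 0.9)
  X <- cbind(1, x)
  oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(residualize(y, x), as.vector(oracle))
  expect_equal(residualize(x, x), rep(0, 5))
  expect_error(residualize(y, rep(1, 5)), "constant covariate")
  # an exactly orthogonal covariate only removes the mean
  y2 <- c(1, 2, 3, 4)
  x2 <- c(1, -1, -1, 1) # cor(x2, y2) = 0
  expect_equal(residualize(y2, x2), y2 - mean(y2))
})

test_that("residualize-then-correlate behaves like a partial rank association", {
  withr::with_seed(8L, {
    z <- rnorm(200)
    x <- z + rnorm(200, 0, 0.5)  # model of interest
    c0 <- z + rnorm(200, 0, 0.5) # covariate
    y <- -x + 0.8 * c0 + rnorm(200, 0, 0.3)
  })
  raw <- model_correlation(y, x)
  part <- model_correlation(residualize(y, c0), residualize(x, c0))
  # removing the shared covariate strengthens the negative association
  expect_lt(part, raw)
  expect_lt(part, -0.8)
})
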