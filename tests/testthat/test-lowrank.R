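test_that("singular value thresholding matches its proximal definition", {
  set.seed(2)
  m <- matrix(rnorm(20), 5, 4)
  expect_equal(svt(m, 0), m, tolerance = 1e-10)
  expect_equal(svt(diag(c(3, 1)), 2), diag(c(1, 0)), tolerance = 1e-12)
  out <- svt(m, 0.5)
  expect_equal(svd(out)$d, pmax(svd(m)$d - 0.5, 0), tolerance = 1e-10)
})

test_that("L2,1 shrinkage scales columns by their norm surplus", {
  expect_equal(l21_shrink(matrix(c(3, 4), 2, 1), 1),
               matrix(c(2.4, 3.2), 2, 1))
  m <- cbind(c(0.3, 0.4), c(3, 4))   # first column norm 0.5 <= tau
  out <- l21_shrink(m, 1)
  expect_equal(out[, 1], c(0, 0))
  set.seed(3)
  m2 <- matrix(rnorm(12), 3)
  expect_equal(l21_shrink(m2, 0), m2)
  expect_equal(l21_shrink(cbind(m2, 0), 0.1)[, 5], c(0, 0, 0))
})

test_that("noiseless LRR recovers the shape-interaction matrix", {
  for (r in c(2, 4)) {
    a <- rand_lowrank(20, 30, r, seed = 40 + r)
    sol <- lrr_solve(a, lambda = 10)
    v <- svd(a)$v[, seq_len(r), drop = FALSE]
    expect_lt(max(abs(sol$X - v %*% t(v))), 1e-3)
    expect_lte(frob_(sol$E), 1e-4 * frob_(a))
    expect_true(sol$converged)
    # constraint conservation at convergence
    expect_lte(frob_(a - a %*% sol$X - sol$E) / max(1, frob_(a)),
               sol$settings$tol)
  }
})

test_that("a repeated single column yields a rank-one representation", {
  a <- matrix(rep(c(1, 2, -1), 6), 3)
  sol <- lrr_solve(a, lambda = 10)
  expect_lt(frob_(sol$denoised - a) / frob_(a), 1e-5)
  sv <- svd(sol$X)$d
  expect_gt(sv[1]^2 / sum(sv^2), 0.999)
})

test_that("lambda trades the error term against the coefficient rank", {
  a <- rand_lowrank(15, 25, 3, seed = 50) + matrix(rnorm(15 * 25, sd = 0.05), 15)
  sols <- lapply(c(1e-4, 0.05, 10),
                 function(l) suppressWarnings(lrr_solve(a, lambda = l)))
  e_norms <- vapply(sols, function(s) frob_(s$E), 1)
  nuc <- vapply(sols, function(s) sum(svd(s$X)$d), 1)
  # larger lambda: smaller corruption term, richer coefficient matrix
  expect_true(all(diff(e_norms) < 0))
  expect_true(all(diff(nuc) > 0))
  expect_lt(e_norms[3] / frob_(a), 1e-2)           # lambda large: E ~ 0
  expect_gt(e_norms[1] / frob_(a), 0.3)            # lambda small: E absorbs A
})

test_that("the residual trace decreases after burn-in", {
  a <- rand_lowrank(15, 25, 3, seed = 51) + matrix(rnorm(15 * 25, sd = 0.1), 15)
  sol <- suppressWarnings(lrr_solve(a, lambda = 0.2))
  res <- sol$trace$residual
  half <- ceiling(length(res) / 2)
  expect_lte(res[length(res)], res[half])
})

test_that("lrr_solve validates its inputs", {
  a <- matrix(rnorm(12), 3)
  expect_error(lrr_solve(a, lambda = -1), "positive")
  a[1, 1] <- NA
  expect_error(lrr_solve(a), "impute")
})

test_that("tuned lambda localizes column-sparse corruption", {
  d <- simulate_multimodal(sim_config(n_per_class = 50, n_classes = 2,
                                      modality_dims = c(40), latent_rank = 5,
                                      noise_sd = 0.3, corrupt_frac = 0.1,
                                      corrupt_sd = 3, missing_frac = 0,
                                      seed = 61))
  a <- d$modalities[[1]]
  cc <- d$ground_truth$corrupt_cols[[1]]
  tune <- lrr_tune_lambda(a)
  nrm <- sqrt(colSums(tune$solution$E^2))
  top <- order(nrm, decreasing = TRUE)[seq_along(cc)]
  expect_gte(length(intersect(top, cc)) / length(cc), 0.8)
})

test_that("denoising preserves shapes and improves corrupted reconstructions", {
  # zero-noise dataset: nothing to remove
  d0 <- simulate_multimodal(sim_config(n_per_class = 15, n_classes = 2,
                                       modality_dims = c(10, 3), latent_rank = 3,
                                       noise_sd = 0, corrupt_frac = 0,
                                       missing_frac = 0, seed = 70))
  dn0 <- denoise_modalities(d0, lambda = 10)
  for (m in seq_along(dn0$modalities)) {
    expect_lt(frob_(dn0$modalities[[m]] - d0$modalities[[m]]) /
                frob_(d0$modalities[[m]]), 1e-3)
    expect_identical(dim(dn0$modalities[[m]]), dim(d0$modalities[[m]]))
  }
  # corrupted dataset: denoised is closer to the clean signal than observed
  d1 <- simulate_multimodal(sim_config(n_per_class = 30, n_classes = 2,
                                       modality_dims = c(30, 3), latent_rank = 4,
                                       noise_sd = 0.3, corrupt_frac = 0.1,
                                       corrupt_sd = 3, missing_frac = 0,
                                       seed = 71))
  dn1 <- suppressWarnings(denoise_modalities(d1, lambda = 0.02))
  for (m in seq_along(dn1$modalities)) {
    expect_lt(frob_(dn1$modalities[[m]] - d1$ground_truth$clean[[m]]),
              frob_(d1$modalities[[m]] - d1$ground_truth$clean[[m]]))
  }
  # a 3-feature (CSF-like) modality runs and keeps its 3 x n shape
  expect_identical(dim(dn1$modalities[[2]]), c(3L, 60L))
  # missing entries must be imputed first, and the message names the modality
  d1$modalities[[1]][1, 1] <- NA
  expect_error(denoise_modalities(d1), "modality")
})
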