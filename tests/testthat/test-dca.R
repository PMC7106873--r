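test_that("between-class scatter matches the hand-computed example", {
  a <- cbind(c(0, 0), c(2, 0), c(4, 0), c(6, 0))
  labels <- factor(c(1, 1, 2, 2))
  bcs <- between_class_scatter(a, labels)
  expect_equal(bcs$grand_mean, c(3, 0))
  expect_equal(unname(bcs$phi),
               cbind(sqrt(2) * c(-2, 0), sqrt(2) * c(2, 0)))
  expect_equal(unname(bcs$s_inter), rbind(c(16, 0), c(0, 0)))
})

test_that("between-class scatter is symmetric PSD with rank below c", {
  set.seed(12)
  for (i in 1:5) {
    c_ <- sample(2:4, 1)
    inst <- rand_discriminative(6, 4, 36, c_, seed = 100 + i)
    s <- between_class_scatter(inst$a, inst$labels)$s_inter
    expect_equal(s, t(s))
    ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_lte(sum(ev > 1e-10 * max(ev)), c_ - 1)
  }
  # identical class means -> zero scatter
  a <- cbind(c(1, 2), c(3, 0), c(1, 2), c(3, 0))
  s0 <- between_class_scatter(a, factor(c(1, 1, 2, 2)))$s_inter
  expect_equal(s0, matrix(0, 2, 2))
  expect_error(between_class_scatter(a, factor(rep(1, 4))), "2 classes")
})

test_that("unitization makes the transformed scatter the identity", {
  a <- cbind(c(0, 0), c(2, 0), c(4, 0), c(6, 0))
  bcs <- between_class_scatter(a, factor(c(1, 1, 2, 2)))
  u <- unitize_scatter(bcs$phi)
  expect_equal(ncol(u$w_inter), 1L)
  expect_identity_matrix(t(u$w_inter) %*% bcs$s_inter %*% u$w_inter, 1e-10)

  # orthogonal equal-norm deviation columns give r = 2 and exact identity
  phi <- cbind(c(3, 0, 0), c(0, 3, 0))
  u2 <- unitize_scatter(phi)
  expect_equal(ncol(u2$w_inter), 2L)
  expect_identity_matrix(t(u2$w_inter) %*% tcrossprod(phi) %*% u2$w_inter, 1e-10)

  # scale invariance: scaling phi leaves r and the identity intact
  u3 <- unitize_scatter(10 * phi)
  expect_equal(ncol(u3$w_inter), 2L)
  expect_identity_matrix(t(u3$w_inter) %*% tcrossprod(10 * phi) %*% u3$w_inter,
                         1e-10)

  expect_error(unitize_scatter(matrix(0, 3, 2)), "no discriminative")
})

test_that("dca_fit satisfies its algebraic identities", {
  inst <- rand_discriminative(8, 5, 40, 3, seed = 200)
  fit <- dca_fit(inst$a, inst$b, inst$labels)
  expect_lte(fit$r, 2)   # c - 1 cap

  # transformed between-set cross matrix is the identity
  ac <- inst$a - rowMeans(inst$a)
  bc <- inst$b - rowMeans(inst$b)
  cross <- (fit$w_a %*% ac) %*% t(fit$w_b %*% bc)
  expect_identity_matrix(cross, 1e-8)

  # the projected between-class scatter is diagonal (inverse cross spectrum)
  s_a <- between_class_scatter(inst$a, inst$labels)$s_inter
  proj <- fit$w_a %*% s_a %*% t(fit$w_a)
  off <- proj - diag(diag(proj))
  expect_lt(max(abs(off)), 1e-8)
  expect_equal(diag(proj), 1 / fit$singular_values, tolerance = 1e-8)

  # identical feature sets are a valid degenerate input
  fit_same <- dca_fit(inst$a, inst$a, inst$labels)
  cross_same <- (fit_same$w_a %*% ac) %*% t(fit_same$w_b %*% ac)
  expect_identity_matrix(cross_same, 1e-8)
})

test_that("dca_transform is a pure columnwise linear projection", {
  inst <- rand_discriminative(6, 4, 30, 2, seed = 300)
  fit <- dca_fit(inst$a, inst$b, inst$labels)
  tr <- dca_transform(fit, inst$a, inst$b)
  expect_identical(dim(tr$astar), c(fit$r, 30L))
  # zero input -> zero output
  z <- dca_transform(fit, matrix(0, 6, 3), matrix(0, 4, 3))
  expect_equal(z$astar, matrix(0, fit$r, 3))
  # held-out columns transform independently
  sub <- dca_transform(fit, inst$a[, 1:5], inst$b[, 1:5])
  expect_equal(sub$astar, tr$astar[, 1:5, drop = FALSE])
  expect_error(dca_transform(fit, inst$b, inst$a), "expected")
})

test_that("adding a constant vector to every sample leaves the transform unchanged", {
  inst <- rand_discriminative(5, 4, 24, 3, seed = 400)
  fit1 <- dca_fit(inst$a, inst$b, inst$labels)
  shift <- matrix(rnorm(5), 5, 24)
  shift[] <- rnorm(5)   # same vector in every column
  fit2 <- dca_fit(inst$a + shift, inst$b, inst$labels)
  expect_equal(fit1$w_a, fit2$w_a, tolerance = 1e-8)
  expect_equal(fit1$w_b, fit2$w_b, tolerance = 1e-8)
})

test_that("fuse_pair stacks or sums aligned projections", {
  a <- matrix(1:3, 1); b <- matrix(4:6, 1)
  fz <- fuse_pair(a, b)
  expect_identical(dim(fz$values), c(2L, 3L))
  expect_equal(fuse_pair(a, -a, mode = "sum")$values, matrix(0, 1, 3))
  # concat then split recovers both inputs
  expect_equal(fz$values[1, , drop = FALSE], a)
  expect_equal(fz$values[2, , drop = FALSE], b)
  expect_error(fuse_pair(a, matrix(1:4, 1)), "mismatch")
})

test_that("multimodal fusion cascades pairwise DCA with capped dimension", {
  inst <- rand_discriminative(8, 6, 36, 2, seed = 500)
  # base case: two matrices reduce to a single fuse_pair of a single dca_fit
  fz <- fuse_multimodal(list(a = inst$a, b = inst$b), inst$labels)
  fit <- dca_fit(inst$a, inst$b, inst$labels)
  tr <- dca_transform(fit, inst$a, inst$b)
  expect_equal(fz$values, fuse_pair(tr$astar, tr$bstar)$values)

  # three modalities at the study's feature counts: fused rows <= 2(c-1)
  d <- simulate_multimodal(sim_config(n_per_class = 20, n_classes = 3,
                                      modality_dims = c(93, 93, 3),
                                      corrupt_frac = 0, missing_frac = 0,
                                      seed = 501))
  fz3 <- fuse_multimodal(d$modalities, d$labels)
  expect_lte(nrow(fz3$values), 2 * (3 - 1))
  expect_equal(fz3$provenance$sources, c("MRI", "PET", "CSF"))

  # permuting samples (with labels) permutes output columns identically
  perm <- sample(36)
  fzp <- fuse_multimodal(list(a = inst$a[, perm], b = inst$b[, perm]),
                         inst$labels[perm])
  expect_equal(fzp$values, fz$values[, perm], tolerance = 1e-8)
})

test_that("regularized CCA behaves like canonical correlation analysis", {
  set.seed(600)
  a <- matrix(rnorm(5 * 60), 5)
  fz <- cca_fuse(a, a + 1e-8 * matrix(rnorm(300), 5), ridge = 1e-6)
  expect_gte(attr(fz, "cca")$cors[1], 0.999)

  # independent sets at n >> p: all canonical correlations small
  set.seed(601)
  x <- matrix(rnorm(5 * 500), 5); y <- matrix(rnorm(5 * 500), 5)
  fz2 <- cca_fuse(x, y, ridge = 1e-6)
  cors <- attr(fz2, "cca")$cors
  expect_lt(max(cors), 0.3)
  expect_true(all(diff(cors) <= 1e-12))
  expect_true(all(cors >= 0 & cors <= 1))

  # agreement with the classical solver on a well-conditioned instance
  set.seed(602)
  x3 <- matrix(rnorm(4 * 200), 4); y3 <- matrix(rnorm(3 * 200), 3)
  y3[1, ] <- y3[1, ] + 0.8 * x3[2, ]
  ref <- stats::cancor(t(x3), t(y3))
  fz3 <- cca_fuse(x3, y3, ridge = 0)
  expect_equal(attr(fz3, "cca")$cors[seq_along(ref$cor)], ref$cor,
               tolerance = 1e-3)

  expect_error(cca_fuse(rbind(x, x), y, ridge = 0), "ridge")
})
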