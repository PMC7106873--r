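# Shared fixture builders (everything is generated in code).

# Noiseless rank-r matrix with well-spread singular values.
rand_lowrank <- function(d, n, r, seed = 1) {
  set.seed(seed)
  matrix(rnorm(d * r), d) %*% matrix(rnorm(r * n), r)
}

# Exactly rank-r matrix with prescribed singular values (orthonormal factors).
rank_r_matrix <- function(d, n, sv, seed = 1) {
  set.seed(seed)
  qa <- qr.Q(qr(matrix(rnorm(d * length(sv)), d)))
  qb <- qr.Q(qr(matrix(rnorm(n * length(sv)), n)))
  qa %*% (sv * t(qb))
}

# Small class-structured feature pair for DCA tests.
rand_discriminative <- function(p, q, n, c, seed = 1, sep = 1) {
  set.seed(seed)
  labels <- factor(rep(seq_len(c), length.out = n))
  shift_a <- matrix(rnorm(p * c, sd = sep), p)
  shift_b <- matrix(rnorm(q * c, sd = sep), q)
  list(a = matrix(rnorm(p * n), p) + shift_a[, as.integer(labels)],
       b = matrix(rnorm(q * n), q) + shift_b[, as.integer(labels)],
       labels = labels)
}

frob_ <- function(m) sqrt(sum(m^2))

expect_identity_matrix <- function(m, tol) {
  expect_lt(max(abs(m - diag(nrow(m)))), tol)
}
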