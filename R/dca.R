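# Discriminant correlation analysis (DCA): class-aware feature-level fusion
# of two aligned feature sets. Each set's between-class scatter
# S_inter = Phi Phi' (Phi columns are sqrt(m_j)-weighted class-mean
# deviations) is unitized -- W_inter' S_inter W_inter = I -- then the
# transformed between-set cross matrix is diagonalized by SVD so the two
# projected sets are pairwise correlated, and the projections are stacked
# (series concatenation). A regularized CCA baseline is included.

# Flip signs so the largest-magnitude entry of each column is positive
# (deterministic factors across platforms). Returns the sign vector.
column_signs <- function(u) {
  apply(u, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
}

#' Between-class scatter of a feature set
#'
#' Computes \eqn{\Phi = [\sqrt{m_1}(\bar a_1 - \bar a), \dots,
#' \sqrt{m_c}(\bar a_c - \bar a)]} (class-mean deviations from the grand mean,
#' weighted by the square root of class sizes) and the scatter
#' \eqn{S_{inter} = \Phi \Phi^T}, a symmetric positive-semidefinite matrix of
#' rank at most c - 1.
#'
#' @param a numeric matrix, features x samples.
#' @param labels factor of class labels, length `ncol(a)`, >= 2 classes.
#' @param weighted if `FALSE`, drop the sqrt(class size) weights (exposed
#'   because the weighting convention differs across the DCA literature).
#' @return List with `phi` (p x c), `s_inter` (p x p), `class_means` (p x c),
#'   `grand_mean` (length p).
#' @export
between_class_scatter <- function(a, labels, weighted = TRUE) {
  a <- as.matrix(a)
  labels <- as.factor(droplevels(labels))
  if (length(labels) != ncol(a)) data_error("labels length must equal ncol(a)")
  if (nlevels(labels) < 2L) {
    data_error("between-class scatter needs at least 2 classes")
  }
  grand <- rowMeans(a)
  cm <- vapply(levels(labels), function(l) {
    rowMeans(a[, labels == l, drop = FALSE])
  }, numeric(nrow(a)))
  cm <- matrix(cm, nrow = nrow(a),
               dimnames = list(rownames(a), levels(labels)))
  m <- as.numeric(table(labels))
  w <- if (weighted) sqrt(m) else rep(1, length(m))
  phi <- sweep(cm - grand, 2, w, `*`)
  list(phi = phi, s_inter = tcrossprod(phi), class_means = cm,
       grand_mean = grand)
}

#' Unitize a between-class scatter
#'
#' Finds \eqn{W_{inter}} with \eqn{W_{inter}^T (\Phi\Phi^T) W_{inter} = I_r}
#' via the eigendecomposition of the small c x c matrix \eqn{\Phi^T\Phi}:
#' eigenpairs with eigenvalue above `energy_tol` times the largest are kept
#' and \eqn{W_{inter} = \Phi Q \Lambda^{-1}}, which satisfies the identity
#' exactly.
#'
#' @param phi p x c matrix of weighted class-mean deviations.
#' @param energy_tol relative eigenvalue cutoff (drop numerically-zero
#'   discriminative directions).
#' @return List with `w_inter` (p x r) and `eigvals` (length r).
#' @export
unitize_scatter <- function(phi, energy_tol = 1e-8) {
  phi <- as.matrix(phi)
  g <- crossprod(phi)
  eg <- eigen(g, symmetric = TRUE)
  keep <- eg$values > energy_tol * max(eg$values, 0) & eg$values > 0
  if (!any(keep)) {
    numerical_error("no discriminative directions: between-class scatter is zero")
  }
  q <- eg$vectors[, keep, drop = FALSE]
  q <- sweep(q, 2, column_signs(q), `*`)
  vals <- eg$values[keep]
  w_inter <- phi %*% sweep(q, 2, vals, `/`)   # Phi Q Lambda^{-1}
  list(w_inter = w_inter, eigvals = vals)
}

#' Fit a discriminant correlation analysis transform for two feature sets
#'
#' Unitizes each set's between-class scatter, forms the transformed
#' between-set cross matrix \eqn{S'_{ab} = A' B'^T} from the centered,
#' unitized projections, diagonalizes it by SVD and scales by
#' \eqn{\Sigma^{-1/2}} on both sides so the transformed cross matrix is the
#' identity. The final projections are \eqn{W_a = W_{ca}^T W_{intera}^T} and
#' \eqn{W_b = W_{cb}^T W_{interb}^T}, each r x (input dim), with
#' r <= c - 1.
#'
#' @param a,b aligned feature sets (p x n and q x n, same samples).
#' @param labels class factor of length n.
#' @param energy_tol relative eigen/singular value cutoff.
#' @param weighted passed to [between_class_scatter()].
#' @return Object of class `dca`: projections `w_a` (r x p), `w_b` (r x q),
#'   effective dimension `r`, singular values of the transformed cross
#'   matrix, per-set scatter eigenvalues, class/grand means.
#' @export
dca_fit <- function(a, b, labels, energy_tol = 1e-8, weighted = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) data_error("'a' and 'b' must share sample columns")
  if (anyNA(a) || anyNA(b)) data_error("inputs must have no missing entries")
  bcs_a <- between_class_scatter(a, labels, weighted)
  bcs_b <- between_class_scatter(b, labels, weighted)
  ua <- unitize_scatter(bcs_a$phi, energy_tol)
  ub <- unitize_scatter(bcs_b$phi, energy_tol)
  ac <- a - bcs_a$grand_mean
  bc <- b - bcs_b$grand_mean
  a1 <- crossprod(ua$w_inter, ac)   # r_a x n
  b1 <- crossprod(ub$w_inter, bc)   # r_b x n
  s_ab <- tcrossprod(a1, b1)
  sv <- svd(s_ab)
  keep <- sv$d > energy_tol * max(sv$d, 0) & sv$d > 0
  if (!any(keep)) {
    numerical_error("feature sets share no between-class correlation")
  }
  r <- sum(keep)
  sgn <- column_signs(sv$u[, keep, drop = FALSE])
  u <- sweep(sv$u[, keep, drop = FALSE], 2, sgn, `*`)
  v <- sweep(sv$v[, keep, drop = FALSE], 2, sgn, `*`)
  d <- sv$d[keep]
  w_ca <- sweep(u, 2, sqrt(d), `/`)   # U Sigma^{-1/2}
  w_cb <- sweep(v, 2, sqrt(d), `/`)
  structure(list(
    w_a = crossprod(w_ca, t(ua$w_inter)),   # r x p
    w_b = crossprod(w_cb, t(ub$w_inter)),   # r x q
    r = r, singular_values = d,
    eigvals_a = ua$eigvals, eigvals_b = ub$eigvals,
    class_means_a = bcs_a$class_means, class_means_b = bcs_b$class_means,
    grand_mean_a = bcs_a$grand_mean, grand_mean_b = bcs_b$grand_mean,
    p = nrow(a), q = nrow(b), levels = levels(as.factor(droplevels(labels)))
  ), class = "dca")
}

#' @export
print.dca <- function(x, ...) {
  cat(sprintf("DCA transform: %d- and %d-feature inputs -> r = %d per set\n",
              x$p, x$q, x$r))
  invisible(x)
}

#' Apply a fitted DCA transform
#'
#' Pure linear projection \eqn{A^* = W_a A}, \eqn{B^* = W_b B}; no refitting,
#' so held-out samples transform columnwise independently.
#'
#' @param transform a fitted [dca_fit()] object.
#' @param a,b matrices with the fitted feature dimensions.
#' @return List with `astar` and `bstar`, each r x n.
#' @export
dca_transform <- function(transform, a, b) {
  stopifnot(inherits(transform, "dca"))
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != transform$p) {
    data_error(sprintf("'a': expected %d rows, got %d", transform$p, nrow(a)))
  }
  if (nrow(b) != transform$q) {
    data_error(sprintf("'b': expected %d rows, got %d", transform$q, nrow(b)))
  }
  list(astar = transform$w_a %*% a, bstar = transform$w_b %*% b)
}

new_fused_matrix <- function(values, provenance) {
  structure(list(values = values, provenance = provenance),
            class = "fused_matrix")
}

#' @export
as.matrix.fused_matrix <- function(x, ...) x$values

#' @export
print.fused_matrix <- function(x, ...) {
  cat(sprintf("Fused matrix: %d x %d (%s)\n", nrow(x$values), ncol(x$values),
              paste(x$provenance$sources, collapse = " + ")))
  invisible(x)
}

#' Combine two transformed feature sets
#'
#' `mode = "concat"` stacks the rows (series concatenation, giving 2r
#' features); `mode = "sum"` adds them elementwise (r features).
#'
#' @param astar,bstar matrices with equal column counts.
#' @param mode `"concat"` (default) or `"sum"`.
#' @param sources character names recorded in the provenance.
#' @return A `fused_matrix`.
#' @export
fuse_pair <- function(astar, bstar, mode = c("concat", "sum"),
                      sources = c("a", "b")) {
  mode <- match.arg(mode)
  astar <- as.matrix(astar); bstar <- as.matrix(bstar)
  if (ncol(astar) != ncol(bstar)) {
    data_error(sprintf("column mismatch: %d vs %d", ncol(astar), ncol(bstar)))
  }
  values <- if (mode == "concat") rbind(astar, bstar) else {
    if (nrow(astar) != nrow(bstar)) {
      data_error("'sum' mode needs equal row counts")
    }
    astar + bstar
  }
  new_fused_matrix(values, list(sources = sources, mode = mode,
                                r = c(nrow(astar), nrow(bstar))))
}

# Fit a left-fold DCA cascade over >= 2 modalities: stage i fuses the running
# fused matrix with the next modality. Returns the fitted stages so held-out
# samples can be pushed through the same transforms.
dca_cascade_fit <- function(mats, labels, energy_tol = 1e-8,
                            mode = "concat", weighted = TRUE) {
  if (length(mats) < 2L) data_error("need at least 2 matrices to fuse")
  if (is.null(names(mats))) names(mats) <- paste0("set", seq_along(mats))
  fits <- vector("list", length(mats) - 1L)
  current <- as.matrix(mats[[1L]])
  stage_r <- integer(0)
  for (i in seq_len(length(mats) - 1L)) {
    nxt <- as.matrix(mats[[i + 1L]])
    fit <- dca_fit(current, nxt, labels, energy_tol, weighted)
    tr <- dca_transform(fit, current, nxt)
    current <- fuse_pair(tr$astar, tr$bstar, mode)$values
    fits[[i]] <- fit
    stage_r <- c(stage_r, fit$r)
  }
  structure(list(fits = fits, mode = mode, order = names(mats),
                 stage_r = stage_r),
            class = "dca_cascade")
}

dca_cascade_transform <- function(cascade, mats) {
  stopifnot(inherits(cascade, "dca_cascade"))
  current <- as.matrix(mats[[1L]])
  for (i in seq_along(cascade$fits)) {
    tr <- dca_transform(cascade$fits[[i]], current, as.matrix(mats[[i + 1L]]))
    current <- fuse_pair(tr$astar, tr$bstar, cascade$mode)$values
  }
  current
}

#' Fuse two or more aligned feature sets by cascaded DCA
#'
#' Pairs are fused by a left fold in the order given -- fuse(fuse(M1, M2), M3)
#' and so on -- each stage fitting a fresh [dca_fit()] on the running fused
#' matrix and the next set. Each stage caps the per-set dimension at c - 1,
#' so the final fused dimension is at most 2(c - 1) under concatenation.
#'
#' @param mats named list of >= 2 aligned matrices (features x samples).
#' @param labels class factor.
#' @param energy_tol,weighted passed to [dca_fit()].
#' @param mode passed to [fuse_pair()].
#' @return A `fused_matrix`; the fitted cascade is attached as attribute
#'   `"cascade"` so new samples can be transformed.
#' @export
fuse_multimodal <- function(mats, labels, energy_tol = 1e-8,
                            mode = c("concat", "sum"), weighted = TRUE) {
  mode <- match.arg(mode)
  cascade <- dca_cascade_fit(mats, labels, energy_tol, mode, weighted)
  values <- dca_cascade_transform(cascade, mats)
  out <- new_fused_matrix(values, list(sources = cascade$order, mode = mode,
                                       r = cascade$stage_r))
  attr(out, "cascade") <- cascade
  out
}

#' Regularized canonical correlation analysis fusion (baseline)
#'
#' Classical CCA on two centered feature sets, solved by whitening the
#' within-set covariances (with a relative ridge so p or q may exceed n) and
#' taking the SVD of the whitened cross-covariance. The canonical projections
#' of both sets are concatenated in series.
#'
#' @param a,b aligned feature sets (p x n, q x n).
#' @param n_components number of canonical pairs (default
#'   `min(p, q, n - 1)`).
#' @param ridge relative ridge added to each within-set covariance
#'   (`ridge * mean(diag(C))`); must be > 0 when a covariance is singular.
#' @return A `fused_matrix` whose provenance records the canonical
#'   correlations; the fitted projections and centers are attached as
#'   attribute `"cca"`.
#' @export
cca_fuse <- function(a, b, n_components = NULL, ridge = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) data_error("'a' and 'b' must share sample columns")
  n <- ncol(a); p <- nrow(a); q <- nrow(b)
  kmax <- min(p, q, n - 1L)
  k <- as.integer(n_components %||% kmax)
  if (k < 1L || k > kmax) {
    config_error(sprintf("'n_components' must be in [1, %d]", kmax))
  }
  ma <- rowMeans(a); mb <- rowMeans(b)
  ac <- a - ma; bc <- b - mb
  caa <- tcrossprod(ac) / (n - 1)
  cbb <- tcrossprod(bc) / (n - 1)
  cab <- tcrossprod(ac, bc) / (n - 1)
  inv_sqrt <- function(cmat, label) {
    eg <- eigen(cmat, symmetric = TRUE)
    tol <- 1e-10 * max(eg$values, 0)
    if (any(eg$values <= tol)) {
      if (ridge <= 0) {
        numerical_error(sprintf(
          "within-set covariance of '%s' is ill-conditioned; use ridge > 0", label))
      }
      cmat <- cmat + diag(ridge * mean(diag(cmat)), nrow(cmat))
      eg <- eigen(cmat, symmetric = TRUE)
    }
    eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  }
  wa_half <- inv_sqrt(caa, "a")
  wb_half <- inv_sqrt(cbb, "b")
  sv <- svd(wa_half %*% cab %*% wb_half)
  sgn <- column_signs(sv$u[, seq_len(k), drop = FALSE])
  u <- sweep(sv$u[, seq_len(k), drop = FALSE], 2, sgn, `*`)
  v <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, sgn, `*`)
  cors <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  wx <- wa_half %*% u   # p x k
  wy <- wb_half %*% v
  values <- rbind(crossprod(wx, ac), crossprod(wy, bc))
  out <- new_fused_matrix(values, list(sources = c("a", "b"), mode = "cca",
                                       r = c(k, k), correlations = cors))
  attr(out, "cca") <- list(wx = wx, wy = wy, ma = ma, mb = mb, cors = cors)
  out
}

cca_apply <- function(cca, a, b) {
  rbind(crossprod(cca$wx, as.matrix(a) - cca$ma),
        crossprod(cca$wy, as.matrix(b) - cca$mb))
}
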