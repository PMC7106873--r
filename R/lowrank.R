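# Low-rank representation (LRR): decompose a fully observed modality matrix A
# as A = A X + E, where X is the low-rank self-expressive coefficient matrix
# (nuclear-norm penalized) and E collects column-sparse gross corruption
# (L2,1-norm penalized):
#
#     min_{X,E}  ||X||_*  +  lambda ||E||_{2,1}   s.t.  A = A X + E.
#
# Solved by inexact ALM with the standard auxiliary splitting J = X: alternate
# a singular-value-thresholding update of J, a closed-form least-squares
# update of X, an L2,1 column-shrinkage update of E, then multiplier/penalty
# updates. The denoised modality is A X.

svt_internal <- function(m, tau) {
  sv <- svd(m)
  keep <- pmax(sv$d - tau, 0)
  nz <- keep > 0
  out <- if (!any(nz)) {
    matrix(0, nrow(m), ncol(m))
  } else {
    sv$u[, nz, drop = FALSE] %*% (keep[nz] * t(sv$v[, nz, drop = FALSE]))
  }
  list(mat = out, nuclear = sum(keep))
}

#' Singular value thresholding (proximal operator of the nuclear norm)
#'
#' Returns \eqn{U \, \max(\Sigma - \tau, 0) \, V^T} for the SVD
#' \eqn{M = U \Sigma V^T}.
#'
#' @param m numeric matrix.
#' @param tau threshold, >= 0.
#' @return Matrix of the same shape with singular values shrunk by `tau`.
#' @examples
#' svt(diag(c(3, 1)), 2)   # diag(1, 0)
#' @export
svt <- function(m, tau) {
  check_scalar(tau, "tau", lower = 0)
  svt_internal(as.matrix(m), tau)$mat
}

#' Column-wise L2,1 shrinkage (proximal operator of the L2,1 norm)
#'
#' Scales each column by \eqn{\max(0, (\|c\|_2 - \tau)/\|c\|_2)}; columns with
#' norm at most `tau` become zero.
#'
#' @inheritParams svt
#' @return Matrix of the same shape.
#' @examples
#' l21_shrink(matrix(c(3, 4), 2, 1), 1)  # (2.4, 3.2)
#' @export
l21_shrink <- function(m, tau) {
  m <- as.matrix(m)
  check_scalar(tau, "tau", lower = 0)
  nrm <- col_norms(m)
  scale <- ifelse(nrm > tau, (nrm - tau) / nrm, 0)
  scale[nrm == 0] <- 0
  sweep(m, 2, scale, `*`)
}

#' Solver settings for [lrr_solve()]
#'
#' @param tol relative stopping tolerance on the constraint residual
#'   \eqn{\|A - AX - E\|_F / \max(1, \|A\|_F)} and on the splitting gap.
#' @param max_iter iteration cap.
#' @param mu0 initial ALM penalty.
#' @param rho penalty growth factor (> 1).
#' @param mu_max penalty cap.
#' @return List of class `lrr_settings`.
#' @export
lrr_settings <- function(tol = 1e-6, max_iter = 500, mu0 = 1e-2, rho = 1.1,
                         mu_max = 1e6) {
  check_scalar(tol, "tol", lower = 1e-300)
  check_scalar(max_iter, "max_iter", lower = 1, integer = TRUE)
  check_scalar(mu0, "mu0", lower = 1e-300)
  if (rho <= 1) config_error("'rho' must be > 1")
  check_scalar(mu_max, "mu_max", lower = mu0)
  structure(list(tol = tol, max_iter = as.integer(max_iter), mu0 = mu0,
                 rho = rho, mu_max = mu_max), class = "lrr_settings")
}

#' Solve the low-rank representation program
#'
#' Minimizes \eqn{\|X\|_* + \lambda \|E\|_{2,1}} subject to
#' \eqn{A = D X + E} by inexact ALM with auxiliary splitting \eqn{J = X}.
#' By default the dictionary `D` is `A` itself (self-expressive LRR); passing
#' a training matrix as `dict` represents new columns in the training sample
#' basis, which is how held-out samples are denoised inside cross-validation.
#'
#' On a noiseless matrix of rank r the minimizer of the lambda-large limit is
#' the shape-interaction matrix \eqn{V_r V_r^T} from the skinny SVD, which
#' serves as the closed-form oracle in the package's tests.
#'
#' @param a numeric matrix (features x samples), fully observed.
#' @param lambda positive balance weight on the corruption term; default
#'   `1/sqrt(max(dim(a)))`, a standard robust-PCA-style heuristic.
#' @param settings an [lrr_settings()] object.
#' @param dict dictionary matrix (defaults to `a`).
#' @return Object of class `lrr`: coefficient matrix `X`, corruption matrix
#'   `E`, `denoised = dict %*% X`, `lambda`, per-iteration `trace`
#'   (residual and objective), `converged`, `iterations`.
#' @export
lrr_solve <- function(a, lambda = NULL, settings = lrr_settings(), dict = NULL) {
  a <- as.matrix(a)
  if (anyNA(a) || any(!is.finite(a))) {
    data_error("'a' must be finite and fully observed (impute first)")
  }
  if (is.null(dict)) dict <- a else dict <- as.matrix(dict)
  d <- nrow(a); n <- ncol(a); nd <- ncol(dict)
  if (n < 1L || nd < 2L) data_error("need at least 2 dictionary samples")
  if (is.null(lambda)) lambda <- 1 / sqrt(max(d, n))
  if (!is.numeric(lambda) || lambda <= 0) {
    config_error("'lambda' must be a positive scalar")
  }
  stopifnot(inherits(settings, "lrr_settings"))

  # Cache the Cholesky factor of (I + D'D) for the closed-form X update.
  dtd <- crossprod(dict)
  ch <- chol(diag(nd) + dtd)
  dta <- crossprod(dict, a)

  x <- matrix(0, nd, n); j <- x
  e <- matrix(0, d, n)
  y1 <- matrix(0, d, n); y2 <- matrix(0, nd, n)
  mu <- settings$mu0
  na <- max(1, frob(a))
  trace <- data.frame(iter = integer(), residual = double(),
                      objective = double())
  converged <- FALSE
  it <- 0L
  for (it in seq_len(settings$max_iter)) {
    sj <- svt_internal(x + y2 / mu, 1 / mu)
    j <- sj$mat
    rhs <- dta - crossprod(dict, e) + j + (crossprod(dict, y1) - y2) / mu
    x <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    dx <- dict %*% x
    e <- l21_shrink(a - dx + y1 / mu, lambda / mu)
    resid <- a - dx - e
    primal <- frob(resid) / na
    gap <- frob(x - j) / na
    trace[nrow(trace) + 1L, ] <- list(it, primal,
                                      sj$nuclear + lambda * sum(col_norms(e)))
    if (primal < settings$tol && gap < settings$tol) {
      converged <- TRUE
      break
    }
    y1 <- y1 + mu * resid
    y2 <- y2 + mu * (x - j)
    mu <- min(mu * settings$rho, settings$mu_max)
  }
  if (!converged) {
    warning(sprintf("lrr_solve: max_iter (%d) reached, residual %.2e",
                    settings$max_iter, trace$residual[nrow(trace)]),
            call. = FALSE)
  }
  structure(list(X = x, E = e, denoised = dict %*% x, lambda = lambda,
                 trace = trace, converged = converged, iterations = it,
                 settings = settings),
            class = "lrr")
}

#' @export
print.lrr <- function(x, ...) {
  cat(sprintf(
    "LRR solution: X %d x %d, lambda = %.4g, %d iterations (%s), residual %.2e\n",
    nrow(x$X), ncol(x$X), x$lambda, x$iterations,
    if (x$converged) "converged" else "NOT converged",
    x$trace$residual[nrow(x$trace)]))
  invisible(x)
}

#' Choose the LRR balance parameter on a small grid
#'
#' For corruption localization the useful lambda regime is the one where the
#' L2,1 error term concentrates on a few large-norm columns. This helper
#' solves the LRR program over a small grid (by default the
#' `1/sqrt(max(d, n))` heuristic scaled by 0.1 to 2) and picks the lambda
#' whose E column-norm distribution shows the strongest separation between
#' the assumed corrupted fraction and the rest -- an unsupervised gap
#' statistic: `(mean top-frac norms - mean rest) / (sd rest + eps)`.
#'
#' @param a fully observed matrix.
#' @param grid candidate lambdas; default `base * c(0.1, 0.2, 0.5, 1, 2)`
#'   with `base = 1/sqrt(max(dim(a)))`.
#' @param frac assumed corrupted-column fraction (default 0.1).
#' @param settings an [lrr_settings()].
#' @return List with `lambda` (the selection), `scores` and the winning
#'   `solution`.
#' @export
lrr_tune_lambda <- function(a, grid = NULL, frac = 0.1,
                            settings = lrr_settings()) {
  a <- as.matrix(a)
  if (is.null(grid)) {
    grid <- (1 / sqrt(max(dim(a)))) * c(0.1, 0.2, 0.5, 1, 2)
  }
  k <- max(1L, ceiling(frac * ncol(a)))
  best <- NULL; best_score <- -Inf
  scores <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sol <- suppressWarnings(lrr_solve(a, lambda = grid[i], settings = settings))
    nrm <- sort(col_norms(sol$E), decreasing = TRUE)
    top <- nrm[seq_len(k)]; rest <- nrm[-seq_len(k)]
    scores[i] <- (mean(top) - mean(rest)) / (stats::sd(rest) + 1e-12)
    if (is.finite(scores[i]) && scores[i] > best_score) {
      best_score <- scores[i]; best <- sol
    }
  }
  list(lambda = best$lambda, scores = data.frame(lambda = grid, score = scores),
       solution = best)
}

#' Denoise every modality of a dataset by low-rank representation
#'
#' Runs [lrr_solve()] independently on each (fully imputed) modality and
#' replaces the observed matrix with the denoised reconstruction `A %*% X`.
#'
#' @param dataset a [multimodal_dataset()] with no missing entries.
#' @param lambda single value or vector (one per modality); `NULL` uses the
#'   per-modality default heuristic.
#' @param settings an [lrr_settings()].
#' @return The dataset with denoised modalities; the per-modality `lrr`
#'   solutions are attached as `dataset$lrr`.
#' @export
denoise_modalities <- function(dataset, lambda = NULL,
                               settings = lrr_settings()) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  k <- length(dataset$modalities)
  if (!is.null(lambda) && !(length(lambda) %in% c(1L, k))) {
    config_error("'lambda' must have length 1 or one value per modality")
  }
  lam <- if (is.null(lambda)) rep(list(NULL), k) else as.list(rep(lambda, length.out = k))
  sols <- vector("list", k)
  names(sols) <- names(dataset$modalities)
  for (m in seq_len(k)) {
    nm <- names(dataset$modalities)[m]
    if (anyNA(dataset$modalities[[m]])) {
      data_error(sprintf("modality '%s' has missing entries; impute first", nm))
    }
    sols[[m]] <- tryCatch(
      lrr_solve(dataset$modalities[[m]], lambda = lam[[m]], settings = settings),
      error = function(e) {
        numerical_error(sprintf("LRR failed on modality '%s': %s",
                                nm, conditionMessage(e)))
      })
    rn <- rownames(dataset$modalities[[m]])
    dataset$modalities[[m]] <- sols[[m]]$denoised
    rownames(dataset$modalities[[m]]) <- rn
  }
  dataset$lrr <- sols
  dataset
}
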