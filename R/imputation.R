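# Missing-value completion for modality matrices (features x samples, NA =
# missing). Three methods: weighted K-nearest-neighbour (the pipeline default),
# EM-style Gaussian conditional-mean iteration, and iterative truncated-SVD
# matrix completion. Each has a "self" form (complete a matrix in place) and an
# internal fit/apply form so cross-validation can learn imputer statistics on
# training samples only.

new_imputation_result <- function(completed, method, params, warnings = character()) {
  structure(list(completed = completed, method = method, params = params,
                 warnings = warnings),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("Imputation (%s): %d x %d matrix, params: %s\n",
              x$method, nrow(x$completed), ncol(x$completed),
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# Squared Euclidean distances between target and donor sample columns over
# co-observed features, rescaled by d / #co-observed so distances stay
# comparable across missingness patterns. Returns an nt x nd matrix; Inf where
# no feature is co-observed.
co_observed_dist2 <- function(x, donors) {
  d <- nrow(x)
  mt <- !is.na(x); md <- !is.na(donors)
  x0 <- ifelse(mt, x, 0); d0 <- ifelse(md, donors, 0)
  st <- x0^2; sd2 <- d0^2
  d2 <- crossprod(st, md) + crossprod(mt, sd2) - 2 * crossprod(x0, d0)
  d2[d2 < 0] <- 0
  co <- crossprod(mt, md)
  out <- d2 * d / co          # co == 0 -> NaN
  out[co == 0] <- Inf
  out
}

# Core KNN completion: fill NA cells of `x` using columns of `donors` as
# neighbour candidates (same feature space). Returns completed matrix plus
# warning messages.
knn_complete <- function(x, donors, k) {
  d2 <- co_observed_dist2(x, donors)
  warns <- character()
  n_short <- 0L; n_meanfb <- 0L
  out <- x
  for (i in seq_len(nrow(x))) {
    need <- which(is.na(x[i, ]))
    if (!length(need)) next
    have <- which(!is.na(donors[i, ]))
    row_mean <- if (length(have)) mean(donors[i, have]) else NA_real_
    for (j in need) {
      usable <- have[is.finite(d2[j, have])]
      if (!length(usable)) {
        if (is.na(row_mean)) {
          out[i, j] <- mean(donors, na.rm = TRUE)
        } else {
          out[i, j] <- row_mean
        }
        n_meanfb <- n_meanfb + 1L
        next
      }
      if (length(usable) < k) n_short <- n_short + 1L
      dd <- d2[j, usable]
      sel <- usable[order(dd)][seq_len(min(k, length(usable)))]
      dsel <- sqrt(d2[j, sel])
      if (any(dsel == 0)) {
        # exact match wins outright: 1/d weight is undefined at distance zero
        out[i, j] <- mean(donors[i, sel[dsel == 0]])
      } else {
        w <- (1 / dsel) / sum(1 / dsel)
        out[i, j] <- sum(w * donors[i, sel])
      }
    }
  }
  if (n_short > 0) {
    warns <- c(warns, sprintf(
      "%d cell(s) had fewer than k usable neighbours; used all available", n_short))
  }
  if (n_meanfb > 0) {
    warns <- c(warns, sprintf(
      "%d cell(s) had no usable neighbour; fell back to feature mean", n_meanfb))
  }
  list(completed = out, warnings = warns)
}

#' K-nearest-neighbour imputation
#'
#' Replaces each missing entry by the inverse-distance-weighted mean of the K
#' nearest sample columns that observe that feature, with weights
#' \eqn{w_i = (1/d_i) / \sum_j (1/d_j)}. Distances are Euclidean over
#' co-observed features, rescaled by \eqn{\sqrt{d/\#co\text{-}observed}} so
#' they remain comparable across missingness patterns. A neighbour at distance
#' zero is an exact match and supplies its value directly. If fewer than K
#' usable neighbours exist, all available ones are used (with a warning); if
#' none exists, the feature mean is used (with a warning).
#'
#' @param x numeric matrix, features x samples, `NA` = missing.
#' @param k number of neighbours (default 5).
#' @param donors optional donor matrix (same feature rows) supplying
#'   neighbours; defaults to `x` itself. Used to complete held-out samples
#'   from training samples only.
#' @return An `imputation_result` with elements `completed`, `method`,
#'   `params`, `warnings`. Observed entries are returned unchanged.
#' @examples
#' m <- rbind(c(1, 1, 10), c(1, 1, 10), c(NA, 5, 9))
#' knn_impute(m, k = 1)$completed[3, 1]  # 5: column 2 is the nearest sample
#' @export
knn_impute <- function(x, k = 5, donors = NULL) {
  x <- as.matrix(x)
  check_scalar(k, "k", lower = 1, integer = TRUE)
  if (is.null(donors)) donors <- x
  res <- knn_complete(x, as.matrix(donors), as.integer(k))
  for (w in res$warnings) warning(w, call. = FALSE)
  new_imputation_result(res$completed, "knn", list(k = as.integer(k)),
                        res$warnings)
}

# Mean and (ridge-regularized) covariance of samples-as-columns matrix.
gaussian_moments <- function(xc, ridge = 1e-6) {
  d <- nrow(xc); n <- ncol(xc)
  mu <- rowMeans(xc)
  centered <- xc - mu
  sigma <- tcrossprod(centered) / max(1, n - 1)
  lam <- ridge * sum(diag(sigma)) / d
  if (lam <= 0) lam <- ridge
  list(mu = mu, sigma = sigma + diag(lam, d))
}

# One conditional-mean pass: for each column, missing coordinates get
# E[x_m | x_o] under N(mu, sigma). Patterns are grouped to share solves.
conditional_fill <- function(x, mu, sigma) {
  out <- x
  miss <- is.na(x)
  if (!any(miss)) return(out)
  pattern <- apply(miss, 2, function(z) paste(which(z), collapse = ","))
  for (pat in unique(pattern[colSums(miss) > 0])) {
    cols <- which(pattern == pat)
    m_idx <- which(miss[, cols[1L]])
    if (!length(m_idx)) next
    o_idx <- setdiff(seq_len(nrow(x)), m_idx)
    if (!length(o_idx)) {
      out[m_idx, cols] <- mu[m_idx]
      next
    }
    s_oo <- sigma[o_idx, o_idx, drop = FALSE]
    s_mo <- sigma[m_idx, o_idx, drop = FALSE]
    resid <- x[o_idx, cols, drop = FALSE] - mu[o_idx]
    out[m_idx, cols] <- mu[m_idx] + s_mo %*% solve(s_oo, resid)
  }
  out
}

#' EM (Gaussian conditional-mean) imputation
#'
#' Iterates between (a) estimating the mean and covariance of the samples from
#' the current completed matrix and (b) replacing missing coordinates of each
#' sample by their Gaussian conditional mean given the observed coordinates.
#' Initialized from feature means; the covariance carries a ridge of
#' `ridge * trace / d` to stay invertible when features outnumber samples.
#'
#' @inheritParams knn_impute
#' @param n_iter maximum iterations (default 50).
#' @param tol stop early when the largest change in any imputed entry falls
#'   below `tol`.
#' @param ridge relative covariance ridge.
#' @param moments optional precomputed `list(mu, sigma)`; when supplied, a
#'   single conditional-mean pass is applied (used to impute held-out samples
#'   from training moments).
#' @return An `imputation_result`; `params$converged` reports early stopping.
#' @export
em_impute <- function(x, n_iter = 50, tol = 1e-6, ridge = 1e-6, moments = NULL) {
  x <- as.matrix(x)
  check_scalar(n_iter, "n_iter", lower = 1, integer = TRUE)
  miss <- is.na(x)
  warns <- character()
  if (!is.null(moments)) {
    out <- conditional_fill(x, moments$mu, moments$sigma)
    return(new_imputation_result(out, "em",
                                 list(n_iter = 1L, converged = TRUE), warns))
  }
  if (!any(miss)) {
    return(new_imputation_result(x, "em",
                                 list(n_iter = 0L, converged = TRUE), warns))
  }
  if (nrow(x) >= ncol(x)) {
    warns <- "covariance is singular (d >= n); ridge-regularized"
    warning(warns, call. = FALSE)
  }
  xf <- x
  rm_ <- rowMeans(x, na.rm = TRUE)
  rm_[is.nan(rm_)] <- mean(x, na.rm = TRUE)
  for (i in seq_len(nrow(x))) xf[i, miss[i, ]] <- rm_[i]
  converged <- FALSE
  it <- 0L
  for (it in seq_len(n_iter)) {
    mom <- gaussian_moments(xf, ridge)
    new <- conditional_fill(x, mom$mu, mom$sigma)
    delta <- max(abs(new[miss] - xf[miss]))
    xf[miss] <- new[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  new_imputation_result(xf, "em",
                        list(n_iter = it, converged = converged,
                             moments = gaussian_moments(xf, ridge)),
                        warns)
}

energy_rank <- function(singular_values, energy) {
  e <- cumsum(singular_values^2) / sum(singular_values^2)
  max(1L, which(e >= energy - 1e-12)[1L])
}

#' Iterative truncated-SVD imputation
#'
#' Alternates (a) filling missing cells with current estimates, (b) truncating
#' the SVD to the smallest rank whose cumulative squared singular values reach
#' the `energy` fraction of the total, and (c) refreshing the missing cells
#' from the truncation, until the imputed entries stabilize.
#'
#' @inheritParams knn_impute
#' @param energy retained energy fraction in (0, 1]; default 0.95.
#' @param max_iter iteration cap.
#' @param tol relative change of imputed entries at which to stop.
#' @param basis optional `list(u, row_means)` from a fitted training matrix;
#'   when supplied, missing cells are refreshed by projection onto that basis
#'   instead of the matrix's own SVD (held-out imputation).
#' @return An `imputation_result`; `params$rank` is the final truncation rank.
#' @export
svd_impute <- function(x, energy = 0.95, max_iter = 500, tol = 1e-7,
                       basis = NULL) {
  x <- as.matrix(x)
  check_scalar(energy, "energy", lower = 1e-12, upper = 1)
  miss <- is.na(x)
  if (!any(miss)) {
    return(new_imputation_result(x, "svd",
                                 list(energy = energy, rank = NA_integer_,
                                      converged = TRUE), character()))
  }
  xf <- x
  rm_ <- if (is.null(basis)) rowMeans(x, na.rm = TRUE) else basis$row_means
  rm_[is.nan(rm_)] <- mean(x, na.rm = TRUE)
  for (i in seq_len(nrow(x))) xf[i, miss[i, ]] <- rm_[i]
  converged <- FALSE; r <- NA_integer_
  for (it in seq_len(max_iter)) {
    if (is.null(basis)) {
      sv <- svd(xf)
      r <- energy_rank(sv$d, energy)
      approx <- sv$u[, seq_len(r), drop = FALSE] %*%
        (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
    } else {
      u <- basis$u
      r <- ncol(u)
      centered <- xf - rm_
      approx <- u %*% crossprod(u, centered) + rm_
    }
    old <- xf[miss]
    xf[miss] <- approx[miss]
    rel <- frob(matrix(xf[miss] - old)) / max(1, frob(matrix(xf[miss])))
    if (rel < tol) { converged <- TRUE; break }
  }
  warns <- character()
  if (!converged) {
    warns <- sprintf("svd_impute did not converge in %d iterations", max_iter)
    warning(warns, call. = FALSE)
  }
  params <- list(energy = energy, rank = r, converged = converged)
  if (is.null(basis)) {
    sv <- svd(xf)
    r_fit <- energy_rank(sv$d, energy)
    params$basis <- list(u = sv$u[, seq_len(r_fit), drop = FALSE],
                         row_means = rowMeans(xf))
  }
  new_imputation_result(xf, "svd", params, warns)
}

#' Feature-mean imputation (reference baseline)
#'
#' @inheritParams knn_impute
#' @param means optional feature means from a training matrix.
#' @return An `imputation_result`.
#' @export
mean_impute <- function(x, means = NULL) {
  x <- as.matrix(x)
  miss <- is.na(x)
  rm_ <- means %||% rowMeans(x, na.rm = TRUE)
  rm_[is.nan(rm_)] <- mean(x, na.rm = TRUE)
  out <- x
  for (i in seq_len(nrow(x))) out[i, miss[i, ]] <- rm_[i]
  new_imputation_result(out, "mean", list(means = rm_), character())
}
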