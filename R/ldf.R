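#' Fit the low-rank denoising + discriminant correlation fusion classifier
#'
#' The full fusion pipeline as one fitted model: missing entries of each
#' modality are completed by weighted K-nearest-neighbour imputation, each
#' completed modality is denoised by solving the low-rank representation
#' program \eqn{\min \|X\|_* + \lambda\|E\|_{2,1}} s.t. \eqn{A = AX + E}
#' (the denoised features are \eqn{AX}), the denoised modalities are fused by
#' cascaded discriminant correlation analysis, and a linear SVM is trained on
#' the standardized fused features.
#'
#' New samples are pushed through the same fitted stages: imputation draws
#' neighbours from the training samples, denoising represents new columns in
#' the training dictionary, and the DCA projections and feature scaling are
#' fixed at their training values, so prediction is leakage-free.
#'
#' @param modalities named list of feature matrices (features x samples,
#'   `NA` = missing) or a [multimodal_dataset()].
#' @param labels class factor (ignored when `modalities` is a dataset).
#' @param k neighbours for KNN imputation (default 5).
#' @param lambda LRR balance parameter, one value or one per modality;
#'   `NULL` uses `1/sqrt(max(d, n))` per modality.
#' @param denoise set `FALSE` to skip the LRR stage.
#' @param fuse fusion method: `"dca"` (default), `"cca"` or `"concat"`.
#' @param cost linear-SVM cost C.
#' @param energy_tol DCA eigenvalue cutoff.
#' @param lrr an [lrr_settings()] object.
#' @return Object of class `ldf` with `print`, `summary`, `predict` and
#'   `coef` methods.
#' @examples
#' d <- simulate_multimodal(sim_config(n_per_class = 12, n_classes = 2,
#'                                     modality_dims = c(10, 8),
#'                                     missing_frac = 0.05, corrupt_frac = 0,
#'                                     seed = 7))
#' fit <- ldf(d, lrr = lrr_settings(max_iter = 150))
#' table(predict(fit, d$modalities), d$labels)
#' @export
ldf <- function(modalities, labels = NULL, k = 5, lambda = NULL,
                denoise = TRUE, fuse = "dca", cost = 1, energy_tol = 1e-8,
                lrr = lrr_settings()) {
  if (inherits(modalities, "multimodal_dataset")) {
    labels <- modalities$labels
    modalities <- modalities$modalities
  }
  if (is.null(labels)) config_error("'labels' are required")
  pl <- ldf_pipeline(impute = "knn", k = k, denoise = denoise,
                     lambda = lambda, lrr = lrr, fuse = fuse,
                     energy_tol = energy_tol, cost = cost)
  fit <- fit_pipeline(modalities, labels, pl)
  structure(list(fit = fit, call = match.call(),
                 n = ncol(modalities[[1L]]),
                 labels = droplevels(as.factor(labels))),
            class = "ldf")
}

#' @export
print.ldf <- function(x, ...) {
  cat("Low-rank denoising + DCA fusion classifier\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Modalities: %s\n",
              paste(x$fit$modality_names, collapse = ", ")))
  cat(sprintf("Samples: %d; classes: %s\n", x$n,
              paste(levels(x$labels), collapse = ", ")))
  if (!is.null(x$fit$fuser) && inherits(x$fit$fuser, "dca_cascade")) {
    cat(sprintf("DCA cascade stage dimensions: %s\n",
                paste(x$fit$fuser$stage_r, collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.ldf <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$fit$lrr)) {
    cat("LRR stage:\n")
    for (m in seq_along(x$fit$lrr)) {
      sol <- x$fit$lrr[[m]]$solution
      cat(sprintf("  %s: lambda = %.4g, %d iters, residual %.2e (%s)\n",
                  x$fit$modality_names[m], sol$lambda, sol$iterations,
                  sol$trace$residual[nrow(sol$trace)],
                  if (sol$converged) "converged" else "not converged"))
    }
  }
  cat(sprintf("SVM support vectors: %d\n", nrow(x$fit$svm$SV)))
  invisible(x)
}

#' Predict classes (or decision scores) for new multimodal samples
#'
#' @param object a fitted [ldf()] model.
#' @param newdata named list of modality matrices with the training feature
#'   dimensions (columns = new samples), or a `multimodal_dataset`.
#' @param type `"class"` for labels, `"score"` for oriented SVM decision
#'   values (larger favors `positive`).
#' @param positive positive class for score orientation (default: second
#'   training level).
#' @param ... unused.
#' @return Character vector of classes or numeric scores.
#' @export
predict.ldf <- function(object, newdata, type = c("class", "score"),
                        positive = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "multimodal_dataset")) newdata <- newdata$modalities
  pred <- predict_pipeline(object$fit, newdata)
  if (type == "class") return(pred$class)
  positive <- positive %||% levels(object$labels)[2L]
  orient_scores(pred$decision, positive)
}

#' Extract the fitted fusion projection matrices
#'
#' @param object a fitted [ldf()] model.
#' @param ... unused.
#' @return For DCA fusion, a list per cascade stage with `w_a` and `w_b`;
#'   for CCA, the canonical direction matrices; `NULL` for plain
#'   concatenation.
#' @export
coef.ldf <- function(object, ...) {
  fuser <- object$fit$fuser
  if (is.null(fuser)) return(NULL)
  if (inherits(fuser, "dca_cascade")) {
    lapply(fuser$fits, function(f) list(w_a = f$w_a, w_b = f$w_b))
  } else {
    list(wx = fuser$wx, wy = fuser$wy)
  }
}
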