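# Classification evaluation: confusion-matrix metrics, empirical ROC/AUC, and
# leakage-safe repeated stratified k-fold cross-validation of a staged
# pipeline (impute -> denoise -> fuse -> classify). All fitted statistics --
# imputer moments/bases, LRR dictionaries, DCA/CCA transforms, feature
# scaling, the SVM -- are learned on training folds only.

#' Binary confusion-matrix metrics
#'
#' Computes ACC (accuracy), SEN (sensitivity), SPE (specificity), BAC
#' (balanced accuracy, `(SEN + SPE)/2`), PPV and NPV from predicted and true
#' binary labels. Ratios with a zero denominator are reported as `NaN` and
#' named in the `undefined` field, never silently zeroed.
#'
#' @param y_true,y_pred vectors of equal length with exactly two possible
#'   labels.
#' @param positive the label treated as positive (e.g. the disease class).
#' @return Object of class `confusion_metrics`: the six metrics plus counts
#'   `tp`, `fn`, `tn`, `fp` and the `undefined` metric names.
#' @examples
#' confusion_metrics(rep(c("AD", "NC"), c(10, 10)),
#'                   rep(c("AD", "NC", "AD", "NC"), c(9, 1, 2, 8)), "AD")
#' @export
confusion_metrics <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    data_error("y_true and y_pred must have equal length")
  }
  labs <- unique(c(y_true, y_pred))
  if (length(labs) > 2L) {
    data_error(paste("labels are not binary; set the task up pairwise",
                     "(e.g. AD/NC, MCI/NC, AD/MCI)"))
  }
  if (!positive %in% labs) data_error("'positive' not among the labels")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sen <- ratio(tp, tp + fn); spe <- ratio(tn, tn + fp)
  m <- list(ACC = ratio(tp + tn, tp + tn + fp + fn),
            SEN = sen, SPE = spe, BAC = (sen + spe) / 2,
            PPV = ratio(tp, tp + fp), NPV = ratio(tn, tn + fn))
  structure(c(m, list(tp = tp, fn = fn, tn = tn, fp = fp,
                      undefined = names(m)[vapply(m, is.nan, TRUE)])),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("ACC %.3f | SEN %.3f | SPE %.3f | BAC %.3f | PPV %.3f | NPV %.3f\n",
              x$ACC, x$SEN, x$SPE, x$BAC, x$PPV, x$NPV))
  if (length(x$undefined)) {
    cat("Undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Empirical ROC curve and AUC
#'
#' AUC is computed as the Mann-Whitney U statistic normalized by the number
#' of positive-negative pairs (ties count one half), which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores continuous decision values; larger favors the positive class.
#' @param labels binary labels aligned with `scores`.
#' @param positive the positive label.
#' @return List with `auc` and `roc_points` (data frame of `fpr`, `tpr`,
#'   `threshold`, starting at (0, 0)).
#' @export
roc_auc <- function(scores, labels, positive) {
  labels <- as.character(labels)
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    data_error("both classes must be present to form an ROC curve")
  }
  r <- rank(scores)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(diff(s) != 0, TRUE)   # last index of each tied score block
  roc <- data.frame(fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos),
                    threshold = c(Inf, s[last]))
  list(auc = auc, roc_points = roc)
}

#' Pipeline stage configuration for cross-validated evaluation
#'
#' Describes one impute -> denoise -> fuse -> classify pipeline. The default
#' is the full fusion pipeline: KNN imputation (K = 5), per-modality low-rank
#' representation denoising, DCA fusion, linear SVM (C = 1) on per-fold
#' standardized features.
#'
#' @param impute one of `"knn"`, `"em"`, `"svd"`, `"mean"`, `"none"`.
#' @param k KNN neighbour count.
#' @param em_iter EM iteration count.
#' @param svd_energy retained energy for SVD imputation.
#' @param denoise logical: run LRR denoising per modality.
#' @param lambda LRR balance parameter(s); `NULL` = per-modality heuristic.
#' @param lrr lrr solver settings, an [lrr_settings()].
#' @param fuse `"dca"`, `"cca"` or `"concat"`.
#' @param fuse_mode `"concat"` or `"sum"` for the DCA pair combiner.
#' @param energy_tol DCA eigenvalue cutoff.
#' @param ridge CCA covariance ridge.
#' @param cost SVM cost parameter C.
#' @param scale logical: standardize fused features per training fold.
#' @param modalities optional character/integer subset of modalities to use
#'   (e.g. a single modality for per-modality baselines).
#' @return List of class `ldf_pipeline`.
#' @export
ldf_pipeline <- function(impute = c("knn", "em", "svd", "mean", "none"),
                         k = 5, em_iter = 50, svd_energy = 0.95,
                         denoise = TRUE, lambda = NULL,
                         lrr = lrr_settings(),
                         fuse = c("dca", "cca", "concat"),
                         fuse_mode = c("concat", "sum"),
                         energy_tol = 1e-8, ridge = 1e-6,
                         cost = 1, scale = TRUE, modalities = NULL) {
  structure(list(impute = match.arg(impute), k = k, em_iter = em_iter,
                 svd_energy = svd_energy, denoise = denoise, lambda = lambda,
                 lrr = lrr, fuse = match.arg(fuse),
                 fuse_mode = match.arg(fuse_mode), energy_tol = energy_tol,
                 ridge = ridge, cost = cost, scale = scale,
                 modalities = modalities),
            class = "ldf_pipeline")
}

select_modalities <- function(mods, which) {
  if (is.null(which)) mods else mods[which]
}

# Fit every pipeline stage on training modalities only.
fit_pipeline <- function(mods, labels, pl) {
  mods <- select_modalities(mods, pl$modalities)
  k <- length(mods)
  imputers <- vector("list", k)
  completed <- vector("list", k); names(completed) <- names(mods)
  for (m in seq_len(k)) {
    x <- mods[[m]]
    res <- switch(pl$impute,
      none = {
        if (anyNA(x)) data_error("pipeline 'none' imputation but data has NAs")
        new_imputation_result(x, "none", list())
      },
      knn = suppressWarnings(knn_impute(x, k = pl$k)),
      em = suppressWarnings(em_impute(x, n_iter = pl$em_iter)),
      svd = suppressWarnings(svd_impute(x, energy = pl$svd_energy)),
      mean = mean_impute(x))
    completed[[m]] <- res$completed
    imputers[[m]] <- switch(pl$impute,
      knn = list(donors = res$completed),
      em = list(moments = res$params$moments %||%
                  gaussian_moments(res$completed)),
      svd = list(basis = res$params$basis %||%
                   list(u = svd(res$completed)$u[, 1, drop = FALSE],
                        row_means = rowMeans(res$completed))),
      mean = list(means = res$params$means),
      none = list())
  }
  lrr_fits <- NULL
  denoised <- completed
  if (isTRUE(pl$denoise)) {
    lam <- if (is.null(pl$lambda)) rep(list(NULL), k) else
      as.list(rep(pl$lambda, length.out = k))
    lrr_fits <- vector("list", k)
    for (m in seq_len(k)) {
      sol <- suppressWarnings(
        lrr_solve(completed[[m]], lambda = lam[[m]], settings = pl$lrr))
      denoised[[m]] <- sol$denoised
      lrr_fits[[m]] <- list(dict = completed[[m]], lambda = sol$lambda,
                            solution = sol)
    }
  }
  fuser <- NULL
  fused <- if (k == 1L || pl$fuse == "concat") {
    do.call(rbind, denoised)
  } else if (pl$fuse == "dca") {
    fuser <- dca_cascade_fit(denoised, labels, pl$energy_tol, pl$fuse_mode)
    dca_cascade_transform(fuser, denoised)
  } else {
    if (k > 2L) {
      fz <- cca_fuse(denoised[[1L]], do.call(rbind, denoised[-1L]),
                     ridge = pl$ridge)
    } else {
      fz <- cca_fuse(denoised[[1L]], denoised[[2L]], ridge = pl$ridge)
    }
    fuser <- attr(fz, "cca")
    fz$values
  }
  ctr <- rowMeans(fused)
  scl <- apply(fused, 1, stats::sd)
  scl[scl < 1e-12] <- 1
  if (!isTRUE(pl$scale)) { ctr <- rep(0, nrow(fused)); scl <- rep(1, nrow(fused)) }
  xs <- t((fused - ctr) / scl)
  svm_fit <- e1071::svm(x = xs, y = droplevels(as.factor(labels)),
                        kernel = "linear", cost = pl$cost, scale = FALSE)
  structure(list(pipeline = pl, imputers = imputers, lrr = lrr_fits,
                 fuser = fuser, center = ctr, scale = scl, svm = svm_fit,
                 modality_names = names(mods),
                 levels = levels(droplevels(as.factor(labels)))),
            class = "pipeline_fit")
}

# Push held-out modalities through the fitted stages.
predict_pipeline <- function(fit, mods) {
  pl <- fit$pipeline
  mods <- select_modalities(mods, pl$modalities)
  k <- length(mods)
  completed <- vector("list", k); names(completed) <- names(mods)
  for (m in seq_len(k)) {
    x <- mods[[m]]
    completed[[m]] <- switch(pl$impute,
      none = x,
      knn = suppressWarnings(
        knn_impute(x, k = pl$k, donors = fit$imputers[[m]]$donors))$completed,
      em = suppressWarnings(
        em_impute(x, moments = fit$imputers[[m]]$moments))$completed,
      svd = suppressWarnings(
        svd_impute(x, energy = pl$svd_energy,
                   basis = fit$imputers[[m]]$basis))$completed,
      mean = mean_impute(x, means = fit$imputers[[m]]$means)$completed)
  }
  denoised <- completed
  if (!is.null(fit$lrr)) {
    for (m in seq_len(k)) {
      sol <- suppressWarnings(
        lrr_solve(completed[[m]], lambda = fit$lrr[[m]]$lambda,
                  settings = pl$lrr, dict = fit$lrr[[m]]$dict))
      denoised[[m]] <- sol$denoised
    }
  }
  fused <- if (k == 1L || pl$fuse == "concat") {
    do.call(rbind, denoised)
  } else if (pl$fuse == "dca") {
    dca_cascade_transform(fit$fuser, denoised)
  } else {
    if (k > 2L) {
      cca_apply(fit$fuser, denoised[[1L]], do.call(rbind, denoised[-1L]))
    } else {
      cca_apply(fit$fuser, denoised[[1L]], denoised[[2L]])
    }
  }
  xs <- t((fused - fit$center) / fit$scale)
  pr <- stats::predict(fit$svm, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  list(class = as.character(pr), decision = dv)
}

# Orient SVM decision values so that larger favors `positive`.
orient_scores <- function(decision, positive) {
  nm <- colnames(decision)[1L]
  parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
  s <- as.numeric(decision[, 1L])
  if (parts[1L] == positive) s else -s
}

make_stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (l in levels(labels)) {
    idx <- which(labels == l)
    if (length(idx) < n_folds) {
      data_error(sprintf(
        "class '%s' has %d samples, fewer than n_folds = %d; use fewer folds",
        l, length(idx), n_folds))
    }
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of a fusion pipeline
#'
#' Partitions the samples into stratified folds, fits every pipeline stage on
#' the training folds only, predicts the held-out fold, and aggregates the
#' six confusion metrics as mean and standard deviation over all
#' `n_folds * n_repeats` fold results (per-repeat aggregates are also kept).
#' Held-out decision values are pooled into one ROC curve and AUC.
#'
#' @param dataset a binary-labelled [multimodal_dataset()] (see
#'   [subset_task()]).
#' @param pipeline an [ldf_pipeline()].
#' @param n_folds,n_repeats protocol size (default 10 x 10).
#' @param seed RNG seed; the fold layout is a deterministic function of the
#'   seed and labels, so different pipelines evaluated at the same seed see
#'   identical folds (paired design).
#' @param positive positive class label; defaults to the dataset's
#'   `positive` attribute, else the second factor level.
#' @param preprocess `"fold"` (default, leakage-safe: every stage inside the
#'   CV loop) or `"global"` (impute/denoise/fuse once on all samples, then
#'   cross-validate only the classifier -- the optimistic variant some studies
#'   use; clearly labelled in the result).
#' @return Object of class `cv_result`: `per_fold` data frame, `mean`, `sd`,
#'   `per_repeat` means, pooled `auc` and `roc_points`, recorded `folds`,
#'   `seed` and `config_hash`.
#' @export
repeated_cv <- function(dataset, pipeline = ldf_pipeline(), n_folds = 10,
                        n_repeats = 10, seed = 1, positive = NULL,
                        preprocess = c("fold", "global")) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  preprocess <- match.arg(preprocess)
  check_scalar(n_folds, "n_folds", lower = 2, integer = TRUE)
  check_scalar(n_repeats, "n_repeats", lower = 1, integer = TRUE)
  labels <- droplevels(dataset$labels)
  if (nlevels(labels) != 2L) {
    data_error("repeated_cv needs a binary task; use subset_task() first")
  }
  positive <- positive %||% attr(dataset, "positive") %||% levels(labels)[2L]
  mods <- dataset$modalities

  global_fit <- NULL
  if (preprocess == "global") {
    # fit transforms once on everything; CV then covers only the classifier
    global_fit <- fit_pipeline(mods, labels, pipeline)
  }

  metric_names <- c("ACC", "SEN", "SPE", "BAC", "PPV", "NPV")
  rows <- list(); fold_record <- list()
  scores <- numeric(0); score_labels <- character(0)
  with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      fold <- make_stratified_folds(labels, n_folds)
      fold_record[[rep_i]] <- fold
      for (f in seq_len(n_folds)) {
        test <- fold == f
        train_mods <- lapply(mods, function(m) m[, !test, drop = FALSE])
        test_mods <- lapply(mods, function(m) m[, test, drop = FALSE])
        if (preprocess == "global") {
          # reuse the globally fitted transforms; only the SVM respects folds
          fit <- global_fit
          fit$svm <- refit_svm_on(fit, train_mods, labels[!test])
          pred <- predict_pipeline(fit, test_mods)
        } else {
          fit <- fit_pipeline(train_mods, labels[!test], pipeline)
          pred <- predict_pipeline(fit, test_mods)
        }
        cm <- confusion_metrics(as.character(labels[test]), pred$class, positive)
        rows[[length(rows) + 1L]] <- data.frame(
          repeat_ = rep_i, fold = f,
          as.data.frame(cm[metric_names]),
          check.names = FALSE)
        sc <- orient_scores(pred$decision, positive)
        scores <- c(scores, sc)
        score_labels <- c(score_labels, as.character(labels[test]))
      }
    }
  })
  per_fold <- do.call(rbind, rows)
  agg_mean <- vapply(metric_names, function(m) mean(per_fold[[m]], na.rm = TRUE), 1)
  agg_sd <- vapply(metric_names, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), 1)
  per_repeat <- stats::aggregate(per_fold[metric_names],
                                 by = list(repeat_ = per_fold$repeat_),
                                 FUN = mean, na.rm = TRUE)
  roc <- roc_auc(scores, score_labels, positive)
  structure(list(per_fold = per_fold, mean = agg_mean, sd = agg_sd,
                 per_repeat = per_repeat, auc = roc$auc,
                 roc_points = roc$roc_points, folds = fold_record,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed,
                 positive = positive, preprocess = preprocess,
                 pipeline = pipeline,
                 config_hash = hash_object(list(pipeline, n_folds, n_repeats,
                                                seed, preprocess))),
            class = "cv_result")
}

refit_svm_on <- function(fit, train_mods, train_labels) {
  pl <- fit$pipeline
  fit_no_svm <- fit
  # project the training folds through the already-fitted transforms
  pred_x <- predict_pipeline_features(fit_no_svm, train_mods)
  e1071::svm(x = pred_x, y = droplevels(as.factor(train_labels)),
             kernel = "linear", cost = pl$cost, scale = FALSE)
}

# Transformed (scaled) feature rows for a set of samples, without classifying.
predict_pipeline_features <- function(fit, mods) {
  pl <- fit$pipeline
  mods <- select_modalities(mods, pl$modalities)
  k <- length(mods)
  completed <- vector("list", k); names(completed) <- names(mods)
  for (m in seq_len(k)) {
    x <- mods[[m]]
    completed[[m]] <- switch(pl$impute,
      none = x,
      knn = suppressWarnings(
        knn_impute(x, k = pl$k, donors = fit$imputers[[m]]$donors))$completed,
      em = suppressWarnings(
        em_impute(x, moments = fit$imputers[[m]]$moments))$completed,
      svd = suppressWarnings(
        svd_impute(x, energy = pl$svd_energy,
                   basis = fit$imputers[[m]]$basis))$completed,
      mean = mean_impute(x, means = fit$imputers[[m]]$means)$completed)
  }
  denoised <- completed
  if (!is.null(fit$lrr)) {
    for (m in seq_len(k)) {
      sol <- suppressWarnings(
        lrr_solve(completed[[m]], lambda = fit$lrr[[m]]$lambda,
                  settings = pl$lrr, dict = fit$lrr[[m]]$dict))
      denoised[[m]] <- sol$denoised
    }
  }
  fused <- if (k == 1L || pl$fuse == "concat") {
    do.call(rbind, denoised)
  } else if (pl$fuse == "dca") {
    dca_cascade_transform(fit$fuser, denoised)
  } else {
    if (k > 2L) {
      cca_apply(fit$fuser, denoised[[1L]], do.call(rbind, denoised[-1L]))
    } else {
      cca_apply(fit$fuser, denoised[[1L]], denoised[[2L]])
    }
  }
  t((fused - fit$center) / fit$scale)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Repeated CV: %d folds x %d repeats, positive = '%s' (%s protocol)\n",
              x$n_folds, x$n_repeats, x$positive, x$preprocess))
  for (m in names(x$mean)) {
    cat(sprintf("  %s: %5.2f +/- %.2f %%\n", m, 100 * x$mean[[m]], 100 * x$sd[[m]]))
  }
  cat(sprintf("  AUC (pooled): %.3f\n", x$auc))
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  plot(x$roc_points$fpr, x$roc_points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

method_pipelines <- function() {
  list(
    "LDF" = ldf_pipeline(impute = "knn", k = 5, denoise = TRUE, fuse = "dca"),
    "KNN-concat" = ldf_pipeline(impute = "knn", k = 7, denoise = FALSE,
                                fuse = "concat"),
    "EM-concat" = ldf_pipeline(impute = "em", em_iter = 50, denoise = FALSE,
                               fuse = "concat"),
    "SVD-concat" = ldf_pipeline(impute = "svd", svd_energy = 0.95,
                                denoise = FALSE, fuse = "concat"),
    "CCA" = ldf_pipeline(impute = "knn", k = 5, denoise = FALSE, fuse = "cca"),
    "concat-only" = ldf_pipeline(impute = "mean", denoise = FALSE,
                                 fuse = "concat")
  )
}

#' Compare fusion methods under one paired cross-validation protocol
#'
#' Runs [repeated_cv()] for each named method on each binary task, using the
#' same seed so all methods see identical fold assignments (paired design).
#'
#' @param dataset a multiclass [multimodal_dataset()].
#' @param methods character subset of `"LDF"`, `"KNN-concat"`, `"EM-concat"`,
#'   `"SVD-concat"`, `"CCA"`, `"concat-only"`.
#' @param tasks list of `c(positive, negative)` label pairs; default the
#'   three pairwise tasks over levels AD/MCI/NC when present, else all pairs.
#' @param n_folds,n_repeats,seed,preprocess passed to [repeated_cv()].
#' @return Object of class `method_comparison`: tidy `table` (method, task,
#'   metric, mean, sd), plus the underlying `cv` results.
#' @export
compare_methods <- function(dataset, methods = "LDF", tasks = NULL,
                            n_folds = 10, n_repeats = 10, seed = 1,
                            preprocess = "fold") {
  pls <- method_pipelines()
  bad <- setdiff(methods, names(pls))
  if (length(bad)) {
    config_error(sprintf("unknown method(s): %s; valid: %s",
                         paste(bad, collapse = ", "),
                         paste(names(pls), collapse = ", ")))
  }
  lv <- levels(dataset$labels)
  if (is.null(tasks)) {
    tasks <- if (all(c("AD", "MCI", "NC") %in% lv)) {
      list(c("AD", "NC"), c("MCI", "NC"), c("AD", "MCI"))
    } else {
      utils::combn(lv, 2, function(p) c(p[2L], p[1L]), simplify = FALSE)
    }
  }
  cvs <- list(); rows <- list()
  for (task in tasks) {
    task_name <- paste(task, collapse = "/")
    sub <- subset_task(dataset, positive = task[1L], negative = task[2L])
    for (meth in methods) {
      cv <- repeated_cv(sub, pls[[meth]], n_folds = n_folds,
                        n_repeats = n_repeats, seed = seed,
                        positive = task[1L], preprocess = preprocess)
      cvs[[paste(meth, task_name, sep = "|")]] <- cv
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, task = task_name,
        metric = c(names(cv$mean), "AUC"),
        mean = c(unname(cv$mean), cv$auc),
        sd = c(unname(cv$sd), NA_real_))
    }
  }
  structure(list(table = do.call(rbind, rows), cv = cvs,
                 methods = methods, seed = seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  tab <- x$table
  tab$value <- ifelse(is.na(tab$sd),
                      sprintf("%.2f", 100 * tab$mean),
                      sprintf("%.2f +/- %.2f", 100 * tab$mean, 100 * tab$sd))
  wide <- stats::reshape(tab[, c("method", "task", "metric", "value")],
                         idvar = c("method", "task"), timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
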