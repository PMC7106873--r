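test_that("confusion metrics reproduce the definitional values", {
  y_true <- rep(c("AD", "AD", "NC", "NC"), c(9, 1, 8, 2))
  y_pred <- rep(c("AD", "NC", "NC", "AD"), c(9, 1, 8, 2))
  cm <- confusion_metrics(y_true, y_pred, positive = "AD")
  expect_equal(cm$SEN, 0.90)
  expect_equal(cm$SPE, 0.80)
  expect_equal(cm$ACC, 0.85)
  expect_equal(cm$BAC, 0.85)
  expect_equal(cm$PPV, 9 / 11)
  expect_equal(cm$NPV, 8 / 9)
  expect_length(cm$undefined, 0)

  perfect <- confusion_metrics(c("a", "b", "a"), c("a", "b", "a"), "a")
  for (m in c("ACC", "SEN", "SPE", "BAC", "PPV", "NPV")) {
    expect_equal(perfect[[m]], 1.0)
  }

  # all predicted positive: SPE = 0 and NPV undefined, flagged not zeroed
  allpos <- confusion_metrics(c("a", "a", "b"), c("a", "a", "a"), "a")
  expect_equal(allpos$SPE, 0)
  expect_true(is.nan(allpos$NPV))
  expect_true("NPV" %in% allpos$undefined)

  expect_error(confusion_metrics(c("a", "b", "c"), c("a", "b", "c"), "a"),
               "pairwise")
})

test_that("BAC is the mean of sensitivity and specificity under fuzzing", {
  set.seed(700)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    y_true <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(y_true)) < 2) y_true[1:2] <- c("p", "n")
    y_pred <- sample(c("p", "n"), n, replace = TRUE)
    cm <- confusion_metrics(y_true, y_pred, "p")
    if (!is.nan(cm$BAC)) {
      expect_equal(cm$BAC, (cm$SEN + cm$SPE) / 2)
    }
    expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, n)
  }
})

test_that("AUC equals brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c("n", "n", "p", "p"), "p")$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 8), rep(c("p", "n"), 4), "p")$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"), "p")
  expect_equal(r$auc, 0.75)   # 3 of 4 positive-negative pairs ordered

  brute_auc <- function(scores, pos) {
    s_p <- scores[pos]; s_n <- scores[!pos]
    total <- 0
    for (i in seq_along(s_p)) for (j in seq_along(s_n)) {
      total <- total + (s_p[i] > s_n[j]) + 0.5 * (s_p[i] == s_n[j])
    }
    total / (length(s_p) * length(s_n))
  }
  set.seed(701)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("p", "n")
    scores <- round(rnorm(n), 1)   # rounding forces ties
    expect_equal(roc_auc(scores, labels, "p")$auc,
                 brute_auc(scores, labels == "p"))
  }
  # independent reference implementation on one instance
  set.seed(702)
  labels <- sample(c("p", "n"), 40, replace = TRUE)
  scores <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(scores, labels, "p")$auc, ref)

  expect_error(roc_auc(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("cross-validation folds partition the samples and are reproducible", {
  d <- simulate_multimodal(sim_config(n_per_class = 20, n_classes = 2,
                                      modality_dims = c(6, 4),
                                      corrupt_frac = 0, missing_frac = 0,
                                      seed = 800))
  pl <- ldf_pipeline(impute = "none", denoise = FALSE, fuse = "concat")
  cv1 <- repeated_cv(d, pl, n_folds = 5, n_repeats = 2, seed = 9)
  for (fold in cv1$folds) {
    expect_equal(sort(unique(fold)), 1:5)
    expect_equal(length(fold), 40)
    # stratified: both classes appear in every fold
    for (f in 1:5) {
      expect_equal(length(unique(d$labels[fold == f])), 2L)
    }
  }
  cv2 <- repeated_cv(d, pl, n_folds = 5, n_repeats = 2, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$mean, cv2$mean)
  expect_equal(nrow(cv1$per_fold), 10)
  expect_error(repeated_cv(d, pl, n_folds = 25), "fewer folds|fewer than")
})

test_that("methods are compared on identical folds (paired design)", {
  d <- simulate_multimodal(sim_config(n_per_class = 12, n_classes = 2,
                                      modality_dims = c(6, 5),
                                      class_separation = 2, corrupt_frac = 0,
                                      missing_frac = 0, seed = 801))
  cmp <- compare_methods(d, methods = c("CCA", "concat-only"),
                         n_folds = 3, n_repeats = 1, seed = 4)
  keys <- names(cmp$cv)
  expect_identical(cmp$cv[[keys[1]]]$folds, cmp$cv[[keys[2]]]$folds)
  expect_setequal(unique(cmp$table$method), c("CCA", "concat-only"))
  expect_error(compare_methods(d, methods = "nonsense"), "valid")
})

test_that("a strongly separable dataset is classified nearly perfectly", {
  d <- simulate_multimodal(sim_config(n_per_class = 15, n_classes = 2,
                                      modality_dims = c(10, 8, 3),
                                      class_separation = 4, noise_sd = 0.3,
                                      corrupt_frac = 0, missing_frac = 0.05,
                                      seed = 802))
  cmp <- suppressWarnings(compare_methods(
    d, methods = c("LDF", "KNN-concat", "CCA"),
    n_folds = 5, n_repeats = 1, seed = 5))
  accs <- subset(cmp$table, metric == "ACC")
  expect_true(all(accs$mean > 0.9))
})

test_that("the global (leaky) protocol runs and is labelled", {
  d <- simulate_multimodal(sim_config(n_per_class = 12, n_classes = 2,
                                      modality_dims = c(6, 5),
                                      corrupt_frac = 0, missing_frac = 0,
                                      seed = 803))
  pl <- ldf_pipeline(impute = "none", denoise = FALSE, fuse = "dca")
  cv <- repeated_cv(d, pl, n_folds = 3, n_repeats = 1, seed = 6,
                    preprocess = "global")
  expect_identical(cv$preprocess, "global")
  expect_true(is.finite(cv$auc))
})
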