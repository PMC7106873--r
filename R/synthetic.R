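#' Simulation settings for synthetic multimodal data
#'
#' Bundles and validates the parameters of [simulate_multimodal()]. The
#' defaults emulate the shape of a three-modality neuroimaging feature study:
#' three diagnostic groups and modality feature counts 93 (MRI regional
#' volumes), 93 (PET regional uptake) and 3 (CSF biomarkers), with a shared
#' low-rank latent signal, dense Gaussian noise, sample-wise (column-sparse)
#' gross corruption and missing-completely-at-random entries.
#'
#' @param n_per_class samples per class (>= 2).
#' @param n_classes number of classes; 3 gives labels NC/MCI/AD.
#' @param modality_dims integer vector of per-modality feature counts.
#' @param latent_rank dimension of the shared latent signal subspace (>= 1).
#' @param class_separation standard deviation of the per-class latent mean
#'   shifts; 0 produces label-independent data (a null dataset).
#' @param noise_sd standard deviation of the dense Gaussian noise.
#' @param corrupt_frac fraction of sample columns per modality receiving gross
#'   corruption (column-sparse, matching an L2,1 error model).
#' @param corrupt_sd standard deviation of the corruption added to a corrupted
#'   column's entries.
#' @param missing_frac per-modality fraction of masked cells (entry mode) or
#'   masked sample columns (block mode). Masking uses exact counts:
#'   `floor(missing_frac * N)` cells drawn without replacement, so missing
#'   counts are deterministic.
#' @param missing_mode `"entry"` for cell-level MCAR, `"block"` to mask whole
#'   modality columns per sample (per-modality subject availability).
#' @param seed RNG seed; identical configs give bit-identical datasets.
#' @return A list of class `sim_config`.
#' @seealso [simulate_multimodal()]
#' @export
sim_config <- function(n_per_class = 50, n_classes = 3,
                       modality_dims = c(93, 93, 3),
                       latent_rank = 5, class_separation = 1,
                       noise_sd = 0.5, corrupt_frac = 0.1, corrupt_sd = 5,
                       missing_frac = 0.1,
                       missing_mode = c("entry", "block"),
                       seed = 1) {
  check_scalar(n_per_class, "n_per_class", lower = 2, integer = TRUE)
  check_scalar(n_classes, "n_classes", lower = 2, integer = TRUE)
  if (!is.numeric(modality_dims) || length(modality_dims) < 1L ||
      any(modality_dims < 1) || any(modality_dims != round(modality_dims))) {
    config_error("'modality_dims' must be positive integers (one per modality)")
  }
  check_scalar(latent_rank, "latent_rank", lower = 1, integer = TRUE)
  check_scalar(class_separation, "class_separation", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(corrupt_frac, "corrupt_frac", lower = 0, upper = 1)
  check_scalar(corrupt_sd, "corrupt_sd", lower = 0)
  check_scalar(missing_frac, "missing_frac", lower = 0, upper = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_per_class = as.integer(n_per_class), n_classes = as.integer(n_classes),
    modality_dims = as.integer(modality_dims),
    latent_rank = as.integer(latent_rank),
    class_separation = class_separation, noise_sd = noise_sd,
    corrupt_frac = corrupt_frac, corrupt_sd = corrupt_sd,
    missing_frac = missing_frac, missing_mode = match.arg(missing_mode),
    seed = as.integer(seed)
  ), class = "sim_config")
}

default_class_names <- function(n_classes) {
  if (n_classes == 3L) c("NC", "MCI", "AD") else paste0("C", seq_len(n_classes))
}

#' Construct and validate a multimodal dataset
#'
#' A `multimodal_dataset` holds aligned per-modality feature matrices in the
#' columns-as-samples convention (features x samples, `NA` = missing) plus a
#' class label per sample.
#'
#' @param modalities named list of numeric matrices, all with the same number
#'   of columns (samples) in the same order; `NA` marks missing entries.
#' @param labels factor (or coercible) of length `n` samples.
#' @param sample_ids character sample identifiers (default S1..Sn).
#' @param ground_truth optional list with elements `clean` (list of noiseless
#'   matrices), `corrupt_cols` (list of corrupted column indices) and `masks`
#'   (list of logical missing masks), as produced by [simulate_multimodal()].
#' @return An object of class `multimodal_dataset`.
#' @export
multimodal_dataset <- function(modalities, labels, sample_ids = NULL,
                               ground_truth = NULL) {
  if (!is.list(modalities) || length(modalities) < 1L) {
    data_error("'modalities' must be a non-empty list of matrices")
  }
  modalities <- lapply(modalities, as.matrix)
  n <- ncol(modalities[[1L]])
  if (any(vapply(modalities, ncol, 1L) != n)) {
    data_error("all modalities must have the same number of sample columns")
  }
  if (is.null(names(modalities))) {
    names(modalities) <- paste0("modality", seq_along(modalities))
  }
  labels <- as.factor(labels)
  if (length(labels) != n) {
    data_error(sprintf("labels length (%d) must equal sample count (%d)",
                       length(labels), n))
  }
  if (any(table(labels) < 2L)) {
    data_error("every class must be present at least twice")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  all_missing <- Reduce(`&`, lapply(modalities, function(m) {
    colSums(!is.na(m)) == 0L
  }))
  if (any(all_missing)) {
    data_error(sprintf("sample(s) %s are entirely missing in every modality",
                       paste(sample_ids[all_missing], collapse = ", ")))
  }
  structure(list(modalities = modalities, labels = labels,
                 sample_ids = sample_ids, ground_truth = ground_truth),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("Multimodal dataset:", ncol(x$modalities[[1L]]), "samples,",
      length(x$modalities), "modalities\n")
  for (nm in names(x$modalities)) {
    m <- x$modalities[[nm]]
    cat(sprintf("  %s: %d features, %d missing cells\n",
                nm, nrow(m), sum(is.na(m))))
  }
  cat("Classes:", paste(sprintf("%s (%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic multimodal dataset with known structure
#'
#' Draws a shared latent signal `Z` (`latent_rank x n`, standard normal) with
#' per-class latent mean shifts of scale `class_separation`, projects it into
#' each modality through a random loading matrix, then adds dense Gaussian
#' noise, column-sparse gross corruption and exact-count MCAR missingness.
#' Because the class signal enters through latent means shared across
#' modalities, the cross-modal correlation is class-discriminative -- the
#' structure discriminant correlation analysis exploits -- and each clean
#' modality matrix has rank at most `latent_rank`.
#'
#' @param config a [sim_config()] object.
#' @return A [multimodal_dataset()] whose `ground_truth` element records the
#'   clean matrices, corrupted column indices and missing masks.
#' @examples
#' d <- simulate_multimodal(sim_config(n_per_class = 10,
#'                                     modality_dims = c(8, 6, 3), seed = 1))
#' mask_report(d)$per_modality
#' @export
simulate_multimodal <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_per_class * config$n_classes
  class_names <- default_class_names(config$n_classes)
  labels <- factor(rep(class_names, each = config$n_per_class),
                   levels = class_names)
  r <- config$latent_rank

  with_seed(config$seed, {
    mu <- matrix(stats::rnorm(r * config$n_classes,
                              sd = config$class_separation),
                 nrow = r)
    z <- matrix(stats::rnorm(r * n), nrow = r) + mu[, as.integer(labels), drop = FALSE]

    clean <- list(); observed <- list(); corrupt_cols <- list(); masks <- list()
    n_corrupt <- floor(config$corrupt_frac * n)
    for (m in seq_along(config$modality_dims)) {
      d <- config$modality_dims[m]
      loading <- matrix(stats::rnorm(d * r), nrow = d) / sqrt(r)
      cl <- loading %*% z
      obs <- cl + matrix(stats::rnorm(d * n, sd = config$noise_sd), nrow = d)
      cc <- integer(0)
      if (n_corrupt > 0) {
        cc <- sort(sample.int(n, n_corrupt))
        obs[, cc] <- obs[, cc] +
          matrix(stats::rnorm(d * n_corrupt, sd = config$corrupt_sd), nrow = d)
      }
      mask <- matrix(FALSE, d, n)
      if (config$missing_frac > 0) {
        if (config$missing_mode == "entry") {
          n_mask <- floor(config$missing_frac * d * n)
          if (n_mask > 0) mask[sample.int(d * n, n_mask)] <- TRUE
        } else {
          n_block <- floor(config$missing_frac * n)
          if (n_block > 0) mask[, sample.int(n, n_block)] <- TRUE
        }
      }
      clean[[m]] <- cl; observed[[m]] <- obs
      corrupt_cols[[m]] <- cc; masks[[m]] <- mask
    }

    # Block masking can (rarely) blank a sample in every modality; shift the
    # first modality's block off such samples to keep the dataset valid.
    if (length(masks) > 1L) {
      blocked <- vapply(masks, function(m) colSums(!m) == 0L,
                        logical(ncol(masks[[1L]])))
      fully_blocked <- rowSums(blocked) == ncol(blocked)
      for (j in which(fully_blocked)) {
        # candidate must be open in modality 1 and observed somewhere else
        other_open <- rowSums(blocked[, -1L, drop = FALSE]) <
          (ncol(blocked) - 1L)
        cand <- which(!blocked[, 1L] & other_open)
        masks[[1L]][, j] <- FALSE
        blocked[j, 1L] <- FALSE
        if (length(cand)) {
          masks[[1L]][, cand[1L]] <- TRUE
          blocked[cand[1L], 1L] <- TRUE
        }
      }
    }

    nm <- if (length(config$modality_dims) == 3L &&
              all(config$modality_dims == c(93L, 93L, 3L))) {
      c("MRI", "PET", "CSF")
    } else {
      paste0("modality", seq_along(config$modality_dims))
    }
    for (m in seq_along(observed)) {
      observed[[m]][masks[[m]]] <- NA_real_
      rownames(observed[[m]]) <- paste0(nm[m], "_f", seq_len(nrow(observed[[m]])))
    }
    names(observed) <- nm
    names(clean) <- nm
    names(corrupt_cols) <- nm
    names(masks) <- nm

    multimodal_dataset(observed, labels,
                       ground_truth = list(clean = clean,
                                           corrupt_cols = corrupt_cols,
                                           masks = masks,
                                           latent = z, config = config))
  })
}

#' Summarize missingness in a multimodal dataset
#'
#' @param dataset a [multimodal_dataset()].
#' @return A list with `per_modality` (data frame of missing-cell counts and
#'   fractions per modality) and `availability` (per-sample data frame of
#'   observed-entry counts per modality plus a `total_missing` column).
#' @export
mask_report <- function(dataset) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  mods <- dataset$modalities
  per_modality <- data.frame(
    modality = names(mods),
    n_cells = vapply(mods, length, 1L),
    n_missing = vapply(mods, function(m) sum(is.na(m)), 1L),
    row.names = NULL
  )
  per_modality$frac_missing <- per_modality$n_missing / per_modality$n_cells
  avail <- data.frame(sample_id = dataset$sample_ids)
  for (nm in names(mods)) {
    avail[[paste0(nm, "_observed")]] <- colSums(!is.na(mods[[nm]]))
    avail[[paste0(nm, "_missing")]] <- colSums(is.na(mods[[nm]]))
  }
  miss_cols <- grep("_missing$", names(avail))
  avail$total_missing <- rowSums(avail[, miss_cols, drop = FALSE])
  list(per_modality = per_modality, availability = avail)
}

#' Restrict a dataset to two classes for a binary task
#'
#' @param dataset a [multimodal_dataset()].
#' @param positive,negative class labels; the returned dataset keeps only
#'   these samples, with factor levels ordered `(negative, positive)`.
#' @return A `multimodal_dataset` with an attribute `positive`.
#' @export
subset_task <- function(dataset, positive, negative) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  lv <- levels(dataset$labels)
  if (!all(c(positive, negative) %in% lv)) {
    data_error(sprintf("classes must be among: %s", paste(lv, collapse = ", ")))
  }
  keep <- dataset$labels %in% c(positive, negative)
  gt <- dataset$ground_truth
  if (!is.null(gt)) {
    gt$clean <- lapply(gt$clean, function(m) m[, keep, drop = FALSE])
    gt$masks <- lapply(gt$masks, function(m) m[, keep, drop = FALSE])
    gt$corrupt_cols <- lapply(gt$corrupt_cols, function(cc) {
      match(intersect(cc, which(keep)), which(keep))
    })
  }
  out <- multimodal_dataset(
    lapply(dataset$modalities, function(m) m[, keep, drop = FALSE]),
    factor(as.character(dataset$labels[keep]), levels = c(negative, positive)),
    sample_ids = dataset$sample_ids[keep],
    ground_truth = gt
  )
  attr(out, "positive") <- positive
  out
}
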