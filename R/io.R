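# Tabular I/O and the end-to-end pipeline runner. CSV files are
# samples-as-rows with a leading sample-ID column (the ergonomic layout);
# matrices are transposed internally to the columns-as-samples convention the
# math modules use.

parse_feature_table <- function(path, missing_token = "NA") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) data_error(sprintf("'%s' needs an ID column plus features", path))
  ids <- trimws(df[[1L]])
  if (anyDuplicated(ids)) {
    data_error(sprintf("duplicate sample IDs in '%s': %s", path,
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  feat <- as.matrix(df[, -1L, drop = FALSE])
  num <- matrix(NA_real_, nrow(feat), ncol(feat),
                dimnames = dimnames(feat))
  for (jj in seq_len(ncol(feat))) {
    cell <- trimws(feat[, jj])
    is_missing <- cell == missing_token | cell == "" | is.na(cell)
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(val))
    if (length(bad)) {
      data_error(sprintf(
        "non-numeric cell '%s' at row %d, column '%s' of '%s' (not the missing token '%s')",
        feat[bad[1L], jj], bad[1L], colnames(feat)[jj], path, missing_token))
    }
    val[is_missing] <- NA_real_
    num[, jj] <- val
  }
  list(ids = ids, values = num)
}

#' Load aligned modality tables and labels from CSV
#'
#' Each modality CSV holds samples as rows with a leading sample-ID column;
#' missing entries are the `missing_token` or empty cells. Samples are
#' aligned across modalities by the intersection of IDs (a per-modality drop
#' report is attached), and every retained ID must have a class label.
#'
#' @param modality_paths named character vector of CSV paths.
#' @param labels_path CSV with columns `sample_id` (or first column) and
#'   `label`.
#' @param missing_token string marking a missing cell (default `"NA"`).
#' @return A [multimodal_dataset()]; attribute `"drop_report"` lists per
#'   modality how many IDs were dropped in the alignment.
#' @export
load_tables <- function(modality_paths, labels_path, missing_token = "NA") {
  if (is.null(names(modality_paths))) {
    names(modality_paths) <- tools::file_path_sans_ext(basename(modality_paths))
  }
  tabs <- lapply(modality_paths, parse_feature_table,
                 missing_token = missing_token)
  common <- Reduce(intersect, lapply(tabs, `[[`, "ids"))
  if (!length(common)) data_error("no sample IDs are shared by all modalities")
  drop_report <- data.frame(
    modality = names(tabs),
    n_samples = vapply(tabs, function(t) length(t$ids), 1L),
    n_dropped = vapply(tabs, function(t) length(setdiff(t$ids, common)), 1L),
    row.names = NULL)
  if (any(drop_report$n_dropped > 0)) {
    message(sprintf("alignment dropped samples: %s",
                    paste(sprintf("%s (%d)", drop_report$modality,
                                  drop_report$n_dropped), collapse = ", ")))
  }
  mods <- lapply(tabs, function(t) {
    m <- t(t$values[match(common, t$ids), , drop = FALSE])
    colnames(m) <- common
    m
  })
  ldf_df <- utils::read.csv(labels_path, colClasses = "character",
                            check.names = FALSE)
  lab_ids <- trimws(ldf_df[[1L]])
  lab_col <- if ("label" %in% names(ldf_df)) ldf_df[["label"]] else ldf_df[[2L]]
  idx <- match(common, lab_ids)
  if (anyNA(idx)) {
    data_error(sprintf("labels file is missing IDs: %s",
                       paste(common[is.na(idx)][1:min(5, sum(is.na(idx)))],
                             collapse = ", ")))
  }
  out <- multimodal_dataset(mods, factor(trimws(lab_col[idx])),
                            sample_ids = common)
  attr(out, "drop_report") <- drop_report
  out
}

#' Write a multimodal dataset to the CSV layout of [load_tables()]
#'
#' @param dataset a [multimodal_dataset()].
#' @param dir output directory (created if needed).
#' @param missing_token string written for missing cells.
#' @param ground_truth also write the clean matrices, corruption indices and
#'   masks (if present) under `dir/ground_truth/`.
#' @return Invisibly, the written file paths.
#' @export
write_dataset_csv <- function(dataset, dir, missing_token = "NA",
                              ground_truth = FALSE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(dataset$modalities)) {
    m <- dataset$modalities[[nm]]
    df <- data.frame(sample_id = dataset$sample_ids,
                     t(m), check.names = FALSE)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, na = missing_token)
    paths <- c(paths, p)
  }
  lp <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(sample_id = dataset$sample_ids,
                              label = as.character(dataset$labels)),
                   lp, row.names = FALSE)
  paths <- c(paths, lp)
  if (ground_truth && !is.null(dataset$ground_truth)) {
    gdir <- file.path(dir, "ground_truth")
    dir.create(gdir, showWarnings = FALSE)
    for (nm in names(dataset$ground_truth$clean)) {
      utils::write.csv(
        data.frame(sample_id = dataset$sample_ids,
                   t(dataset$ground_truth$clean[[nm]]), check.names = FALSE),
        file.path(gdir, paste0(nm, "_clean.csv")), row.names = FALSE)
    }
  }
  invisible(paths)
}

pipeline_config_defaults <- function() {
  list(
    simulate = NULL,
    inputs = NULL,
    methods = "LDF",
    tasks = NULL,
    pipeline = list(),
    cv = list(n_folds = 10L, n_repeats = 10L, preprocess = "fold"),
    seed = 1L,
    output_dir = "ldfuse_run"
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Unknown keys are rejected; missing keys take their defaults. Exactly one
#' of `simulate` (a [sim_config()] argument list) or `inputs`
#' (`list(modalities = <named paths>, labels = <path>, missing_token)`) must
#' be supplied.
#'
#' @param config a named list or path to a YAML file.
#' @return The resolved configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) config_error(sprintf("config file '%s' not found", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or YAML path")
  defaults <- pipeline_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    config_error(sprintf("unknown config key(s): %s (allowed: %s)",
                         paste(unknown, collapse = ", "),
                         paste(names(defaults), collapse = ", ")))
  }
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(out$simulate) == is.null(out$inputs)) {
    config_error("exactly one of 'simulate' or 'inputs' must be given")
  }
  if (!is.null(out$simulate)) {
    bad <- setdiff(names(out$simulate), names(formals(sim_config)))
    if (length(bad)) {
      config_error(sprintf("unknown simulate key(s): %s",
                           paste(bad, collapse = ", ")))
    }
  }
  bad <- setdiff(names(out$pipeline), names(formals(ldf_pipeline)))
  if (length(bad)) {
    config_error(sprintf("unknown pipeline key(s): %s",
                         paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(out$cv), c("n_folds", "n_repeats", "preprocess"))
  if (length(bad)) {
    config_error(sprintf("unknown cv key(s): %s", paste(bad, collapse = ", ")))
  }
  out$cv <- utils::modifyList(pipeline_config_defaults()$cv, out$cv)
  if (is.character(out$tasks)) {
    out$tasks <- lapply(strsplit(out$tasks, "/", fixed = TRUE), identity)
  }
  out
}

#' Run the full pipeline end to end
#'
#' Loads (or simulates) the multimodal dataset, evaluates the configured
#' methods on the configured binary tasks under leakage-safe repeated
#' stratified cross-validation, and writes the resolved config, a metrics
#' table, per-fold metrics, ROC points and a run manifest to the output
#' directory. Rerunning with the same config and seed reproduces every
#' output bit for bit.
#'
#' @param config list or YAML path accepted by [validate_config()].
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  out_dir <- cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character()
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))

  dataset <- timed("load", {
    if (!is.null(cfg$simulate)) {
      sc <- cfg$simulate
      if (is.null(sc$seed)) sc$seed <- cfg$seed
      simulate_multimodal(do.call(sim_config, sc))
    } else {
      load_tables(unlist(cfg$inputs$modalities), cfg$inputs$labels,
                  cfg$inputs$missing_token %||% "NA")
    }
  })

  cmp <- timed("evaluate", {
    compare_methods(dataset, methods = cfg$methods, tasks = cfg$tasks,
                    n_folds = cfg$cv$n_folds, n_repeats = cfg$cv$n_repeats,
                    seed = cfg$seed, preprocess = cfg$cv$preprocess)
  })

  timed("write", {
    utils::write.csv(cmp$table, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    per_fold <- do.call(rbind, lapply(names(cmp$cv), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      cbind(method = parts[1L], task = parts[2L], cmp$cv[[key]]$per_fold)
    }))
    utils::write.csv(per_fold, file.path(out_dir, "per_fold.csv"),
                     row.names = FALSE)
    roc <- do.call(rbind, lapply(names(cmp$cv), function(key) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
      cbind(method = parts[1L], task = parts[2L], cmp$cv[[key]]$roc_points)
    }))
    utils::write.csv(roc, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
  })

  outputs <- c("config_resolved.yaml", "metrics.csv", "per_fold.csv",
               "roc_points.csv")
  checksums <- tools::md5sum(file.path(out_dir, outputs))
  names(checksums) <- outputs
  manifest <- list(
    package = "ldfuse",
    version = as.character(utils::packageVersion("ldfuse")),
    seed = cfg$seed,
    config = cfg,
    stage_seconds = timings,
    warnings = warnings_seen,
    output_checksums = as.list(checksums)
  )
  tmp <- file.path(out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
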