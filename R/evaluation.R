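#' Label dimensions of the accuracy grid
#'
#' Mental-demand and situational-stress mean-binarized labels coincide with
#' group membership in cohorts with the published group separation, so the
#' grid carries a single combined experience/mental/stress row (computed from
#' group membership) alongside the other workload dimensions and the
#' dissection outcome.
#'
#' @return Character vector of the six grid row names.
#' @export
grid_dimensions <- function() {
  c("experience_mental_stress", "physical", "temporal", "complexity",
    "distractions", "outcome")
}

#' Channel subsets of the accuracy grid
#'
#' @return The ten subset names: seven single-source subsets and three
#'   combinations.
#' @export
grid_subsets <- function() {
  c("forcex", "forcey", "forcez", "forcexyz", "Dxy", "Sxy", "Cxy",
    "Dxy,Sxy,Cxy,forcexyz", "Dxy,Sxy,forcexyz", "Dxy,Sxy,forcez")
}

resolve_labels <- function(dataset, dimension) {
  if (dimension == "experience_mental_stress") {
    experience_labels(dataset)
  } else {
    trial_labels(dataset, dimension)
  }
}

default_trainer <- function(config, train_series, train_labels) {
  train_fcn(config, train_series, train_labels)$model
}

#' Leave-one-out cross-validation
#'
#' For each trial, per-channel normalization statistics and the classifier
#' are fit on the remaining trials only, and the held-out trial is predicted;
#' accuracy is the mean 0/1 correctness over all folds. A fold whose training
#' set collapses to a single class predicts that class (LOOCV over a small
#' unbalanced cohort must always complete). Per-fold training seed is
#' `master_seed + fold index`, so folds are independent but reproducible.
#'
#' @param series_list Padded, unnormalized `assembled_series` list (>= 3).
#' @param labels A `binary_labels` object or named 0/1 vector aligned with
#'   the series' trial ids.
#' @param subset Channel subset name or index vector (see
#'   [resolve_channels()]); `NULL` keeps all channels.
#' @param config An [fcn_config()] for the per-fold classifier.
#' @param master_seed Base seed for the per-fold seeds.
#' @param trainer,predictor Classifier interface,
#'   `trainer(config, train_series, train_labels) -> model` and
#'   `predictor(model, series) -> 0/1`; defaults train and apply the FCN.
#' @return List of class `cv_result`: `folds` data.frame (`trial_id`,
#'   `truth`, `pred`), `mean_accuracy`, `n_folds`.
#' @export
loocv <- function(series_list, labels, subset = NULL,
                  config = fcn_config(), master_seed = 1L,
                  trainer = default_trainer, predictor = fcn_predict) {
  n <- length(series_list)
  if (n < 3L) stop("LOOCV needs at least 3 trials")
  ids <- vapply(series_list, function(s) s$trial_id, "")
  y <- if (inherits(labels, "binary_labels")) labels$labels else labels
  if (!is.null(names(y))) y <- y[ids]
  y <- as.integer(y)
  if (any(is.na(y))) stop("labels missing for some trials")
  if (length(unique(y)) < 2L) stop("both classes must be present overall")

  if (!is.null(subset)) {
    series_list <- lapply(series_list, select_channels, subset = subset)
  }
  preds <- integer(n)
  for (i in seq_len(n)) {
    tr <- series_list[-i]
    ytr <- y[-i]
    st <- channel_stats(tr)
    tr <- lapply(tr, apply_normalization, stats_ = st)
    te <- apply_normalization(series_list[[i]], st)
    if (length(unique(ytr)) < 2L) {
      preds[i] <- ytr[1]
    } else {
      cfg <- config
      cfg$seed <- as.integer(master_seed + i)
      model <- trainer(cfg, tr, ytr)
      preds[i] <- predictor(model, te)
    }
  }
  folds <- data.frame(trial_id = ids, truth = y, pred = preds,
                      stringsAsFactors = FALSE)
  structure(list(folds = folds, mean_accuracy = mean(preds == y),
                 n_folds = n), class = "cv_result")
}

#' LOOCV accuracy grid over label dimensions and channel subsets
#'
#' Runs [loocv()] for every (label dimension, channel subset) pair;
#' deterministic given `master_seed`.
#'
#' @param series_list Padded `assembled_series` list for the cohort.
#' @param dataset Workload data.frame from [workload_dataset()].
#' @param config An [fcn_config()].
#' @param dimensions,subsets Grid rows/columns (defaults:
#'   [grid_dimensions()], [grid_subsets()]).
#' @param master_seed Base seed; each cell uses an offset so cells are
#'   independent.
#' @inheritParams loocv
#' @return List of class `results_grid`: `accuracy` (dimensions x subsets
#'   matrix), `cells` (named list of `cv_result`s), `master_seed`.
#' @export
full_grid <- function(series_list, dataset, config = fcn_config(),
                      dimensions = grid_dimensions(),
                      subsets = grid_subsets(), master_seed = 1L,
                      trainer = default_trainer, predictor = fcn_predict) {
  acc <- matrix(NA_real_, length(dimensions), length(subsets),
                dimnames = list(dimensions, subsets))
  cells <- list()
  for (i in seq_along(dimensions)) {
    lab <- resolve_labels(dataset, dimensions[i])
    for (j in seq_along(subsets)) {
      cell_seed <- master_seed + 1000L * ((i - 1L) * length(subsets) + j)
      cv <- loocv(series_list, lab, subsets[j], config, cell_seed,
                  trainer, predictor)
      acc[i, j] <- cv$mean_accuracy
      cells[[paste(dimensions[i], subsets[j], sep = "|")]] <- cv
    }
  }
  structure(list(accuracy = acc, cells = cells, master_seed = master_seed),
            class = "results_grid")
}

#' Write grid and workload reports
#'
#' Writes `results_grid.csv`, a Markdown `results_grid.md` with the best cell
#' flagged, per-cell fold predictions under `folds/`, the workload statistics
#' table when given, and `run_config.json`. Re-running on the same inputs
#' produces byte-identical files.
#'
#' @param grid A `results_grid`.
#' @param out Output directory (created if needed).
#' @param stats Optional data.frame from [group_workload_stats()].
#' @param config Optional [fcn_config()] echoed into `run_config.json`.
#' @return Invisibly, the output directory.
#' @export
write_report <- function(grid, out, stats = NULL, config = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  acc <- grid$accuracy
  utils::write.csv(data.frame(dimension = rownames(acc), acc,
                              check.names = FALSE),
                   file.path(out, "results_grid.csv"), row.names = FALSE)

  best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  lines <- c("# LOOCV accuracy grid", "",
             paste0("| dimension | ", paste(colnames(acc), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(acc) + 1L), collapse = "|"), "|"))
  for (i in seq_len(nrow(acc))) {
    cells <- sprintf("%.2f", acc[i, ])
    if (i == best[1]) cells[best[2]] <- paste0("**", cells[best[2]], "**")
    lines <- c(lines, paste0("| ", rownames(acc)[i], " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  lines <- c(lines, "",
             sprintf("Best cell: %s x %s = %.2f", rownames(acc)[best[1]],
                     colnames(acc)[best[2]], max(acc)))
  if (!is.null(stats)) {
    lines <- c(lines, "", "## Group workload comparison", "",
               "| dimension | MP mean (SD) | CG mean (SD) | p | |",
               "|---|---|---|---|---|",
               vapply(seq_len(nrow(stats)), function(i) {
                 sprintf("| %s | %.2f (%.2f) | %.2f (%.2f) | %.3g | %s |",
                         stats$dimension[i], stats$mp_mean[i], stats$mp_sd[i],
                         stats$cg_mean[i], stats$cg_sd[i], stats$p[i],
                         stats$annotation[i])
               }, ""))
    utils::write.csv(stats, file.path(out, "workload_stats.csv"),
                     row.names = FALSE)
  }
  writeLines(lines, file.path(out, "results_grid.md"))

  fold_dir <- file.path(out, "folds")
  dir.create(fold_dir, showWarnings = FALSE)
  for (nm in names(grid$cells)) {
    fn <- gsub("[^A-Za-z0-9_]+", "_", nm)
    utils::write.csv(grid$cells[[nm]]$folds,
                     file.path(fold_dir, paste0(fn, ".csv")), row.names = FALSE)
  }
  run <- list(master_seed = grid$master_seed)
  if (!is.null(config)) run$fcn_config <- unclass(config)
  jsonlite::write_json(run, file.path(out, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
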