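make_series_set <- function(n = 10, tt = 30) {
  set.seed(41)
  lapply(seq_len(n), function(i)
    as_series(matrix(rnorm(tt * 9), tt, 9,
                     dimnames = list(NULL, series_channels())),
              sprintf("t%02d", i)))
}

test_that("LOOCV runs one singleton fold per trial and scores exactly", {
  series <- make_series_set(20)
  truth <- stats::setNames(rep(c(0L, 1L), 10),
                           vapply(series, function(s) s$trial_id, ""))
  cv <- loocv(series, truth, "forcez", fcn_config(epochs = 1L),
              trainer = oracle_trainer(truth),
              predictor = oracle_predictor)
  expect_equal(cv$n_folds, 20)
  expect_equal(nrow(cv$folds), 20)
  expect_equal(cv$folds$trial_id, names(truth))
  expect_equal(cv$mean_accuracy, 1.0)
  expect_equal(cv$mean_accuracy, mean(cv$folds$pred == cv$folds$truth))

  # a fixed (label-independent) predictor scores 1 - a under flipped labels
  fixed_pred <- stats::setNames(rep(c(0L, 0L, 1L, 1L), 5), names(truth))
  pred_fixed <- function(model, series) fixed_pred[[series$trial_id]]
  a1 <- loocv(series, truth, "forcez", fcn_config(epochs = 1L),
              trainer = oracle_trainer(truth), predictor = pred_fixed)
  flipped <- stats::setNames(1L - truth, names(truth))
  a2 <- loocv(series, flipped, "forcez", fcn_config(epochs = 1L),
              trainer = oracle_trainer(truth), predictor = pred_fixed)
  expect_equal(a2$mean_accuracy, 1 - a1$mean_accuracy)

  expect_error(loocv(series[1:2], truth[1:2]), "at least 3")
  expect_error(loocv(series, stats::setNames(rep(0L, 20), names(truth))),
               "both classes")
})

test_that("single-class training folds fall back to the majority class", {
  series <- make_series_set(5)
  # one lone class-1 trial: its fold trains on class 0 only
  truth <- stats::setNames(c(1L, 0L, 0L, 0L, 0L),
                           vapply(series, function(s) s$trial_id, ""))
  called <- 0L
  tr <- function(config, train_series, train_labels) {
    called <<- called + 1L
    list(truth = truth)
  }
  cv <- loocv(series, truth, NULL, fcn_config(epochs = 1L),
              trainer = tr, predictor = oracle_predictor)
  expect_equal(called, 4L)                  # fold 1 never trains
  expect_equal(cv$folds$pred[1], 0L)        # majority-class fallback
})

test_that("the accuracy grid covers six dimensions by ten subsets", {
  coh <- small_cohort(seed = 51L, len = c(40L, 60L))
  series <- assemble_cohort(coh)
  ds <- workload_dataset(coh)
  truth <- stats::setNames(experience_labels(ds)$labels, ds$trial_id)
  grid <- full_grid(series, ds, fcn_config(epochs = 1L),
                    trainer = oracle_trainer(truth),
                    predictor = oracle_predictor, master_seed = 5L)
  expect_equal(dim(grid$accuracy), c(6L, 10L))
  expect_equal(rownames(grid$accuracy), grid_dimensions())
  expect_equal(colnames(grid$accuracy), grid_subsets())
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  expect_equal(length(grid$cells), 60)
  # oracle stub is right on the experience row by construction
  expect_true(all(grid$accuracy["experience_mental_stress", ] == 1))
})

test_that("reports are complete and byte-identical across re-runs", {
  coh <- small_cohort(seed = 52L, len = c(40L, 60L))
  series <- assemble_cohort(coh)
  ds <- workload_dataset(coh)
  truth <- stats::setNames(experience_labels(ds)$labels, ds$trial_id)
  grid <- full_grid(series, ds, fcn_config(epochs = 1L),
                    dimensions = c("experience_mental_stress", "temporal"),
                    subsets = c("forcez", "Dxy"),
                    trainer = oracle_trainer(truth),
                    predictor = oracle_predictor, master_seed = 6L)
  stats_tab <- group_workload_stats(summary = surgtlx_group_params())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(grid, d1, stats = stats_tab, config = fcn_config())
  write_report(grid, d2, stats = stats_tab, config = fcn_config())
  for (f in c("results_grid.csv", "results_grid.md", "workload_stats.csv",
              "run_config.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  md <- readLines(file.path(d1, "results_grid.md"))
  expect_true(any(grepl("\\*\\*1\\.00\\*\\*", md)))   # best cell flagged
  expect_true(any(grepl("results_grid", list.files(d1))))
  expect_equal(length(list.files(file.path(d1, "folds"))), 4)
})

test_that("the full pipeline is deterministic end to end", {
  run_once <- function() {
    coh <- small_cohort(seed = 53L, len = c(40L, 80L))
    series <- assemble_cohort(coh, stride = 2L)
    ds <- workload_dataset(coh)
    cv <- loocv(series, binarize_labels(ds, "temporal"), "forcez",
                fcn_config(filters = c(4L, 4L, 4L), epochs = 3L),
                master_seed = 7L)
    cv$folds$pred
  }
  expect_identical(run_once(), run_once())
})
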