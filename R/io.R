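# Full-precision CSV: doubles written with %.17g round-trip bit-exactly.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a cohort to its on-disk layout
#'
#' One directory per trial containing `frames.csv` (frame index, time and
#' per-tool x/y/valid columns), `force.csv` (time and 3-axis force) and
#' `meta.json` (subject, group, trial index, outcome, SURG-TLX scores), plus
#' a cohort-level `manifest.json` listing the trial directories and the
#' generator configuration. Numeric columns are written in full precision so
#' a read-back reproduces values bit-exactly.
#'
#' @param cohort List of trials from [generate_cohort()].
#' @param dir Output directory.
#' @param config Optional [generator_config()] echoed into the manifest.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in cohort) {
    td <- file.path(dir, tr$trial_id)
    dir.create(td, showWarnings = FALSE)
    meta <- list(trial_id = tr$trial_id, subject_id = tr$subject_id,
                 group = tr$group, trial_index = tr$trial_index,
                 outcome = tr$outcome,
                 surgtlx = tr$response[surgtlx_dimensions()])
    jsonlite::write_json(meta, file.path(td, "meta.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(tr$frame_times)) {
      fdf <- data.frame(frame_index = seq_along(tr$frame_times) - 1L,
                        time_s = tr$frame_times)
      for (tool in names(tr$tracks)) {
        tk <- tr$tracks[[tool]]
        fdf[[paste0(tool, "_x")]] <- tk$x
        fdf[[paste0(tool, "_y")]] <- tk$y
        fdf[[paste0(tool, "_valid")]] <- as.integer(tk$valid)
      }
      write_csv_exact(fdf, file.path(td, "frames.csv"))
      write_csv_exact(data.frame(time_s = tr$force$time, fx = tr$force$fx,
                                 fy = tr$force$fy, fz = tr$force$fz),
                      file.path(td, "force.csv"))
    }
  }
  manifest <- list(trials = vapply(cohort, function(tr) tr$trial_id, ""),
                   n_trials = length(cohort))
  if (!is.null(config)) {
    manifest$config <- unclass(config)
    manifest$config$surgtlx_params <- NULL
    manifest$seed <- config$seed
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return List of trials in manifest order.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lapply(manifest$trials, function(id) {
    td <- file.path(dir, id)
    meta <- jsonlite::read_json(file.path(td, "meta.json"),
                                simplifyVector = TRUE)
    tr <- list(trial_id = meta$trial_id, subject_id = meta$subject_id,
               group = meta$group, trial_index = meta$trial_index,
               outcome = meta$outcome,
               response = do.call(surgtlx_response, as.list(meta$surgtlx)))
    fpath <- file.path(td, "frames.csv")
    if (file.exists(fpath)) {
      fdf <- utils::read.csv(fpath)
      tr$frame_times <- fdf$time_s
      tools <- c("dissector", "scissors", "clipper")
      tr$tracks <- lapply(stats::setNames(tools, tools), function(tool) {
        data.frame(x = fdf[[paste0(tool, "_x")]],
                   y = fdf[[paste0(tool, "_y")]],
                   valid = fdf[[paste0(tool, "_valid")]] == 1L)
      })
      fo <- utils::read.csv(file.path(td, "force.csv"))
      tr$force <- data.frame(time = fo$time_s, fx = fo$fx, fy = fo$fy,
                             fz = fo$fz)
    }
    tr
  })
}

#' Write assembled series to disk
#'
#' One full-precision CSV per trial (`series/<trial_id>.csv`, frame index
#' plus the nine channels) and a `series_manifest.json` with the template
#' length and channel order.
#'
#' @param series_list List of `assembled_series`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_series <- function(series_list, dir) {
  sd_ <- file.path(dir, "series")
  dir.create(sd_, recursive = TRUE, showWarnings = FALSE)
  for (s in series_list) {
    df <- data.frame(frame_index = seq_len(nrow(s$values)) - 1L, s$values,
                     check.names = FALSE)
    write_csv_exact(df, file.path(sd_, paste0(s$trial_id, ".csv")))
  }
  jsonlite::write_json(
    list(trials = vapply(series_list, function(s) s$trial_id, ""),
         template_length = nrow(series_list[[1]]$values),
         original_lengths = vapply(series_list,
                                   function(s) s$original_length, 1L),
         channels = series_list[[1]]$channel_names),
    file.path(dir, "series_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read assembled series from disk
#'
#' @param dir Directory written by [write_series()].
#' @return List of `assembled_series`.
#' @export
read_series <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "series_manifest.json"),
                             simplifyVector = TRUE)
  lapply(seq_along(man$trials), function(i) {
    df <- utils::read.csv(file.path(dir, "series",
                                    paste0(man$trials[i], ".csv")),
                          check.names = FALSE)
    vals <- as.matrix(df[, man$channels, drop = FALSE])
    structure(list(trial_id = man$trials[i], values = vals,
                   channel_names = man$channels,
                   original_length = man$original_lengths[i]),
              class = "assembled_series")
  })
}

#' Write a tool track to CSV
#'
#' @param track data.frame from [track_sequence()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path) {
  write_csv_exact(track, path)
  invisible(path)
}
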