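#' Fixed channel order of the assembled series
#'
#' @return The nine channel names: dissector, scissors and clipper x/y pixel
#'   coordinates followed by the three force axes.
#' @export
series_channels <- function() {
  c("dissector_x", "dissector_y", "scissors_x", "scissors_y",
    "clipper_x", "clipper_y", "force_x", "force_y", "force_z")
}

#' Synchronize force samples to frame timestamps
#'
#' Each frame receives the force sample whose timestamp is nearest; an exact
#' equidistant tie resolves to the earlier sample.
#'
#' @param force data.frame with `time`, `fx`, `fy`, `fz` (time strictly
#'   increasing and spanning the frame times).
#' @param frame_times Strictly increasing frame timestamps, seconds.
#' @return data.frame `fx`, `fy`, `fz`, one row per frame.
#' @export
synchronize <- function(force, frame_times) {
  ft <- force$time
  if (is.unsorted(ft, strictly = TRUE) ||
      is.unsorted(frame_times, strictly = TRUE)) {
    stop("time vectors must be strictly increasing")
  }
  if (frame_times[1] < ft[1] || frame_times[length(frame_times)] > ft[length(ft)]) {
    stop("frame times fall outside the force sampling span")
  }
  lo <- findInterval(frame_times, ft)            # ft[lo] <= t < ft[lo+1]
  hi <- pmin(lo + 1L, length(ft))
  # later sample only when strictly nearer (beyond float jitter):
  # an equidistant tie keeps the earlier sample
  tol <- 1e-9 * pmax(1, abs(frame_times))
  idx <- ifelse((frame_times - ft[lo]) - (ft[hi] - frame_times) > tol, hi, lo)
  data.frame(fx = force$fx[idx], fy = force$fy[idx], fz = force$fz[idx])
}

#' Assemble a trial's nine-channel series
#'
#' Stacks the three tool tracks (x, y each) and the frame-synchronized force
#' axes in the fixed [series_channels()] order. Frames on which a tool is
#' invalid or absent carry 0 in its channels, the same fill value as
#' end-padding, so "missing" and "padded" share one semantics.
#'
#' @param tracks Named list (`dissector`, `scissors`, `clipper`) of
#'   data.frames with `x`, `y` and logical `valid`, aligned to `frame_times`.
#' @param force_sync data.frame from [synchronize()] (one row per frame).
#' @param frame_times Frame timestamps (defines the trial length).
#' @param trial_id Identifier carried in the result.
#' @return An `assembled_series`: list with `trial_id`, `values`
#'   (T x 9 matrix), `channel_names`, `original_length`.
#' @export
assemble_series <- function(tracks, force_sync, frame_times,
                            trial_id = NA_character_) {
  n <- length(frame_times)
  vals <- matrix(0, n, 9L, dimnames = list(NULL, series_channels()))
  for (j in seq_along(c("dissector", "scissors", "clipper"))) {
    tool <- c("dissector", "scissors", "clipper")[j]
    tk <- tracks[[tool]]
    if (is.null(tk)) next
    if (nrow(tk) != n) stop("track length does not match the frame count")
    v <- if (is.null(tk$valid)) rep(TRUE, n) else tk$valid
    vals[, 2 * j - 1] <- ifelse(v, tk$x, 0)
    vals[, 2 * j] <- ifelse(v, tk$y, 0)
  }
  if (nrow(force_sync) != n) stop("force rows do not match the frame count")
  vals[, 7] <- force_sync$fx; vals[, 8] <- force_sync$fy
  vals[, 9] <- force_sync$fz
  structure(list(trial_id = trial_id, values = vals,
                 channel_names = series_channels(), original_length = n),
            class = "assembled_series")
}

#' Assemble every trial of a cohort
#'
#' Convenience wrapper: synchronizes and assembles each trial, optionally
#' stride-downsampling (every `stride`-th frame, before padding) for
#' desk-scale classifier runs, then zero-pads all series to the longest.
#'
#' @param cohort List of trials from [generate_cohort()] (with signals).
#' @param stride Integer downsampling stride (1 = keep every frame).
#' @param pad If `TRUE`, pad the list to a common template length.
#' @return List of `assembled_series`.
#' @export
assemble_cohort <- function(cohort, stride = 1L, pad = TRUE) {
  out <- lapply(cohort, function(tr) {
    if (is.null(tr$frame_times)) stop("trial has no signals to assemble")
    fs <- synchronize(tr$force, tr$frame_times)
    s <- assemble_series(tr$tracks, fs, tr$frame_times, tr$trial_id)
    if (stride > 1L) {
      keep <- seq(1L, s$original_length, by = as.integer(stride))
      s$values <- s$values[keep, , drop = FALSE]
      s$original_length <- length(keep)
    }
    s
  })
  if (pad) out <- pad_to_template(out) else out
}

#' Zero-pad series to a common template length
#'
#' The template is the maximum `original_length` in the list; every series is
#' padded at the end with all-zero rows to that length (classifier-readable
#' equal-length format). Idempotent.
#'
#' @param series_list Non-empty list of `assembled_series`.
#' @return The list with every `values` matrix having `template` rows.
#' @export
pad_to_template <- function(series_list) {
  if (length(series_list) == 0L) stop("empty series list")
  template <- max(vapply(series_list, function(s) s$original_length, 1L))
  lapply(series_list, function(s) {
    nr <- nrow(s$values)
    if (nr < template) {
      s$values <- rbind(s$values,
                        matrix(0, template - nr, ncol(s$values),
                               dimnames = list(NULL, colnames(s$values))))
    }
    s
  })
}

#' Resolve a channel-subset name
#'
#' Subset names are comma-separated tokens: `forcex`, `forcey`, `forcez`,
#' `forcexyz`, `Dxy` (dissector), `Sxy` (scissors), `Cxy` (clipper);
#' case-insensitive, whitespace ignored.
#'
#' @param name Subset name, e.g. `"forcez"` or `"Dxy,Sxy,forcez"`.
#' @return Integer vector of channel indices (1-based into
#'   [series_channels()]).
#' @export
resolve_channels <- function(name) {
  map <- list(forcex = 7L, forcey = 8L, forcez = 9L, forcexyz = 7:9,
              dxy = 1:2, sxy = 3:4, cxy = 5:6, all = 1:9)
  tokens <- tolower(gsub("[[:space:]]", "", strsplit(name, ",")[[1]]))
  if (!length(tokens) || !all(tokens %in% names(map))) {
    stop("unknown channel subset: ", name)
  }
  idx <- unlist(map[tokens], use.names = FALSE)
  if (anyDuplicated(idx)) stop("channel subset repeats channels: ", name)
  idx
}

#' Project a series onto a channel subset
#'
#' @param series An `assembled_series`.
#' @param subset Subset name (see [resolve_channels()]) or integer indices.
#' @return The series restricted to those channels (order and padding
#'   preserved).
#' @export
select_channels <- function(series, subset) {
  idx <- if (is.character(subset)) resolve_channels(subset) else as.integer(subset)
  if (any(idx < 1L | idx > ncol(series$values))) stop("channel index out of range")
  series$values <- series$values[, idx, drop = FALSE]
  series$channel_names <- series$channel_names[idx]
  series
}

#' Per-channel normalization statistics from training trials
#'
#' Means and SDs are computed over the unpadded rows of the training trials
#' only, so a held-out trial never influences its own scaling.
#'
#' @param train_list Non-empty list of `assembled_series`.
#' @return List with `mean` and `sd` vectors (one entry per channel).
#' @export
channel_stats <- function(train_list) {
  if (length(train_list) == 0L) stop("empty training list")
  rows <- do.call(rbind, lapply(train_list, function(s) {
    s$values[seq_len(s$original_length), , drop = FALSE]
  }))
  list(mean = colMeans(rows), sd = apply(rows, 2, stats::sd))
}

#' Apply z-normalization to a series
#'
#' Unpadded rows are centered and scaled per channel with the supplied
#' training statistics; padded rows stay exactly 0 (the padding value is the
#' post-normalization mean). A zero-SD channel is centered only.
#'
#' @param series An `assembled_series`.
#' @param stats_ Output of [channel_stats()].
#' @return The normalized series.
#' @export
apply_normalization <- function(series, stats_) {
  sd_ <- ifelse(stats_$sd > 0, stats_$sd, 1)
  n <- series$original_length
  v <- series$values
  v[seq_len(n), ] <- sweep(sweep(v[seq_len(n), , drop = FALSE], 2, stats_$mean),
                           2, sd_, "/")
  if (nrow(v) > n) v[(n + 1):nrow(v), ] <- 0
  series$values <- v
  series
}

#' Normalize a list of series from training statistics
#'
#' @param train_list Series used to compute the statistics.
#' @param apply_list Series to normalize (default: the training list).
#' @return Normalized `apply_list`.
#' @export
normalize_series <- function(train_list, apply_list = train_list) {
  st <- channel_stats(train_list)
  lapply(apply_list, apply_normalization, stats_ = st)
}
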