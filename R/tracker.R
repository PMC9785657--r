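#' Tracker configuration
#'
#' Defaults are conventional discriminative-correlation-filter settings: a
#' search window 2.5x the RoI, Gaussian label sigma at 1/16 of the template
#' width, ridge regularizer 1e-3, learning rate 0.02, and a
#' peak-to-sidelobe-ratio (PSR) failure threshold of 5.
#'
#' @param search_factor Template size as a multiple of the RoI size.
#' @param sigma_factor Gaussian label sigma as a fraction of template width.
#' @param lambda Ridge regularizer of the filter.
#' @param eta Exponential learning rate for filter and channel weights.
#' @param psr_threshold PSR below which a frame is flagged as lost.
#' @param psr_exclude Half-size of the peak exclusion window for PSR.
#' @return List of class `tracker_config`.
#' @export
tracker_config <- function(search_factor = 2.5, sigma_factor = 1 / 16,
                           lambda = 1e-3, eta = 0.02,
                           psr_threshold = 5, psr_exclude = 5L) {
  structure(list(search_factor = search_factor, sigma_factor = sigma_factor,
                 lambda = lambda, eta = eta, psr_threshold = psr_threshold,
                 psr_exclude = as.integer(psr_exclude)),
            class = "tracker_config")
}

#' Region of interest
#'
#' 0-based top-left corner and size; the RoI covers the half-open pixel
#' rectangle \[x, x+w) x \[y, y+h) and must be at least 8 px on a side.
#'
#' @param x,y Top-left pixel (0-based).
#' @param w,h Width and height in pixels (>= 8).
#' @return List of class `roi`.
#' @export
roi <- function(x, y, w, h) {
  if (w < 8 || h < 8) stop("RoI must be at least 8x8 pixels")
  structure(list(x = x, y = y, w = w, h = h), class = "roi")
}

frame_dims <- function(frame) {
  d <- dim(frame)
  if (is.null(d) || length(d) < 2L) stop("frame must be a matrix or H x W x 3 array")
  c(h = d[1], w = d[2], ch = if (length(d) == 3L) d[3] else 1L)
}

check_roi_in_frame <- function(r, frame) {
  d <- frame_dims(frame)
  if (r$x < 0 || r$y < 0 || r$x + r$w > d[["w"]] || r$y + r$h > d[["h"]]) {
    stop("RoI falls outside the frame")
  }
}

# Extract a th x tw patch centered on (cx, cy) (0-based continuous pixel
# coords), replicating border pixels where the window leaves the frame.
extract_patch <- function(frame, cx, cy, th, tw) {
  d <- frame_dims(frame)
  # half-up rounding commutes with integer frame shifts (round() does not)
  rows <- floor(cy + 0.5) + 1 + seq_len(th) - 1 - (th - 1) %/% 2
  cols <- floor(cx + 0.5) + 1 + seq_len(tw) - 1 - (tw - 1) %/% 2
  rows <- pmin(pmax(rows, 1L), d[["h"]])
  cols <- pmin(pmax(cols, 1L), d[["w"]])
  if (d[["ch"]] == 1L) frame[rows, cols, drop = FALSE] else frame[rows, cols, ]
}

# Feature channels: for RGB input, intensity + two chroma channels; for
# grayscale, intensity + horizontal and vertical gradients. Each channel is
# standardized and tapered with a Hann window.
patch_features <- function(patch, window) {
  if (length(dim(patch)) == 3L) {
    r <- patch[, , 1]; g <- patch[, , 2]; b <- patch[, , 3]
    ch <- list((r + g + b) / 3, r - g, b - (r + g) / 2)
  } else {
    gx <- (patch[, c(2:ncol(patch), ncol(patch))] -
           patch[, c(1, 1:(ncol(patch) - 1))]) / 2
    gy <- (patch[c(2:nrow(patch), nrow(patch)), ] -
           patch[c(1, 1:(nrow(patch) - 1)), ]) / 2
    ch <- list(patch, gx, gy)
  }
  lapply(ch, function(x) ((x - mean(x)) / (stats::sd(x) + 1e-5)) * window)
}

hann2 <- function(th, tw) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(th) - 1) / (th - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(tw) - 1) / (tw - 1))
  outer(wr, wc)
}

gaussian_label <- function(th, tw, sigma) {
  r0 <- (th - 1) %/% 2 + 1; c0 <- (tw - 1) %/% 2 + 1
  d2 <- outer((seq_len(th) - r0)^2, (seq_len(tw) - c0)^2, "+")
  exp(-d2 / (2 * sigma^2))
}

#' Initialize a correlation-filter tracker
#'
#' Learns a per-channel ridge-regression correlation filter in the frequency
#' domain from the windowed feature channels of the patch around the RoI,
#' with a Gaussian target response; channel reliability weights start
#' uniform.
#'
#' @param frame Grayscale matrix (H x W, values in \[0,1\]) or H x W x 3
#'   RGB array.
#' @param r A [roi()] fully inside the frame.
#' @param config A [tracker_config()].
#' @return A `tracker_state` list.
#' @export
init_tracker <- function(frame, r, config = tracker_config()) {
  stopifnot(inherits(r, "roi"))
  check_roi_in_frame(r, frame)
  th <- 2 * floor(r$h * config$search_factor / 2) + 1
  tw <- 2 * floor(r$w * config$search_factor / 2) + 1
  cx <- r$x + r$w / 2; cy <- r$y + r$h / 2
  window <- hann2(th, tw)
  g <- gaussian_label(th, tw, config$sigma_factor * tw)
  ghat <- stats::fft(g)
  feats <- patch_features(extract_patch(frame, cx, cy, th, tw), window)
  A <- vector("list", length(feats)); B <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    fhat <- stats::fft(feats[[i]])
    A[[i]] <- ghat * Conj(fhat)
    B[[i]] <- Re(fhat * Conj(fhat))
  }
  structure(list(
    A = A, B = B, weights = rep(1 / length(feats), length(feats)),
    window = window, ghat = ghat, th = th, tw = tw,
    cx = cx, cy = cy, roi_w = r$w, roi_h = r$h,
    config = config, psr = Inf
  ), class = "tracker_state")
}

quad_subpixel <- function(vm, v0, vp) {
  den <- vm - 2 * v0 + vp
  if (abs(den) < 1e-12) return(0)
  min(max(0.5 * (vm - vp) / den, -0.5), 0.5)
}

response_psr <- function(resp, pr, pc, excl) {
  th <- nrow(resp); tw <- ncol(resp)
  mask <- matrix(TRUE, th, tw)
  rr <- max(1L, pr - excl):min(th, pr + excl)
  cc <- max(1L, pc - excl):min(tw, pc + excl)
  mask[rr, cc] <- FALSE
  side <- resp[mask]
  (resp[pr, pc] - mean(side)) / (stats::sd(side) + 1e-9)
}

#' Advance the tracker by one frame
#'
#' Correlates the learned filter with the feature channels of the search
#' window centered on the previous position; the new center is the
#' channel-weighted response argmax with sub-pixel quadratic refinement.
#' Filter and channel-reliability weights are then updated with exponential
#' rate `eta`. Confidence is the PSR of the response on the re-centered
#' patch, which stays high for fast-moving targets where the response at the
#' old center is window-attenuated.
#'
#' @param state A `tracker_state`.
#' @param frame Frame of the same dimensions as at initialization.
#' @return List with elements `state` (updated), `roi` (new [roi()]) and
#'   `psr`.
#' @export
track_update <- function(state, frame) {
  stopifnot(inherits(state, "tracker_state"))
  cfg <- state$config
  th <- state$th; tw <- state$tw
  feats <- patch_features(extract_patch(frame, state$cx, state$cy, th, tw),
                          state$window)
  if (length(feats) != length(state$A)) stop("feature channel mismatch")
  n <- th * tw
  resp_c <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    zhat <- stats::fft(feats[[i]])
    resp_c[[i]] <- Re(stats::fft(zhat * state$A[[i]] / (state$B[[i]] + cfg$lambda),
                                 inverse = TRUE)) / n
  }
  resp <- Reduce(`+`, Map(`*`, resp_c, as.list(state$weights)))

  pk <- which.max(resp)
  pr <- (pk - 1) %% th + 1; pc <- (pk - 1) %/% th + 1
  wrap <- function(i, m) (i - 1) %% m + 1
  dr <- quad_subpixel(resp[wrap(pr - 1, th), pc], resp[pr, pc], resp[wrap(pr + 1, th), pc])
  dc <- quad_subpixel(resp[pr, wrap(pc - 1, tw)], resp[pr, pc], resp[pr, wrap(pc + 1, tw)])
  r0 <- (th - 1) %/% 2 + 1; c0 <- (tw - 1) %/% 2 + 1
  dy <- pr + dr - r0; dx <- pc + dc - c0
  if (dy > th / 2) dy <- dy - th
  if (dx > tw / 2) dx <- dx - tw

  state$cx <- state$cx + dx
  state$cy <- state$cy + dy

  # confidence: PSR of the response on the re-centered patch, where a true
  # target peaks at the center undiminished by the window (the displaced
  # response under-reads confidence for fast motion)
  feats2 <- patch_features(extract_patch(frame, state$cx, state$cy, th, tw),
                           state$window)
  zhat2 <- lapply(feats2, stats::fft)
  resp2 <- Reduce(`+`, Map(function(zh, a, b, w) {
    w * Re(stats::fft(zh * a / (b + cfg$lambda), inverse = TRUE)) / n
  }, zhat2, state$A, state$B, as.list(state$weights)))
  pk2 <- which.max(resp2)
  psr <- response_psr(resp2, (pk2 - 1) %% th + 1, (pk2 - 1) %/% th + 1,
                      cfg$psr_exclude)
  state$psr <- psr

  # learn on the re-centered patch
  rel <- numeric(length(feats2))
  for (i in seq_along(feats2)) {
    fhat <- zhat2[[i]]
    state$A[[i]] <- (1 - cfg$eta) * state$A[[i]] + cfg$eta * state$ghat * Conj(fhat)
    state$B[[i]] <- (1 - cfg$eta) * state$B[[i]] + cfg$eta * Re(fhat * Conj(fhat))
    rel[i] <- max(max(resp_c[[i]]), 1e-6)
  }
  state$weights <- (1 - cfg$eta) * state$weights + cfg$eta * rel / sum(rel)
  state$weights <- state$weights / sum(state$weights)

  list(state = state,
       roi = roi(state$cx - state$roi_w / 2, state$cy - state$roi_h / 2,
                 state$roi_w, state$roi_h),
       psr = psr)
}

#' Re-select the region of interest
#'
#' Re-initializes the filter from a manually supplied RoI (used after
#' large-scale motion or occlusion), preserving the configuration.
#'
#' @inheritParams init_tracker
#' @param state The current `tracker_state`.
#' @return A fresh `tracker_state` at the new RoI.
#' @export
reselect <- function(state, frame, r) {
  init_tracker(frame, r, state$config)
}

#' Track a tool through a frame sequence
#'
#' Initializes on the first frame, updates through the sequence, and applies
#' any re-selection events. Frames whose PSR falls below the failure
#' threshold are flagged invalid; they hold the last confident center and do
#' not update the filter.
#'
#' @param frames List of frames (all the same size).
#' @param initial_roi A [roi()] on the first frame.
#' @param events Optional list of re-selections, each
#'   `list(frame = index, roi = roi(...))`.
#' @param config A [tracker_config()].
#' @return data.frame `frame_index`, `cx`, `cy`, `psr`, `valid`.
#' @export
track_sequence <- function(frames, initial_roi, events = NULL,
                           config = tracker_config()) {
  if (length(frames) == 0L) stop("no frames to track")
  ev_idx <- vapply(events, function(e) as.integer(e$frame), 1L)
  if (length(ev_idx) && any(ev_idx < 1L | ev_idx > length(frames))) {
    stop("re-selection event frame index out of range")
  }
  state <- init_tracker(frames[[1]], initial_roi, config)
  n <- length(frames)
  cx <- numeric(n); cy <- numeric(n); psr <- numeric(n); valid <- logical(n)
  cx[1] <- state$cx; cy[1] <- state$cy; psr[1] <- Inf; valid[1] <- TRUE
  last_cx <- cx[1]; last_cy <- cy[1]
  for (f in seq_len(n)[-1]) {
    hit <- if (length(ev_idx)) which(ev_idx == f) else integer(0)
    if (length(hit)) {
      state <- reselect(state, frames[[f]], events[[hit[1]]]$roi)
      cx[f] <- state$cx; cy[f] <- state$cy; psr[f] <- Inf; valid[f] <- TRUE
      last_cx <- cx[f]; last_cy <- cy[f]
      next
    }
    up <- track_update(state, frames[[f]])
    if (up$psr < config$psr_threshold) {
      # lost: hold last confident center, do not learn from this frame
      state$cx <- last_cx; state$cy <- last_cy
      cx[f] <- last_cx; cy[f] <- last_cy; psr[f] <- up$psr; valid[f] <- FALSE
    } else {
      state <- up$state
      cx[f] <- state$cx; cy[f] <- state$cy; psr[f] <- up$psr; valid[f] <- TRUE
      last_cx <- cx[f]; last_cy <- cy[f]
    }
  }
  data.frame(frame_index = seq_len(n), cx = cx, cy = cy, psr = psr,
             valid = valid)
}
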