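#' Rendering configuration for synthetic frames
#'
#' @param width,height Frame size in pixels.
#' @param scale Factor applied to track coordinates before drawing (use < 1
#'   to render a cohort generated in a larger image space at desk scale).
#' @param disc_radius Tool disc radius, pixels.
#' @param intensities Named per-tool disc intensities in \[0, 1\].
#' @param background_seed Seed for the static textured background.
#' @param background_contrast Peak-to-peak amplitude of the background
#'   texture around 0.45.
#' @return List of class `render_config`.
#' @export
render_config <- function(width = 160L, height = 120L, scale = 0.25,
                          disc_radius = 6, intensities = c(dissector = 1.0,
                                                           scissors = 0.85,
                                                           clipper = 0.7),
                          background_seed = 42L, background_contrast = 0.2) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 scale = scale, disc_radius = disc_radius,
                 intensities = intensities,
                 background_seed = as.integer(background_seed),
                 background_contrast = background_contrast),
            class = "render_config")
}

# Static smoothed-noise background, deterministic in the background seed.
render_background <- function(cfg) {
  rng <- local({
    set.seed(cfg$background_seed)
    matrix(stats::runif(cfg$height * cfg$width), cfg$height, cfg$width)
  })
  k <- rep(1 / 7, 7)
  sm <- apply(rng, 2, function(col) stats::filter(col, k, circular = TRUE))
  sm <- t(apply(sm, 1, function(row) stats::filter(row, k, circular = TRUE)))
  sm <- (sm - mean(sm)) / max(abs(sm - mean(sm)))
  0.45 + cfg$background_contrast / 2 * sm
}

draw_disc <- function(img, cx, cy, radius, intensity) {
  h <- nrow(img); w <- ncol(img)
  # 0-based pixel coords -> 1-based matrix indices
  c0 <- cx + 1; r0 <- cy + 1
  rr <- max(1L, floor(r0 - radius - 1)):min(h, ceiling(r0 + radius + 1))
  cc <- max(1L, floor(c0 - radius - 1)):min(w, ceiling(c0 + radius + 1))
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
  a <- pmin(pmax(radius + 0.5 - d, 0), 1)  # 1-px soft edge
  img[rr, cc] <- img[rr, cc] * (1 - a) + intensity * a
  img
}

#' Render a trial's frames
#'
#' Draws one filled disc per valid tool at its track coordinates on a fixed
#' textured background, one grayscale matrix (values in \[0, 1\],
#' rows = y, columns = x) per frame.
#'
#' @param trial A trial from [generate_cohort()] (needs `tracks`).
#' @param cfg A [render_config()].
#' @param frames Optional integer vector of frame indices to render
#'   (default: all frames).
#' @param tools Which tools to draw.
#' @return List of `height` x `width` matrices.
#' @export
render_frames <- function(trial, cfg = render_config(),
                          frames = NULL,
                          tools = c("dissector", "scissors", "clipper")) {
  if (is.null(trial$tracks)) stop("trial has no tracks to render")
  n <- nrow(trial$tracks[[tools[1]]])
  if (is.null(frames)) frames <- seq_len(n)
  if (any(frames < 1L | frames > n)) stop("frame index out of range")
  bg <- render_background(cfg)
  out <- vector("list", length(frames))
  for (j in seq_along(frames)) {
    f <- frames[j]
    img <- bg
    for (tool in tools) {
      tk <- trial$tracks[[tool]]
      if (!isTRUE(tk$valid[f])) next
      cx <- tk$x[f] * cfg$scale
      cy <- tk$y[f] * cfg$scale
      if (cx < 0 || cy < 0 || cx > cfg$width - 1 || cy > cfg$height - 1) {
        stop("track coordinates fall outside the rendered frame")
      }
      img <- draw_disc(img, cx, cy, cfg$disc_radius, cfg$intensities[[tool]])
    }
    out[[j]] <- img
  }
  out
}
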