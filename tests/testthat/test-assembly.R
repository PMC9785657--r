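test_that("synchronization picks the nearest force sample, earlier on ties", {
  force <- data.frame(time = c(0.00, 0.09, 0.12), fx = 1:3, fy = 4:6, fz = 7:9)
  expect_equal(synchronize(force, 0.10)$fx, 2)       # 0.09 is nearer

  force2 <- data.frame(time = c(0.08, 0.12), fx = c(10, 20), fy = 0, fz = 0)
  expect_equal(synchronize(force2, 0.10)$fx, 10)     # equidistant -> earlier

  ft <- c(0.1, 0.2, 0.3)
  force3 <- data.frame(time = ft, fx = 1:3, fy = 1:3, fz = 1:3)
  expect_equal(synchronize(force3, ft)$fx, 1:3)      # identity mapping

  expect_error(synchronize(force, c(0.05, 0.50)), "span")
  expect_error(synchronize(data.frame(time = c(1, 1), fx = 0, fy = 0, fz = 0),
                           1), "strictly increasing")
})

test_that("assembly yields the fixed nine-channel layout with zero-filled gaps", {
  n <- 10
  tracks <- list(
    dissector = data.frame(x = 1:10, y = 11:20, valid = TRUE),
    scissors = data.frame(x = 21:30, y = 31:40, valid = TRUE),
    clipper = data.frame(x = 41:50, y = 51:60,
                         valid = c(rep(FALSE, 5), rep(TRUE, 5))))
  fs <- data.frame(fx = rep(1, n), fy = rep(2, n), fz = rep(3, n))
  s <- assemble_series(tracks, fs, seq_len(n) / 30, "t1")
  expect_equal(ncol(s$values), 9)
  expect_equal(colnames(s$values), series_channels())
  expect_equal(s$original_length, n)
  expect_true(all(s$values[1:5, c("clipper_x", "clipper_y")] == 0))
  expect_equal(s$values[6:10, "clipper_x"], 46:50)
  expect_equal(unname(s$values[, "force_z"]), rep(3, n))

  bad <- tracks; bad$dissector <- bad$dissector[1:5, ]
  expect_error(assemble_series(bad, fs, seq_len(n) / 30), "match")
})

test_that("padding to the template is forced, idempotent and commutes with selection", {
  mk <- function(n, id) as_series(matrix(seq_len(n * 9), n, 9,
                                         dimnames = list(NULL, series_channels())), id)
  lst <- list(mk(3, "a"), mk(5, "b"))
  pad <- pad_to_template(lst)
  expect_equal(vapply(pad, function(s) nrow(s$values), 1L), c(5L, 5L))
  expect_true(all(pad[[1]]$values[4:5, ] == 0))
  expect_equal(pad[[1]]$original_length, 3)
  expect_identical(pad_to_template(pad), pad)            # idempotent
  expect_identical(pad_to_template(lst[2]), lst[2])      # single series

  sel_then_pad <- pad_to_template(lapply(lst, select_channels, subset = "forcez"))
  pad_then_sel <- lapply(pad, select_channels, subset = "forcez")
  expect_identical(sel_then_pad, pad_then_sel)           # commutation
  expect_error(pad_to_template(list()), "empty")
})

test_that("channel subset names resolve to the printed column sets", {
  expect_equal(resolve_channels("forcez"), 9L)
  expect_equal(resolve_channels("forcexyz"), 7:9)
  expect_equal(length(resolve_channels("Dxy,Sxy,forcexyz")), 7)
  expect_equal(length(resolve_channels("Dxy,Sxy,Cxy,forcexyz")), 9)
  expect_equal(length(resolve_channels("Dxy,Sxy,forcez")), 5)
  expect_equal(resolve_channels("all"), 1:9)
  expect_error(resolve_channels("forceq"), "unknown")

  m <- matrix(1:18, 2, 9, dimnames = list(NULL, series_channels()))
  s <- select_channels(as_series(m, "x"), "forcez")
  expect_equal(ncol(s$values), 1)
  expect_equal(s$channel_names, "force_z")
  full <- select_channels(as_series(m, "x"), "all")
  expect_equal(full$values, m)
})

test_that("normalization uses training rows only and fixes padded rows at zero", {
  set.seed(2)
  tr1 <- as_series(matrix(rnorm(40 * 2, 5, 2), 40, 2), "tr1")
  tr2 <- as_series(matrix(rnorm(40 * 2, 5, 2), 40, 2), "tr2")
  te <- as_series(rbind(matrix(rnorm(20 * 2, 5, 2), 20, 2),
                        matrix(0, 20, 2)), "te", orig = 20)
  st <- channel_stats(list(tr1, tr2))
  norm_tr <- normalize_series(list(tr1, tr2))
  rows <- do.call(rbind, lapply(norm_tr, function(s) s$values))
  expect_equal(unname(colMeans(rows)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(rows, 2, sd)), c(1, 1), tolerance = 0.02)

  norm_te <- apply_normalization(te, st)
  expect_true(all(norm_te$values[21:40, ] == 0))         # padding stays 0
  # the held-out trial's own values never enter the statistics
  st2 <- channel_stats(list(tr1, tr2, te))
  expect_false(isTRUE(all.equal(st$mean, st2$mean)))

  cst <- as_series(matrix(3, 10, 2), "c")
  expect_true(all(apply_normalization(cst, channel_stats(list(cst)))$values == 0))
})

test_that("series and cohorts round-trip through disk bit-exactly", {
  coh <- small_cohort(seed = 12L, len = c(30L, 60L))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir, generator_config(seed = 12L))
  back <- read_cohort(dir)
  expect_equal(length(back), 20)
  expect_identical(back[[1]]$force$fz, coh[[1]]$force$fz)
  expect_identical(back[[5]]$tracks$dissector$x, coh[[5]]$tracks$dissector$x)
  expect_identical(back[[5]]$response, coh[[5]]$response)

  series <- assemble_cohort(coh)
  sdir <- withr::local_tempdir()
  write_series(series, sdir)
  back_s <- read_series(sdir)
  for (i in c(1, 7, 20)) {
    expect_identical(unname(back_s[[i]]$values), unname(series[[i]]$values))
    expect_equal(back_s[[i]]$original_length, series[[i]]$original_length)
  }
})

test_that("cohort assembly synchronizes, strides and pads consistently", {
  coh <- small_cohort(seed = 13L, len = c(60L, 120L))
  series <- assemble_cohort(coh, stride = 2L)
  tmpl <- max(vapply(series, function(s) s$original_length, 1L))
  expect_true(all(vapply(series, function(s) nrow(s$values), 1L) == tmpl))
  for (s in series) {
    n <- s$original_length
    if (n < tmpl) expect_true(all(s$values[(n + 1):tmpl, ] == 0))
  }
  # channel order stable across trials
  expect_true(all(vapply(series, function(s)
    identical(s$channel_names, series_channels()), TRUE)))
})
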