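test_that("conv block reproduces hand-computed convolution and degenerate cases", {
  x <- matrix(as.numeric(1:6), 6, 1)   # ramp x_t = t

  # all-zero weights with beta = 0 -> all zeros after BN + ReLU
  blk0 <- list(W = array(0, c(3, 1, 2)), b = c(0, 0), gamma = c(1, 1),
               beta = c(0, 0), mean = c(0, 0), var = c(1, 1))
  expect_true(all(conv_block(x, blk0, "eval") == 0))
  expect_true(all(conv_block(x, blk0, "train") == 0))

  # kernel [1], identity BN -> ReLU(x) (gamma cancels the eps factor)
  blk1 <- list(W = array(1, c(1, 1, 1)), b = 0, gamma = sqrt(1 + 1e-5),
               beta = 0, mean = 0, var = 1)
  xx <- matrix(c(-2, -1, 0, 1, 2), 5, 1)
  expect_equal(conv_block(xx, blk1, "eval"), pmax(xx, 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # kernel [1, 0, -1] on a ramp: interior pre-BN output is constant -2.
  # BN is frozen to shift by +4 (gamma cancels eps) so ReLU passes the value.
  blk2 <- list(W = array(c(1, 0, -1), c(3, 1, 1)), b = 0,
               gamma = sqrt(1 + 1e-5), beta = 2, mean = -2, var = 1)
  out <- conv_block(x, blk2, "eval") - 4
  expect_equal(drop(out)[2:5], rep(-2, 4), tolerance = 1e-9)

  expect_error(conv_block(x, list(W = array(0, c(3, 2, 1)), b = 0,
                                  gamma = 1, beta = 0, mean = 0, var = 1)),
               "channel mismatch")
})

test_that("forward pass is a softmax over GAP features and handles any length", {
  set.seed(3)
  cfg <- fcn_config(filters = c(4L, 4L, 4L), epochs = 1L, seed = 5L)
  dat <- shifted_series(2, 40, shift = 1, seed = 5L)
  model <- train_fcn(cfg, dat$series, dat$labels)$model

  for (tt in c(50, 500, 5000)) {
    p <- fcn_forward(model, matrix(rnorm(tt * 2), tt, 2))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  expect_error(fcn_forward(model, matrix(0, 10, 5)), "channel")

  # zero softmax head -> uniform probabilities
  m0 <- model
  m0$head$W[] <- 0; m0$head$b[] <- 0
  expect_equal(unname(fcn_forward(m0, matrix(rnorm(60), 30, 2))),
               c(0.5, 0.5))
  expect_equal(fcn_predict(m0, matrix(rnorm(60), 30, 2)), 0L)  # tie -> 0

  # predict is argmax of forward
  for (i in 1:20) {
    xr <- matrix(rnorm(80), 40, 2)
    expect_equal(fcn_predict(model, xr),
                 unname(as.integer(which.max(fcn_forward(model, xr)) == 2L)))
  }
})

test_that("a hand-sized network matches a fully hand-computed forward pass", {
  # 1 block, 2 filters, kernel 1, T = 3, 1 channel
  cfg <- fcn_config(n_blocks = 1L, filters = 2L, kernel_sizes = 1L,
                    epochs = 1L, seed = 1L)
  model <- structure(list(
    blocks = list(list(W = array(c(2, -1), c(1, 1, 2)), b = c(0.5, 0),
                       gamma = c(1, 1), beta = c(0, 0.25),
                       mean = c(0.5, -1), var = c(4, 1))),
    head = list(W = matrix(c(1, 0, 0, 1), 2, 2), b = c(0.1, -0.1)),
    n_channels = 1L, config = cfg), class = "fcn_model")
  x <- matrix(c(1, 2, 3), 3, 1)
  # conv: f1 = 2x + 0.5 = (2.5, 4.5, 6.5); f2 = -x = (-1, -2, -3)
  # BN eval: f1 -> (f1 - 0.5)/sqrt(4 + 1e-5); f2 -> (f2 + 1)/sqrt(1 + 1e-5) + 0.25
  f1 <- (c(2.5, 4.5, 6.5) - 0.5) / sqrt(4 + 1e-5)
  f2 <- (c(-1, -2, -3) + 1) / sqrt(1 + 1e-5) + 0.25
  g <- c(mean(pmax(f1, 0)), mean(pmax(f2, 0)))
  logits <- g + c(0.1, -0.1)
  expected <- exp(logits) / sum(exp(logits))
  expect_equal(unname(fcn_forward(model, x)), unname(expected),
               tolerance = 1e-12)
})

test_that("training is deterministic, separates shifted classes, and validates input", {
  dat <- shifted_series(8, 500, shift = 3, seed = 2L)
  cfg <- fcn_config(filters = c(8L, 8L, 8L), epochs = 50L, seed = 3L)
  fit <- train_fcn(cfg, dat$series, dat$labels)
  expect_gte(fit$report$train_accuracy, 0.95)
  expect_true(all(is.finite(fit$report$loss)))

  fit2 <- train_fcn(cfg, dat$series, dat$labels)
  expect_identical(fit$model, fit2$model)

  expect_error(train_fcn(cfg, dat$series, rep(0, 16)), "single class")
  expect_error(train_fcn(cfg, dat$series[1], 0), "at least 2")
})

test_that("compiled and reference training engines agree", {
  dat <- shifted_series(4, 60, shift = 2, seed = 7L)
  cfg <- fcn_config(filters = c(5L, 4L, 3L), epochs = 8L, batch_size = 3L,
                    seed = 11L)
  fr <- train_fcn(cfg, dat$series, dat$labels, engine = "r")
  fc <- train_fcn(cfg, dat$series, dat$labels, engine = "cpp")
  expect_equal(fr$report$loss, fc$report$loss, tolerance = 1e-10)
  for (l in 1:3) {
    expect_equal(fr$model$blocks[[l]]$W, fc$model$blocks[[l]]$W,
                 tolerance = 1e-10)
    expect_equal(fr$model$blocks[[l]]$mean, fc$model$blocks[[l]]$mean,
                 tolerance = 1e-10)
  }
  expect_equal(fr$model$head$W, fc$model$head$W, tolerance = 1e-10)
})

test_that("eval-mode outputs are independent of batch composition", {
  dat <- shifted_series(4, 50, shift = 2, seed = 9L)
  cfg <- fcn_config(filters = c(4L, 4L, 4L), epochs = 5L, seed = 13L)
  model <- train_fcn(cfg, dat$series, dat$labels)$model
  p1 <- fcn_forward(model, dat$series[[1]])
  p2 <- fcn_forward(model, dat$series[[1]])  # no batch context in eval
  expect_identical(p1, p2)
})

test_that("zero-padded separable data still classifies with train-fold normalization", {
  # 50% padding fraction
  set.seed(17)
  tt <- 200
  mk <- function(s, id) {
    m <- matrix(rnorm(tt * 2), tt, 2); m[, 1] <- m[, 1] + s
    as_series(rbind(m, matrix(0, tt, 2)), id, orig = tt)
  }
  series <- c(lapply(1:7, function(i) mk(0, paste0("a", i))),
              lapply(1:7, function(i) mk(3, paste0("b", i))))
  labels <- stats::setNames(rep(0:1, each = 7),
                            vapply(series, function(s) s$trial_id, ""))
  cfg <- fcn_config(filters = c(8L, 8L, 8L), epochs = 20L, seed = 19L)
  cv <- loocv(series, labels, NULL, cfg, master_seed = 23L)
  expect_gte(cv$mean_accuracy, 0.9)
})

test_that("shuffled labels give chance-level LOOCV accuracy", {
  set.seed(29)
  series <- lapply(1:16, function(i)
    as_series(matrix(rnorm(100 * 2), 100, 2), paste0("t", i)))
  labels <- stats::setNames(sample(rep(0:1, each = 8)),
                            vapply(series, function(s) s$trial_id, ""))
  cfg <- fcn_config(filters = c(4L, 4L, 4L), epochs = 10L, seed = 31L)
  cv <- loocv(series, labels, NULL, cfg, master_seed = 37L)
  # two-sided 95% binomial band around 0.5 for n = 16
  expect_gte(cv$mean_accuracy, 4 / 16)
  expect_lte(cv$mean_accuracy, 12 / 16)
})
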