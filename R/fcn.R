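#' FCN configuration
#'
#' The classifier stacks three convolution blocks (1-D convolution along
#' time, batch normalization, ReLU) with 64 filters each and kernel sizes
#' 8, 5, 3, followed by global average pooling over time and a 2-way softmax
#' head; it is trained with Adam on binary cross-entropy.
#'
#' @param n_blocks Number of convolution blocks.
#' @param filters Filters per block.
#' @param kernel_sizes Kernel length per block.
#' @param epochs Training epochs.
#' @param batch_size Trials per minibatch.
#' @param learning_rate Adam step size.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param bn_eps Batch-norm variance floor.
#' @param bn_momentum Momentum of the running batch-norm statistics.
#' @param masked_gap If `TRUE`, global average pooling averages only over a
#'   series' unpadded rows (requires `original_length`); default averages
#'   the full padded length.
#' @return List of class `fcn_config`.
#' @export
fcn_config <- function(n_blocks = 3L, filters = c(64L, 64L, 64L),
                       kernel_sizes = c(8L, 5L, 3L), epochs = 100L,
                       batch_size = 4L, learning_rate = 1e-3, seed = 1L,
                       bn_eps = 1e-5, bn_momentum = 0.9, masked_gap = FALSE) {
  if (length(filters) != n_blocks || length(kernel_sizes) != n_blocks) {
    stop("filters and kernel_sizes must have one entry per block")
  }
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(n_blocks = as.integer(n_blocks),
                 filters = as.integer(filters),
                 kernel_sizes = as.integer(kernel_sizes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 bn_eps = bn_eps, bn_momentum = bn_momentum,
                 masked_gap = isTRUE(masked_gap)),
            class = "fcn_config")
}

# "same" temporal padding: output length equals input length.
im2col <- function(x, k) {
  tt <- nrow(x); cc <- ncol(x)
  pl <- (k - 1L) %/% 2L
  xp <- rbind(matrix(0, pl, cc), x, matrix(0, k - 1L - pl, cc))
  out <- matrix(0, tt, k * cc)
  for (ki in seq_len(k)) {
    out[, ((ki - 1L) * cc + 1L):(ki * cc)] <- xp[ki:(ki + tt - 1L), , drop = FALSE]
  }
  out
}

col2im <- function(dcol, k, cc, tt) {
  pl <- (k - 1L) %/% 2L
  dxp <- matrix(0, tt + k - 1L, cc)
  for (ki in seq_len(k)) {
    dxp[ki:(ki + tt - 1L), ] <- dxp[ki:(ki + tt - 1L), ] +
      dcol[, ((ki - 1L) * cc + 1L):(ki * cc), drop = FALSE]
  }
  dxp[(pl + 1L):(pl + tt), , drop = FALSE]
}

# weight array (k, C, F) -> im2col weight matrix (k*C, F)
flatten_kernel <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' One convolution block
#'
#' Applies 1-D convolution along time (with "same" padding so the length is
#' preserved), batch normalization (batch statistics in `"train"` mode,
#' running statistics in `"eval"` mode) and ReLU.
#'
#' @param x T x C input matrix.
#' @param params List with `W` (kernel x in-channels x filters array), `b`,
#'   `gamma`, `beta`, `mean`, `var`.
#' @param mode `"train"` or `"eval"`.
#' @param eps Batch-norm variance floor.
#' @return T x filters activation matrix.
#' @export
conv_block <- function(x, params, mode = c("eval", "train"), eps = 1e-5) {
  mode <- match.arg(mode)
  k <- dim(params$W)[1]
  if (dim(params$W)[2] != ncol(x)) stop("input channel mismatch")
  y <- im2col(x, k) %*% flatten_kernel(params$W)
  y <- sweep(y, 2, params$b, "+")
  if (mode == "train") {
    m <- colMeans(y)
    v <- colMeans(sweep(y, 2, m)^2)
  } else {
    m <- params$mean; v <- params$var
  }
  yh <- sweep(sweep(y, 2, m), 2, sqrt(v + eps), "/")
  z <- sweep(sweep(yh, 2, params$gamma, "*"), 2, params$beta, "+")
  pmax(z, 0)
}

init_fcn_model <- function(config, n_channels) {
  blocks <- vector("list", config$n_blocks)
  cin <- n_channels
  for (l in seq_len(config$n_blocks)) {
    k <- config$kernel_sizes[l]; f <- config$filters[l]
    sd0 <- sqrt(2 / (k * cin))
    blocks[[l]] <- list(
      W = array(stats::rnorm(k * cin * f, 0, sd0), c(k, cin, f)),
      b = numeric(f), gamma = rep(1, f), beta = numeric(f),
      mean = numeric(f), var = rep(1, f)
    )
    cin <- f
  }
  f <- config$filters[config$n_blocks]
  head <- list(W = matrix(stats::rnorm(f * 2L, 0, sqrt(1 / f)), f, 2L),
               b = numeric(2L))
  structure(list(blocks = blocks, head = head, n_channels = n_channels,
                 config = config), class = "fcn_model")
}

series_matrix <- function(s) {
  if (inherits(s, "assembled_series")) s$values else as.matrix(s)
}

series_length <- function(s) {
  if (inherits(s, "assembled_series")) s$original_length else nrow(as.matrix(s))
}

gap_pool <- function(h, orig_len, masked) {
  if (masked) colMeans(h[seq_len(min(orig_len, nrow(h))), , drop = FALSE])
  else colMeans(h)
}

#' Forward pass: class probabilities
#'
#' Three conv blocks in eval mode, global average pooling over time, then an
#' affine softmax head; any series length is accepted.
#'
#' @param model An `fcn_model` from [train_fcn()].
#' @param series T x C matrix or `assembled_series` with the model's channel
#'   count.
#' @return Numeric probability pair `(p0, p1)` summing to 1.
#' @export
fcn_forward <- function(model, series) {
  x <- series_matrix(series)
  if (ncol(x) != model$n_channels) stop("channel count mismatch")
  cfg <- model$config
  for (bl in model$blocks) x <- conv_block(x, bl, "eval", cfg$bn_eps)
  g <- gap_pool(x, series_length(series), cfg$masked_gap)
  logits <- drop(g %*% model$head$W) + model$head$b
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  names(p) <- c("p0", "p1")
  p
}

#' Predict a binary class label
#'
#' Argmax of the forward probabilities; an exact tie resolves to class 0.
#'
#' @inheritParams fcn_forward
#' @return Integer 0 or 1.
#' @export
fcn_predict <- function(model, series) {
  p <- fcn_forward(model, series)
  if (p[2] > p[1]) 1L else 0L
}

adam_step <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mh <- st$m / (1 - b1^t); vh <- st$v / (1 - b2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

#' Train the FCN
#'
#' Minimizes binary cross-entropy over the 2-way softmax with Adam;
#' initialization and minibatch orders are drawn from R's RNG, so the final
#' weights are deterministic given `config$seed` for either engine. The
#' compiled engine is the default; the pure-R engine is retained as a
#' readable reference and the two are cross-checked in the test suite.
#'
#' @param config An [fcn_config()].
#' @param series_list List of equal-length T x C matrices or
#'   `assembled_series`.
#' @param labels Integer 0/1 vector, one label per series; both classes must
#'   be present.
#' @param engine `"cpp"` (compiled core) or `"r"` (reference loop).
#' @return List with `model` (an `fcn_model`) and `report` (per-epoch loss,
#'   final training accuracy, config echo).
#' @export
train_fcn <- function(config, series_list, labels, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (length(series_list) < 2L) stop("need at least 2 training trials")
  labels <- as.integer(labels)
  if (length(labels) != length(series_list)) stop("one label per series required")
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single class; decision boundary undefined")
  }
  xs <- lapply(series_list, series_matrix)
  if (length(unique(vapply(xs, nrow, 1L))) != 1L) {
    stop("training series must share one padded length (see pad_to_template)")
  }
  lens <- as.integer(vapply(series_list, series_length, numeric(1)))
  cc <- ncol(xs[[1]])
  n <- length(xs)
  cfg <- config

  set.seed(cfg$seed)
  model <- init_fcn_model(cfg, cc)
  orders <- t(vapply(seq_len(cfg$epochs), function(e) sample.int(n),
                     integer(n)))

  if (engine == "cpp") {
    tt <- nrow(xs[[1]])
    X <- array(unlist(xs, use.names = FALSE), c(tt, cc, n))
    res <- .fcn_train_core(X, labels, lens,
                           list(blocks = model$blocks, head = model$head),
                           orders, cfg$batch_size, cfg$learning_rate,
                           cfg$bn_eps, cfg$bn_momentum, cfg$masked_gap)
    for (l in seq_len(cfg$n_blocks)) {
      bl <- res$blocks[[l]]
      model$blocks[[l]] <- list(W = bl$W, b = as.numeric(bl$b),
                                gamma = as.numeric(bl$gamma),
                                beta = as.numeric(bl$beta),
                                mean = as.numeric(bl$mean),
                                var = as.numeric(bl$var))
    }
    model$head$W <- res$head$W
    model$head$b <- as.numeric(res$head$b)
    losses <- as.numeric(res$losses)
  } else {
    res <- train_fcn_loop_r(cfg, xs, lens, labels, model, orders)
    model <- res$model
    losses <- res$losses
  }

  preds <- vapply(seq_len(n), function(i) fcn_predict(model, series_list[[i]]), 1L)
  report <- list(loss = losses, train_accuracy = mean(preds == labels),
                 seed = cfg$seed, config = cfg)
  list(model = model, report = report)
}

# Reference training loop in plain R; same arithmetic as the compiled core.
train_fcn_loop_r <- function(cfg, xs, lens, labels, model, orders) {
  n <- length(xs)
  # flat parameter list for Adam
  params <- list()
  for (l in seq_len(cfg$n_blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      params[[paste0("b", l, "_", nm)]] <- model$blocks[[l]][[nm]]
    }
  }
  params$head_W <- model$head$W; params$head_b <- model$head$b
  opt <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  tstep <- 0L
  losses <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- orders[epoch, ]
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      bs <- length(idx)
      caches <- vector("list", cfg$n_blocks)
      acts <- xs[idx]

      for (l in seq_len(cfg$n_blocks)) {
        k <- cfg$kernel_sizes[l]
        wm <- flatten_kernel(params[[paste0("b", l, "_W")]])
        cols <- lapply(acts, im2col, k = k)
        xcol <- do.call(rbind, cols)
        y <- sweep(xcol %*% wm, 2, params[[paste0("b", l, "_b")]], "+")
        m <- colMeans(y)
        v <- colMeans(sweep(y, 2, m)^2)
        yh <- sweep(sweep(y, 2, m), 2, sqrt(v + cfg$bn_eps), "/")
        z <- sweep(sweep(yh, 2, params[[paste0("b", l, "_gamma")]], "*"),
                   2, params[[paste0("b", l, "_beta")]], "+")
        h <- pmax(z, 0)
        model$blocks[[l]]$mean <- cfg$bn_momentum * model$blocks[[l]]$mean +
          (1 - cfg$bn_momentum) * m
        model$blocks[[l]]$var <- cfg$bn_momentum * model$blocks[[l]]$var +
          (1 - cfg$bn_momentum) * v
        caches[[l]] <- list(xcol = xcol, yh = yh, v = v, mask = h > 0,
                            in_ch = ncol(acts[[1]]),
                            tt = vapply(acts, nrow, 1L))
        acts <- lapply(seq_len(bs), function(i) {
          h[((i - 1L) * nrow(acts[[i]]) + 1L):(i * nrow(acts[[i]])), , drop = FALSE]
        })
      }

      g <- t(vapply(seq_len(bs), function(i) {
        gap_pool(acts[[i]], lens[idx[i]], cfg$masked_gap)
      }, numeric(cfg$filters[cfg$n_blocks])))
      logits <- sweep(g %*% params$head_W, 2, params$head_b, "+")
      mx <- apply(logits, 1, max)
      e <- exp(logits - mx)
      p <- e / rowSums(e)
      yidx <- labels[idx] + 1L
      ep_loss <- ep_loss - sum(log(pmax(p[cbind(seq_len(bs), yidx)], 1e-12)))

      # backward
      dlog <- p
      dlog[cbind(seq_len(bs), yidx)] <- dlog[cbind(seq_len(bs), yidx)] - 1
      dlog <- dlog / bs
      grads <- list(head_W = t(g) %*% dlog, head_b = colSums(dlog))
      dg <- dlog %*% t(params$head_W)

      tt_each <- caches[[cfg$n_blocks]]$tt
      dh_list <- lapply(seq_len(bs), function(i) {
        ti <- tt_each[i]
        if (cfg$masked_gap) {
          nl <- min(lens[idx[i]], ti)
          d <- matrix(0, ti, length(dg[i, ]))
          d[seq_len(nl), ] <- matrix(dg[i, ] / nl, nl, length(dg[i, ]), byrow = TRUE)
          d
        } else {
          matrix(dg[i, ] / ti, ti, length(dg[i, ]), byrow = TRUE)
        }
      })
      dh <- do.call(rbind, dh_list)

      for (l in rev(seq_len(cfg$n_blocks))) {
        ca <- caches[[l]]
        dz <- dh * ca$mask
        grads[[paste0("b", l, "_gamma")]] <- colSums(dz * ca$yh)
        grads[[paste0("b", l, "_beta")]] <- colSums(dz)
        dyh <- sweep(dz, 2, params[[paste0("b", l, "_gamma")]], "*")
        nn <- nrow(dyh)
        s1 <- colSums(dyh)
        s2 <- colSums(dyh * ca$yh)
        dy <- sweep(sweep(nn * dyh, 2, s1) - sweep(ca$yh, 2, s2, "*"),
                    2, nn * sqrt(ca$v + cfg$bn_eps), "/")
        wm <- flatten_kernel(params[[paste0("b", l, "_W")]])
        k <- cfg$kernel_sizes[l]
        gW <- t(ca$xcol) %*% dy
        # (k*C, F) grad back to (k, C, F) array layout
        gWarr <- aperm(array(gW, c(ca$in_ch, k, ncol(gW))), c(2, 1, 3))
        grads[[paste0("b", l, "_W")]] <- gWarr
        grads[[paste0("b", l, "_b")]] <- colSums(dy)
        if (l > 1L) {
          dxcol <- dy %*% t(wm)
          offs <- c(0L, cumsum(ca$tt))
          dh <- do.call(rbind, lapply(seq_len(bs), function(i) {
            col2im(dxcol[(offs[i] + 1L):offs[i + 1L], , drop = FALSE],
                   k, ca$in_ch, ca$tt[i])
          }))
        }
      }

      tstep <- tstep + 1L
      for (nm in names(grads)) {
        up <- adam_step(params[[nm]], grads[[nm]], opt[[nm]],
                        cfg$learning_rate, tstep)
        params[[nm]] <- up$par; opt[[nm]] <- up$st
      }
    }
    losses[epoch] <- ep_loss / n
  }

  for (l in seq_len(cfg$n_blocks)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      model$blocks[[l]][[nm]] <- params[[paste0("b", l, "_", nm)]]
    }
  }
  model$head$W <- params$head_W; model$head$b <- params$head_b

  list(model = model, losses = losses)
}
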