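#' Configuration of the 1D convolutional classifier
#'
#' Architecture: `n_conv_blocks` repetitions of
#' [conv(kernels_per_conv kernels of length kernel_size) -> ReLU ->
#' batch normalization -> max pooling], then flatten and three ReLU dense
#' layers, then a softmax output over the classes. The kernel length is
#' automatically capped at the current input length so short SNP panels
#' still build. Training uses Adam and the focal loss.
#'
#' @param n_conv_blocks Number of convolution blocks (default 2).
#' @param kernels_per_conv Feature maps per convolution (default 10).
#' @param kernel_size Kernel length (default 150; capped at input length).
#' @param pool_size Max-pooling window (default 5, non-overlapping).
#' @param dense_sizes Widths of the three hidden dense layers
#'   (default 128, 64, 32).
#' @param learning_rate Adam learning rate (default 5e-5).
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Seed for initialization and batch shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_conv_blocks = 2, kernels_per_conv = 10,
                       kernel_size = 150, pool_size = 5,
                       dense_sizes = c(128, 64, 32), learning_rate = 5e-5,
                       epochs = 50, batch_size = 32, seed = 1) {
  stopifnot(n_conv_blocks >= 1, kernels_per_conv >= 1, kernel_size >= 1,
            pool_size >= 1, length(dense_sizes) == 3, all(dense_sizes >= 1),
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(n_conv_blocks = as.integer(n_conv_blocks),
                 kernels_per_conv = as.integer(kernels_per_conv),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dense_sizes = as.integer(dense_sizes),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a seeded, untrained 1D-CNN classifier
#'
#' @param input_len Number of input SNPs (sequence length).
#' @param n_classes Number of output classes.
#' @param cfg A [cnn_config()].
#' @return A `cnn_model` handle with seeded initial weights.
#' @export
build_classifier <- function(input_len, n_classes, cfg = cnn_config()) {
  stopifnot(input_len >= 1, n_classes >= 2)
  set.seed(cfg$seed)
  layers <- list()
  len <- as.integer(input_len)
  chan <- 1L
  for (blk in seq_len(cfg$n_conv_blocks)) {
    k <- min(cfg$kernel_size, len)
    layers[[length(layers) + 1L]] <- list(
      type = "conv", k = k, c_in = chan, c_out = cfg$kernels_per_conv,
      w = he_init(k * chan, cfg$kernels_per_conv, k * chan),
      b = numeric(cfg$kernels_per_conv))
    len <- len - k + 1L
    chan <- cfg$kernels_per_conv
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- list(
      type = "bn", c = chan, gamma = rep(1, chan), beta = numeric(chan),
      run_mean = numeric(chan), run_var = rep(1, chan),
      momentum = 0.9, eps = 1e-5)
    if (len < cfg$pool_size) {
      stop(sprintf(
        "input too short after pooling: conv block %d leaves length %d < pool size %d (input_len %d, kernel %d)",
        blk, len, cfg$pool_size, input_len, k))
    }
    layers[[length(layers) + 1L]] <- list(type = "pool", p = cfg$pool_size)
    len <- len %/% cfg$pool_size
    if (len < 1L) {
      stop(sprintf("input too short after pooling: block %d leaves length 0",
                   blk))
    }
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten",
                                        len = len, chan = chan)
  fan <- len * chan
  for (d in cfg$dense_sizes) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", w = he_init(fan, d, fan), b = numeric(d),
      activation = "relu")
    fan <- d
  }
  # zero-initialized output layer: exactly uniform softmax before training
  layers[[length(layers) + 1L]] <- list(
    type = "dense", w = matrix(0, fan, n_classes), b = numeric(n_classes),
    activation = "linear")
  structure(list(cfg = cfg, input_len = as.integer(input_len),
                 n_classes = as.integer(n_classes), layers = layers),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("cnn_model: input %d SNPs -> %d classes, %d layers\n",
              x$input_len, x$n_classes, length(x$layers)))
  invisible(x)
}

im2col <- function(x, k) {
  # x: (n, L, C) -> (n, L_out, k*C), channel-major within kernel offset
  n <- dim(x)[1]; l <- dim(x)[2]; cc <- dim(x)[3]
  l_out <- l - k + 1L
  out <- array(0, dim = c(n, l_out, k * cc))
  for (c_i in seq_len(cc)) {
    for (o in seq_len(k)) {
      out[, , (c_i - 1L) * k + o] <- x[, o:(o + l_out - 1L), c_i]
    }
  }
  out
}

col2im_add <- function(dcol, k, cc, l) {
  n <- dim(dcol)[1]; l_out <- dim(dcol)[2]
  dx <- array(0, dim = c(n, l, cc))
  for (c_i in seq_len(cc)) {
    for (o in seq_len(k)) {
      dx[, o:(o + l_out - 1L), c_i] <-
        dx[, o:(o + l_out - 1L), c_i] + dcol[, , (c_i - 1L) * k + o]
    }
  }
  dx
}

cnn_forward <- function(model, x_mat, train = FALSE, keep_cache = FALSE) {
  n <- nrow(x_mat)
  a <- array(x_mat, dim = c(n, ncol(x_mat), 1L))
  caches <- vector("list", length(model$layers))
  layers <- model$layers
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type == "conv") {
      xc <- im2col(a, lay$k)
      l_out <- dim(xc)[2]
      xc_mat <- xc
      dim(xc_mat) <- c(n * l_out, lay$k * lay$c_in)
      y <- xc_mat %*% lay$w
      y <- sweep(y, 2, lay$b, "+")
      caches[[li]] <- list(xc_mat = xc_mat, l_in = dim(a)[2], l_out = l_out)
      a <- array(y, dim = c(n, l_out, lay$c_out))
    } else if (lay$type == "relu") {
      caches[[li]] <- list(mask = a > 0)
      a <- a * (a > 0)
    } else if (lay$type == "bn") {
      l <- dim(a)[2]
      m <- n * l
      am <- a
      dim(am) <- c(m, dim(a)[3])          # (n*L) x C view
      if (train) {
        mu <- .colMeans(am, m, ncol(am))
        v <- .colMeans(am^2, m, ncol(am)) - mu^2
        v[v < 0] <- 0
        layers[[li]]$run_mean <- lay$momentum * lay$run_mean +
          (1 - lay$momentum) * mu
        layers[[li]]$run_var <- lay$momentum * lay$run_var +
          (1 - lay$momentum) * v * m / max(1, m - 1)
      } else {
        mu <- lay$run_mean
        v <- lay$run_var
      }
      inv_sd <- 1 / sqrt(v + lay$eps)
      xhat <- (am - rep(mu, each = m)) * rep(inv_sd, each = m)
      out <- xhat * rep(lay$gamma, each = m) + rep(lay$beta, each = m)
      caches[[li]] <- list(xhat = xhat, inv_sd = inv_sd, m = m,
                           train = train, dims = dim(a))
      dim(out) <- dim(a)
      a <- out
    } else if (lay$type == "pool") {
      l <- dim(a)[2]
      cc <- dim(a)[3]
      n_win <- l %/% lay$p
      cur <- a[, seq(1L, by = lay$p, length.out = n_win), , drop = FALSE]
      argmax <- array(1L, dim = dim(cur))
      for (j in seq_len(lay$p)[-1]) {
        cand <- a[, seq(j, by = lay$p, length.out = n_win), , drop = FALSE]
        upd <- cand > cur
        cur[upd] <- cand[upd]
        argmax[upd] <- j
      }
      caches[[li]] <- list(argmax = argmax, l_in = l)
      a <- cur
    } else if (lay$type == "flatten") {
      caches[[li]] <- list(dims = dim(a))
      dim(a) <- c(n, dim(a)[2] * dim(a)[3])
    } else if (lay$type == "dense") {
      caches[[li]] <- list(x = a)
      a <- sweep(a %*% lay$w, 2, lay$b, "+")
      if (lay$activation == "relu") {
        caches[[li]]$pre_mask <- a > 0
        a <- a * (a > 0)
      }
    }
  }
  logits <- a
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits,
       caches = if (keep_cache) caches else NULL,
       layers = layers)   # layers carry updated running stats
}

# Backpropagate d(loss)/d(logits) through the network.
# Returns list(grads = per-layer list(dw, db, dgamma, dbeta), dx = input grad)
cnn_backward <- function(model, caches, dlogits) {
  n <- nrow(dlogits)
  grads <- vector("list", length(model$layers))
  da <- dlogits
  for (li in rev(seq_along(model$layers))) {
    lay <- model$layers[[li]]
    cache <- caches[[li]]
    if (lay$type == "dense") {
      if (lay$activation == "relu") da <- da * cache$pre_mask
      grads[[li]] <- list(dw = crossprod(cache$x, da), db = colSums(da))
      da <- da %*% t(lay$w)
    } else if (lay$type == "flatten") {
      dim(da) <- cache$dims
    } else if (lay$type == "pool") {
      dims_in <- c(n, cache$l_in, dim(cache$argmax)[3])
      dx <- array(0, dim = dims_in)
      n_win <- dim(cache$argmax)[2]
      for (j in seq_len(lay$p)) {
        dx[, seq(j, by = lay$p, length.out = n_win), ] <-
          da * (cache$argmax == j)
      }
      da <- dx
    } else if (lay$type == "bn") {
      m <- cache$m
      dam <- da
      dim(dam) <- c(m, length(lay$gamma))
      dgamma <- colSums(dam * cache$xhat)
      dbeta <- colSums(dam)
      grads[[li]] <- list(dgamma = dgamma, dbeta = dbeta)
      if (cache$train) {
        dxhat <- dam * rep(lay$gamma, each = m)
        t1 <- dxhat - rep(colSums(dxhat) / m, each = m)
        t2 <- cache$xhat * rep(colSums(dxhat * cache$xhat) / m, each = m)
        dam <- (t1 - t2) * rep(cache$inv_sd, each = m)
      } else {
        # eval mode: a fixed per-channel affine map
        dam <- dam * rep(lay$gamma * cache$inv_sd, each = m)
      }
      da <- dam
      dim(da) <- cache$dims
    } else if (lay$type == "relu") {
      da <- da * cache$mask
    } else if (lay$type == "conv") {
      l_out <- cache$l_out
      da_mat <- da
      dim(da_mat) <- c(n * l_out, lay$c_out)
      grads[[li]] <- list(dw = crossprod(cache$xc_mat, da_mat),
                          db = colSums(da_mat))
      dcol <- da_mat %*% t(lay$w)
      dim(dcol) <- c(n, l_out, lay$k * lay$c_in)
      da <- col2im_add(dcol, lay$k, lay$c_in, cache$l_in)
    }
  }
  list(grads = grads, dx = da[, , 1L])
}

adam_init <- function(model) {
  lapply(model$layers, function(lay) {
    switch(lay$type,
           conv = list(mw = lay$w * 0, vw = lay$w * 0,
                       mb = lay$b * 0, vb = lay$b * 0),
           dense = list(mw = lay$w * 0, vw = lay$w * 0,
                        mb = lay$b * 0, vb = lay$b * 0),
           bn = list(mg = lay$gamma * 0, vg = lay$gamma * 0,
                     mb = lay$beta * 0, vb = lay$beta * 0),
           NULL)
  })
}

adam_step <- function(model, state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  corr1 <- 1 - beta1^t
  corr2 <- 1 - beta2^t
  upd <- function(m, v, g) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(m = m, v = v, step = lr * (m / corr1) / (sqrt(v / corr2) + eps))
  }
  for (li in seq_along(model$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    lay <- model$layers[[li]]
    st <- state[[li]]
    if (lay$type %in% c("conv", "dense")) {
      u <- upd(st$mw, st$vw, g$dw)
      lay$w <- lay$w - u$step; st$mw <- u$m; st$vw <- u$v
      u <- upd(st$mb, st$vb, g$db)
      lay$b <- lay$b - u$step; st$mb <- u$m; st$vb <- u$v
    } else if (lay$type == "bn") {
      u <- upd(st$mg, st$vg, g$dgamma)
      lay$gamma <- lay$gamma - u$step; st$mg <- u$m; st$vg <- u$v
      u <- upd(st$mb, st$vb, g$dbeta)
      lay$beta <- lay$beta - u$step; st$mb <- u$m; st$vb <- u$v
    }
    model$layers[[li]] <- lay
    state[[li]] <- st
  }
  list(model = model, state = state)
}

# d(focal loss)/d(logits), mean-over-batch convention
focal_dlogits <- function(probs, y_idx, alphas, gamma = 2) {
  n <- nrow(probs)
  p_true <- pmax(probs[cbind(seq_len(n), y_idx)], 1e-15)
  a <- alphas[y_idx]
  # dL/dp_true = a * [-gamma (1-p)^{gamma-1} (-log p) - (1-p)^gamma / p]
  dldp <- a * (-gamma * (1 - p_true)^(gamma - 1) * (-log(p_true)) -
                 (1 - p_true)^gamma / p_true)
  dl <- probs * (-p_true * dldp)        # dp_true/dz_j = -p_true p_j, j != y
  dl[cbind(seq_len(n), y_idx)] <- dldp * p_true * (1 - p_true)
  dl / n
}

#' Train a 1D-CNN classifier with Adam and focal loss
#'
#' @param model A [build_classifier()] handle.
#' @param x N x P dosage matrix (rows = individuals).
#' @param y Factor of N class labels; levels must match the model's output
#'   width.
#' @param alphas Optional class-weight vector (see [focal_alpha()]);
#'   defaults to the focal weights of the training class counts.
#' @param verbose Print the focal loss each epoch?
#' @return The trained `cnn_model` (with the final-epoch mean batch focal
#'   loss in `train_loss`).
#' @export
train_classifier <- function(model, x, y, alphas = NULL, verbose = FALSE) {
  cfg <- model$cfg
  y <- factor(y)
  if (nlevels(y) != model$n_classes) {
    stop("number of label levels differs from model output width")
  }
  if (ncol(x) != model$input_len) stop("input width mismatch")
  y_idx <- as.integer(y)
  if (is.null(alphas)) {
    alphas <- focal_alpha(length(y_idx), as.integer(table(y)))
  }
  state <- adam_init(model)
  n <- nrow(x)
  set.seed(derive_seed(cfg$seed, 7L))
  t_step <- 0L
  flc <- focal_loss_config(length(y), as.integer(table(y)))
  flc$alphas <- alphas
  epoch_loss <- NA_real_
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      st <- starts[bi]
      rows <- ord[st:min(st + cfg$batch_size - 1L, n)]
      fw <- cnn_forward(model, x[rows, , drop = FALSE], train = TRUE,
                        keep_cache = TRUE)
      model$layers <- fw$layers          # updated running stats
      batch_losses[bi] <- focal_loss(fw$probs, y[rows], flc)
      dlog <- focal_dlogits(fw$probs, y_idx[rows], alphas)
      bk <- cnn_backward(model, fw$caches, dlog)
      t_step <- t_step + 1L
      res <- adam_step(model, state, bk$grads, cfg$learning_rate, t_step)
      model <- res$model
      state <- res$state
    }
    epoch_loss <- mean(batch_losses)
    if (verbose) {
      message(sprintf("epoch %d: focal loss %.4f", ep, epoch_loss))
    }
  }
  model$train_loss <- epoch_loss
  model
}

#' Predict class probabilities from a trained classifier
#'
#' @param model A `cnn_model`.
#' @param x N x P dosage matrix.
#' @return N x B matrix of softmax probabilities (columns in level order).
#' @export
predict_classifier <- function(model, x) {
  cnn_forward(model, as.matrix(x), train = FALSE)$probs
}

#' Per-sample, per-class input attributions
#'
#' Gradient x input backend: for every class b the gradient of the softmax
#' probability of b with respect to each input SNP is multiplied by the
#' input dosage, giving an N x B x P attribution tensor for
#' [aggregate_attributions()].
#'
#' @param model A trained `cnn_model`.
#' @param x N x P dosage matrix.
#' @return N x B x P array of attributions.
#' @export
compute_attributions <- function(model, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  b <- model$n_classes
  fw <- cnn_forward(model, x, train = FALSE, keep_cache = TRUE)
  probs <- fw$probs
  attr_arr <- array(0, dim = c(n, b, ncol(x)))
  for (cls in seq_len(b)) {
    # d p_cls / d z_j = p_cls (1{j = cls} - p_j)
    dlog <- -probs * probs[, cls]
    dlog[, cls] <- dlog[, cls] + probs[, cls]
    bk <- cnn_backward(model, fw$caches, dlog)
    attr_arr[, cls, ] <- bk$dx * x
  }
  attr_arr
}
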