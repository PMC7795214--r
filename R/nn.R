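# Lightweight CPU neural-network engine.
#
# Convolutional tensors are arrays with dim c(H, W, C, N); dense activations
# are N x F matrices. Convolution is im2col + GEMM. Forward supports
# sequential stacks plus two composites used by the named backbones
# ("branch" = parallel stacks concatenated along channels, "residual" =
# body + shortcut add). Backpropagation is implemented for the simple
# sequential layer set (conv stride 1, relu, average pooling, global average
# pooling, dense, dense batch norm, dropout), which covers the trainable
# tiny backbone and the fusion subnet; composite trunks are used as frozen
# feature extractors.

layer_conv <- function(filters, kernel = c(3, 3), stride = 1L, padding = "same",
                       activation = NULL) {
  if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  list(type = "conv", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), padding = padding, activation = activation)
}
layer_relu <- function() list(type = "relu")
layer_maxpool <- function(pool = 3L, stride = 2L, padding = "same") {
  list(type = "maxpool", pool = as.integer(pool), stride = as.integer(stride),
       padding = padding)
}
layer_avgpool <- function(pool = 2L, stride = pool, padding = "same") {
  list(type = "avgpool", pool = as.integer(pool), stride = as.integer(stride),
       padding = padding)
}
layer_gap <- function() list(type = "gap")
layer_dense <- function(units) list(type = "dense", units = as.integer(units))
layer_batchnorm <- function() list(type = "batchnorm")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_branch <- function(branches) list(type = "branch", branches = branches)
layer_residual <- function(body, shortcut = NULL, scale = 1, post_relu = TRUE) {
  list(type = "residual", body = body, shortcut = shortcut, scale = scale,
       post_relu = post_relu)
}

# ---- shape propagation and weight initialization -------------------------

conv_out_hw <- function(hw, kernel, stride, padding) {
  as.integer(if (padding == "same") ceiling(hw / stride)
             else floor((hw - kernel) / stride) + 1L)
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# Build (initialize) a stack of layer specs for a given input shape.
# Returns list(layers = built, out_shape). Conv shapes are c(H, W, C);
# dense shapes are a single integer.
nn_build_stack <- function(specs, in_shape) {
  built <- vector("list", length(specs))
  shape <- in_shape
  for (i in seq_along(specs)) {
    l <- specs[[i]]
    switch(l$type,
      conv = {
        fan_in <- prod(l$kernel) * shape[3]
        l$W <- he_init(fan_in, l$filters, fan_in)
        l$b <- numeric(l$filters)
        l$in_shape <- shape
        shape <- c(conv_out_hw(shape[1], l$kernel[1], l$stride, l$padding),
                   conv_out_hw(shape[2], l$kernel[2], l$stride, l$padding),
                   l$filters)
      },
      maxpool = ,
      avgpool = {
        l$in_shape <- shape
        shape <- c(conv_out_hw(shape[1], l$pool, l$stride, l$padding),
                   conv_out_hw(shape[2], l$pool, l$stride, l$padding), shape[3])
      },
      gap = {
        l$in_shape <- shape
        shape <- shape[3]
      },
      dense = {
        stopifnot(length(shape) == 1L)
        l$W <- he_init(shape, l$units, shape)
        l$b <- numeric(l$units)
        l$in_dim <- shape
        shape <- l$units
      },
      batchnorm = {
        d <- if (length(shape) == 1L) shape else shape[3]
        l$gamma <- rep(1, d); l$beta <- numeric(d)
        l$run_mean <- numeric(d); l$run_var <- rep(1, d)
        l$conv <- length(shape) > 1L
      },
      dropout = NULL,
      relu = NULL,
      branch = {
        outs <- lapply(l$branches, nn_build_stack, in_shape = shape)
        hw <- lapply(outs, function(o) o$out_shape[1:2])
        if (length(unique(hw)) != 1L) stop("branch outputs disagree in spatial size")
        l$branches <- lapply(outs, `[[`, "layers")
        shape <- as.integer(c(hw[[1]], sum(vapply(outs, function(o) as.integer(o$out_shape[3]), 0L))))
      },
      residual = {
        body <- nn_build_stack(l$body, shape)
        l$body <- body$layers
        if (!is.null(l$shortcut)) {
          sc <- nn_build_stack(l$shortcut, shape)
          if (!identical(sc$out_shape, body$out_shape)) {
            stop("residual shortcut shape mismatch")
          }
          l$shortcut <- sc$layers
        } else if (!identical(shape, body$out_shape)) {
          stop("identity residual requires matching shapes")
        }
        shape <- body$out_shape
      },
      stop(sprintf("unknown layer type '%s'", l$type))
    )
    built[[i]] <- l
  }
  list(layers = built, out_shape = shape)
}

#' Build a network from layer specifications
#'
#' @param specs list of layer specifications (internal constructors).
#' @param input_shape `c(H, W, C)` for convolutional input or a single
#'   integer for dense input.
#' @param seed integer seed for He-normal weight initialization.
#' @return object of class `nn_net`.
#' @keywords internal
nn_network <- function(specs, input_shape, seed = 1L) {
  built <- with_seed(seed, nn_build_stack(specs, as.integer(input_shape)))
  structure(list(layers = built$layers, input_shape = as.integer(input_shape),
                 output_shape = built$out_shape, seed = seed),
            class = "nn_net")
}

# ---- forward pass --------------------------------------------------------

pad_tensor <- function(x, pt, pb, pl, pr, value = 0) {
  if (pt + pb + pl + pr == 0L) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1] + pt + pb, d[2] + pl + pr, d[3], d[4]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), , ] <- x
  out
}

same_pad <- function(hw, kernel, stride) {
  out <- ceiling(hw / stride)
  total <- max((out - 1L) * stride + kernel - hw, 0L)
  c(total %/% 2L, total - total %/% 2L)
}

# im2col index matrix for one padded plane set: rows are output positions
# (row-major fastest), columns are kernel offsets x input channels.
im2col_index <- function(hp, wp, cin, kh, kw, stride, oh, ow) {
  start_r <- (seq_len(oh) - 1L) * stride
  start_c <- (seq_len(ow) - 1L) * stride
  pos_r <- rep(start_r, ow)                      # oh*ow, row-major in oh
  pos_c <- rep(start_c, each = oh)
  off_r <- rep(seq_len(kh), kw)                  # kh*kw, kernel row fastest
  off_c <- rep(seq_len(kw), each = kh)
  base <- matrix(0L, oh * ow, kh * kw)
  for (k in seq_len(kh * kw)) {
    base[, k] <- (pos_r + off_r[k]) + (pos_c + off_c[k] - 1L) * hp
  }
  if (cin == 1L) return(base)
  plane <- hp * wp
  idx <- matrix(0L, oh * ow, kh * kw * cin)
  for (ch in seq_len(cin)) {
    idx[, (ch - 1L) * kh * kw + seq_len(kh * kw)] <- base + (ch - 1L) * plane
  }
  idx
}

conv_forward <- function(l, x, training = FALSE) {
  d <- dim(x); n <- d[4]; cin <- d[3]
  if (l$padding == "same") {
    pr <- same_pad(d[1], l$kernel[1], l$stride)
    pc <- same_pad(d[2], l$kernel[2], l$stride)
    x <- pad_tensor(x, pr[1], pr[2], pc[1], pc[2])
  }
  dp <- dim(x)
  oh <- conv_out_hw(d[1], l$kernel[1], l$stride, l$padding)
  ow <- conv_out_hw(d[2], l$kernel[2], l$stride, l$padding)
  idx <- im2col_index(dp[1], dp[2], cin, l$kernel[1], l$kernel[2], l$stride, oh, ow)
  out <- array(0, dim = c(oh, ow, l$filters, n))
  cache <- if (training) vector("list", n) else NULL
  plane <- dp[1] * dp[2] * cin
  xf <- as.vector(x)
  for (s in seq_len(n)) {
    P <- xf[idx + (s - 1L) * plane]
    dim(P) <- dim(idx)
    Y <- P %*% l$W
    Y <- Y + rep(l$b, each = oh * ow)
    out[, , , s] <- Y
    if (training) cache[[s]] <- P
  }
  list(out = out, cache = list(P = cache, idx = idx, padded_dim = dp, in_dim = d))
}

conv_backward <- function(l, cache, dy) {
  if (l$stride != 1L) stop("conv backward implemented for stride 1 only")
  d <- cache$in_dim; dp <- cache$padded_dim
  n <- d[4]; ohow <- dim(dy)[1] * dim(dy)[2]
  dW <- matrix(0, nrow(l$W), ncol(l$W))
  db <- numeric(length(l$b))
  dx <- array(0, dim = d)
  g <- as.vector(cache$idx)
  pr <- if (l$padding == "same") same_pad(d[1], l$kernel[1], l$stride) else c(0L, 0L)
  pc <- if (l$padding == "same") same_pad(d[2], l$kernel[2], l$stride) else c(0L, 0L)
  for (s in seq_len(n)) {
    dY <- matrix(dy[, , , s], ohow, l$filters)
    P <- cache$P[[s]]
    dW <- dW + crossprod(P, dY)
    db <- db + colSums(dY)
    dP <- dY %*% t(l$W)
    acc <- rowsum(as.vector(dP), group = g)
    dxp <- numeric(dp[1] * dp[2] * d[3])
    dxp[as.integer(rownames(acc))] <- acc
    dim(dxp) <- dp[1:3]
    dx[, , , s] <- dxp[pr[1] + seq_len(d[1]), pc[1] + seq_len(d[2]), , drop = FALSE]
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

pool_forward <- function(l, x, type) {
  d <- dim(x)
  pad_val <- if (type == "max") -Inf else 0
  if (l$padding == "same") {
    pr <- same_pad(d[1], l$pool, l$stride)
    pc <- same_pad(d[2], l$pool, l$stride)
    x <- pad_tensor(x, pr[1], pr[2], pc[1], pc[2], value = pad_val)
  }
  dp <- dim(x)
  oh <- conv_out_hw(d[1], l$pool, l$stride, l$padding)
  ow <- conv_out_hw(d[2], l$pool, l$stride, l$padding)
  idx <- im2col_index(dp[1], dp[2], 1L, l$pool, l$pool, l$stride, oh, ow)
  xm <- matrix(x, dp[1] * dp[2], dp[3] * dp[4])
  if (type == "max") {
    out <- xm[idx[, 1], , drop = FALSE]
    for (k in 2:ncol(idx)) out <- pmax(out, xm[idx[, k], , drop = FALSE])
  } else {
    out <- xm[idx[, 1], , drop = FALSE]
    for (k in 2:ncol(idx)) out <- out + xm[idx[, k], , drop = FALSE]
    out <- out / ncol(idx)
  }
  dim(out) <- c(oh, ow, d[3], d[4])
  list(out = out, cache = list(idx = idx, padded_dim = dp, in_dim = d))
}

avgpool_backward <- function(l, cache, dy) {
  d <- cache$in_dim; dp <- cache$padded_dim
  do <- dim(dy)
  dym <- matrix(dy, do[1] * do[2], do[3] * do[4]) / ncol(cache$idx)
  dxm <- matrix(0, dp[1] * dp[2], dp[3] * dp[4])
  for (k in seq_len(ncol(cache$idx))) {
    dxm[cache$idx[, k], ] <- dxm[cache$idx[, k], ] + dym
  }
  dim(dxm) <- dp
  pr <- if (l$padding == "same") same_pad(d[1], l$pool, l$stride) else c(0L, 0L)
  pc <- if (l$padding == "same") same_pad(d[2], l$pool, l$stride) else c(0L, 0L)
  dxm[pr[1] + seq_len(d[1]), pc[1] + seq_len(d[2]), , , drop = FALSE]
}

gap_forward <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  out <- matrix(colMeans(m), d[3], d[4])
  list(out = t(out), cache = list(in_dim = d))
}

gap_backward <- function(cache, dy) {
  d <- cache$in_dim
  per <- t(dy) / (d[1] * d[2])            # C x N
  array(rep(as.vector(per), each = d[1] * d[2]), dim = d)
}

bn_forward <- function(l, x, training, momentum = 0.9, eps = 1e-5) {
  if (l$conv) {
    # per-channel over (H, W, N); inference path only (frozen trunks)
    d <- dim(x)
    xp <- aperm(x, c(1, 2, 4, 3))
    m <- matrix(xp, ncol = d[3])
    y <- sweep(sweep(m, 2, l$run_mean), 2, sqrt(l$run_var + eps), `/`)
    y <- sweep(sweep(y, 2, l$gamma, `*`), 2, l$beta, `+`)
    dim(y) <- dim(xp)
    return(list(out = aperm(y, c(1, 2, 4, 3)), cache = NULL))
  }
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    l$run_mean <- momentum * l$run_mean + (1 - momentum) * mu
    l$run_var <- momentum * l$run_var + (1 - momentum) * v
    invstd <- 1 / sqrt(v + eps)
    xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
    out <- sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`)
    list(out = out, cache = list(xhat = xhat, invstd = invstd), layer = l)
  } else {
    xhat <- sweep(sweep(x, 2, l$run_mean), 2, sqrt(l$run_var + eps), `/`)
    list(out = sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`), cache = NULL)
  }
}

bn_backward <- function(l, cache, dy) {
  n <- nrow(dy)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, l$gamma, `*`)
  dx <- sweep(
    dxhat * n - matrix(colSums(dxhat), n, ncol(dy), byrow = TRUE) -
      xhat * matrix(colSums(dxhat * xhat), n, ncol(dy), byrow = TRUE),
    2, cache$invstd / n, `*`)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# Forward through a stack. training = TRUE collects caches for backward and
# uses batch statistics / dropout sampling. Returns list(out, caches, layers)
# where layers carries updated BN running stats.
stack_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    res <- switch(l$type,
      conv = conv_forward(l, x, training),
      relu = {
        cache <- if (training) (x > 0) else NULL
        list(out = pmax(x, 0), cache = cache)
      },
      maxpool = pool_forward(l, x, "max"),
      avgpool = pool_forward(l, x, "avg"),
      gap = gap_forward(x),
      dense = {
        cache <- if (training) x else NULL
        list(out = sweep(x %*% l$W, 2, l$b, `+`), cache = cache)
      },
      batchnorm = {
        r <- bn_forward(l, x, training)
        if (!is.null(r$layer)) layers[[i]] <- r$layer
        r
      },
      dropout = {
        if (training && l$rate > 0) {
          keep <- 1 - l$rate
          mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
          list(out = x * mask, cache = mask)
        } else list(out = x, cache = NULL)
      },
      branch = {
        outs <- lapply(l$branches, function(br) stack_forward(br, x, FALSE))
        pieces <- lapply(outs, `[[`, "out")
        ds <- lapply(pieces, dim)
        ctot <- sum(vapply(ds, `[`, 0L, 3))
        out <- array(0, dim = c(ds[[1]][1], ds[[1]][2], ctot, ds[[1]][4]))
        at <- 0L
        for (p in pieces) {
          out[, , at + seq_len(dim(p)[3]), ] <- p
          at <- at + dim(p)[3]
        }
        list(out = out, cache = NULL)
      },
      residual = {
        body <- stack_forward(l$body, x, FALSE)$out
        short <- if (is.null(l$shortcut)) x else stack_forward(l$shortcut, x, FALSE)$out
        out <- short + l$scale * body
        if (isTRUE(l$post_relu)) out <- pmax(out, 0)
        list(out = out, cache = NULL)
      },
      stop("unknown layer type")
    )
    x <- res$out
    caches[[i]] <- res$cache
  }
  list(out = x, caches = caches, layers = layers)
}

# Backward through a simple sequential stack. Returns list(dx, grads) where
# grads[[i]] holds the gradient list for layer i (NULL for parameter-free).
stack_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    switch(l$type,
      conv = {
        r <- conv_backward(l, caches[[i]], dy)
        dy <- r$dx; grads[[i]] <- r$grads
      },
      relu = { dy <- dy * caches[[i]] },
      avgpool = { dy <- avgpool_backward(l, caches[[i]], dy) },
      gap = { dy <- gap_backward(caches[[i]], dy) },
      dense = {
        x <- caches[[i]]
        grads[[i]] <- list(W = crossprod(x, dy), b = colSums(dy))
        dy <- dy %*% t(l$W)
      },
      batchnorm = {
        r <- bn_backward(l, caches[[i]], dy)
        dy <- r$dx; grads[[i]] <- r$grads
      },
      dropout = { if (!is.null(caches[[i]])) dy <- dy * caches[[i]] },
      stop(sprintf("backward not implemented for layer type '%s'", l$type))
    )
  }
  list(dx = dy, grads = grads)
}

# Layer types through which gradients can flow.
trainable_stack <- function(layers) {
  ok <- c("conv", "relu", "avgpool", "gap", "dense", "batchnorm", "dropout")
  all(vapply(layers, function(l) l$type %in% ok &&
               (l$type != "conv" || l$stride == 1L), TRUE))
}

#' Forward pass through a network
#'
#' @param net an `nn_net`.
#' @param x input tensor `H x W x C x N` or matrix `N x F`.
#' @return network output (matrix `N x units` after dense/gap layers).
#' @keywords internal
nn_forward <- function(net, x) {
  stack_forward(net$layers, x, training = FALSE)$out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Categorical cross-entropy
#'
#' `CE = -sum_i y_i log f_i(x)` for a predicted class-probability vector and
#' a one-hot (or integer) label. Zero exactly when the prediction puts all
#' mass on the true class.
#'
#' @param probs probability vector (or `n x C` matrix of row distributions).
#' @param label one-hot vector / matrix of the same shape, or 0-based integer
#'   labels when `probs` is a matrix.
#' @param tol tolerance for the probability-vector check.
#' @return mean cross-entropy over rows (a single non-negative number).
#' @export
categorical_cross_entropy <- function(probs, label, tol = 1e-6) {
  if (is.vector(probs)) probs <- matrix(probs, 1)
  if (any(probs < -tol) || any(abs(rowSums(probs) - 1) > tol)) {
    stop("probs rows must be probability vectors (non-negative, summing to 1)")
  }
  if (!is.matrix(label)) {
    label <- if (length(label) == ncol(probs) && nrow(probs) == 1L) {
      matrix(label, 1)                      # a single one-hot vector
    } else {
      one_hot(label, ncol(probs))           # 0-based integer labels
    }
  }
  if (!identical(dim(label), dim(probs))) {
    stop_shape("categorical_cross_entropy", dim(probs), dim(label))
  }
  p <- pmax(probs, 1e-12)
  mean(-rowSums(label * log(p)))
}

# SGD with per-epoch learning-rate schedule and optional L1 on kernels.
# `l1_on` is a predicate over layer index selecting L1-penalized kernels.
sgd_update <- function(layers, grads, lr, l1 = 0, l1_on = NULL) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    if (!is.null(l$trainable) && !l$trainable) next
    if (!is.null(g$W)) {
      pen <- if (l1 > 0 && (is.null(l1_on) || l1_on(i, l))) l1 * sign(l$W) else 0
      l$W <- l$W - lr * (g$W + pen)
      l$b <- l$b - lr * g$b
    }
    if (!is.null(g$gamma)) {
      l$gamma <- l$gamma - lr * g$gamma
      l$beta <- l$beta - lr * g$beta
    }
    layers[[i]] <- l
  }
  layers
}

# One training run over a simple sequential network with a softmax/CE head.
# y: 0-based integer labels. Returns list(net, history).
nn_train <- function(net, x, y, epochs, batch_size = 32L, schedule = lr_schedule(),
                     l1 = 0, l1_on = NULL, seed = 1L, shuffle = TRUE) {
  if (!trainable_stack(net$layers)) {
    stop("network contains layers without backward support; freeze the trunk instead")
  }
  n <- if (is.matrix(x)) nrow(x) else dim(x)[4]
  C <- net$output_shape
  Y <- one_hot(y, C)
  history <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                        accuracy = numeric())
  if (epochs == 0) return(list(net = net, history = history))
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      lr <- lr_at_epoch(ep - 1L, schedule)
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      tot_loss <- 0; tot_correct <- 0
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        xb <- if (is.matrix(x)) x[b, , drop = FALSE] else x[, , , b, drop = FALSE]
        yb <- Y[b, , drop = FALSE]
        fw <- stack_forward(net$layers, xb, training = TRUE)
        net$layers <- fw$layers
        p <- softmax_rows(fw$out)
        tot_loss <- tot_loss + sum(-rowSums(yb * log(pmax(p, 1e-12))))
        tot_correct <- tot_correct + sum(max.col(p) == max.col(yb))
        dlogits <- (p - yb) / length(b)
        bw <- stack_backward(net$layers, fw$caches, dlogits)
        net$layers <- sgd_update(net$layers, bw$grads, lr, l1, l1_on)
      }
      history <- rbind(history, data.frame(
        epoch = ep, lr = lr, loss = tot_loss / n, accuracy = tot_correct / n))
    }
  })
  list(net = net, history = history)
}

#' Learning-rate schedule
#'
#' Piecewise-constant schedule used throughout training: 0.1 for epochs 0-60,
#' 0.01 for 61-120, 0.001 for 121-180 and 0.0001 from epoch 181 on. Custom
#' breakpoints may be supplied for desk-scale runs.
#'
#' @param breaks integer epochs at which each rate takes effect.
#' @param rates learning rates, one per break.
#' @return object of class `lr_schedule`.
#' @export
lr_schedule <- function(breaks = c(0L, 61L, 121L, 181L),
                        rates = c(0.1, 0.01, 0.001, 0.0001)) {
  stopifnot(length(breaks) == length(rates), !is.unsorted(breaks))
  structure(list(breaks = as.integer(breaks), rates = rates), class = "lr_schedule")
}

#' Learning rate at a given epoch
#'
#' @param epoch integer epoch (0-based, matching the printed schedule).
#' @param schedule an [lr_schedule()].
#' @return the learning rate in force at `epoch`.
#' @export
lr_at_epoch <- function(epoch, schedule = lr_schedule()) {
  schedule$rates[findInterval(epoch, schedule$breaks)]
}

#' One-hot encode integer labels
#'
#' @param y 0-based integer labels.
#' @param C number of classes.
#' @return `length(y) x C` 0/1 matrix.
#' @export
one_hot <- function(y, C) {
  Y <- matrix(0, length(y), C)
  Y[cbind(seq_along(y), as.integer(y) + 1L)] <- 1
  Y
}
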