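# Layer constructors and per-layer forward/backward dispatch.
# A layer is a plain list: type, hyperparameters, trainable params (list of
# numeric arrays), non-trainable buffers.  Initialization is uniform on
# (-sqrt(1/fan_in), sqrt(1/fan_in)); biases start at zero.

.init_unif <- function(dims, fan_in) {
  a <- sqrt(1 / fan_in)
  array(stats::runif(prod(dims), -a, a), dims)
}

layer_dense <- function(n_in, n_out, bias = TRUE) {
  p <- list(w = .init_unif(c(n_out, n_in), n_in))
  if (bias) p$b <- numeric(n_out)
  list(type = "dense", n_in = n_in, n_out = n_out, bias = bias, params = p)
}

layer_conv1d <- function(f_in, f_out, kernel = 5L, bias = FALSE) {
  p <- list(w = .init_unif(c(kernel, f_in, f_out), kernel * f_in))
  if (bias) p$b <- numeric(f_out)
  list(type = "conv1d", kernel = kernel, bias = bias, params = p)
}

layer_conv2d <- function(c_in, c_out, kernel = c(4L, 4L), stride = c(2L, 2L),
                         padding = "same", bias = FALSE) {
  p <- list(w = .init_unif(c(kernel[1L], kernel[2L], c_in, c_out),
                           prod(kernel) * c_in))
  if (bias) p$b <- numeric(c_out)
  list(type = "conv2d", stride = stride, padding = padding, bias = bias,
       params = p)
}

layer_tconv2d <- function(c_in, c_out, kernel = c(4L, 4L), stride = c(1L, 1L),
                          bias = FALSE) {
  p <- list(w = .init_unif(c(kernel[1L], kernel[2L], c_in, c_out),
                           prod(kernel) * c_in))
  if (bias) p$b <- numeric(c_out)
  list(type = "tconv2d", stride = stride, bias = bias, params = p)
}

# Batch statistics are taken per feature over the batch axis; inference uses
# exponential running averages (momentum 0.9).  No learned affine: the
# normalization is the plain standardization y_hat = (y - mu_B)/sqrt(s2_B + eps).
layer_batchnorm <- function(n_features, conv = FALSE, eps = 1e-5,
                            momentum = 0.9) {
  list(type = "batchnorm", conv = conv, eps = eps, momentum = momentum,
       params = list(),
       buffers = list(r_mean = numeric(n_features), r_var = rep(1, n_features)))
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate, params = list())
layer_leaky <- function(alpha = 0.1) list(type = "leaky", alpha = alpha, params = list())
layer_sigmoid <- function() list(type = "sigmoid", params = list())
layer_log_softmax <- function() list(type = "log_softmax", params = list())
# conv (T,C,N,F) or (H,W,N,C) -> matrix (features, N)
layer_flatten <- function() list(type = "flatten", params = list())
# matrix (H*W*C, N) -> (H, W, N, C)
layer_reshape <- function(shape) list(type = "reshape", shape = shape, params = list())

.batch_to_last <- function(x) {
  # (a, b, N, c) -> matrix (a*b*c, N)
  xp <- aperm(x, c(1L, 2L, 4L, 3L))
  d <- dim(xp)
  dim(xp) <- c(d[1L] * d[2L] * d[3L], d[4L])
  xp
}

.batch_from_last <- function(m, dims) {
  # inverse of .batch_to_last; dims is the original (a, b, N, c)
  a <- array(m, c(dims[1L], dims[2L], dims[4L], dims[3L]))
  aperm(a, c(1L, 2L, 4L, 3L))
}

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    dense = {
      y <- layer$params$w %*% x
      if (layer$bias) y <- y + layer$params$b
      list(out = y, cache = list(x = x))
    },
    conv1d = list(out = conv1d_dw_forward(x, layer$params$w, layer$params$b),
                  cache = list(x = x)),
    conv2d = list(out = conv2d_forward(x, layer$params$w, layer$params$b,
                                       layer$stride, layer$padding),
                  cache = list(x = x)),
    tconv2d = list(out = tconv2d_forward(x, layer$params$w, layer$params$b,
                                         layer$stride),
                   cache = list(x = x)),
    leaky = list(out = pmax(x, 0) + layer$alpha * pmin(x, 0),
                 cache = list(x = x)),
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = list(y = y))
    },
    log_softmax = {
      mx <- apply(x, 2L, max)
      z <- x - rep(mx, each = nrow(x))
      lse <- log(colSums(exp(z)))
      y <- z - rep(lse, each = nrow(x))
      list(out = y, cache = list(y = y))
    },
    dropout = {
      if (!training || layer$rate <= 0) {
        list(out = x, cache = list(mask = NULL))
      } else {
        keep <- 1 - layer$rate
        mask <- (stats::runif(length(x)) < keep) / keep
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask))
      }
    },
    batchnorm = {
      dims <- dim(x)
      xm <- if (layer$conv) .batch_to_last(x) else x
      if (training) {
        mu <- rowMeans(xm)
        v <- rowMeans((xm - mu)^2)
      } else {
        mu <- layer$buffers$r_mean
        v <- layer$buffers$r_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- (xm - mu) * inv
      y <- if (layer$conv) .batch_from_last(xhat, dims) else xhat
      list(out = y,
           cache = list(xhat = xhat, inv = inv, dims = dims,
                        mu = if (training) mu else NULL,
                        v = if (training) v else NULL))
    },
    flatten = {
      m <- .batch_to_last(x)
      list(out = m, cache = list(dims = dim(x)))
    },
    reshape = {
      s <- layer$shape
      a <- array(x, c(s[1L], s[2L], s[3L], ncol(x)))
      list(out = aperm(a, c(1L, 2L, 4L, 3L)), cache = list(n = ncol(x)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    dense = {
      g <- list(w = dy %*% t(cache$x))
      if (layer$bias) g$b <- rowSums(dy)
      list(dx = crossprod(layer$params$w, dy), grads = g)
    },
    conv1d = {
      r <- conv1d_dw_backward(cache$x, layer$params$w, dy, layer$bias)
      list(dx = r$dx, grads = if (layer$bias) list(w = r$dw, b = r$db)
                              else list(w = r$dw))
    },
    conv2d = {
      r <- conv2d_backward(cache$x, layer$params$w, layer$stride,
                           layer$padding, dy, layer$bias)
      list(dx = r$dx, grads = if (layer$bias) list(w = r$dw, b = r$db)
                              else list(w = r$dw))
    },
    tconv2d = {
      r <- tconv2d_backward(cache$x, layer$params$w, layer$stride, dy,
                            layer$bias)
      list(dx = r$dx, grads = if (layer$bias) list(w = r$dw, b = r$db)
                              else list(w = r$dw))
    },
    leaky = {
      slope <- ifelse(cache$x > 0, 1, layer$alpha)
      list(dx = dy * slope, grads = list())
    },
    sigmoid = list(dx = dy * cache$y * (1 - cache$y), grads = list()),
    log_softmax = {
      p <- exp(cache$y)
      cs <- colSums(dy)
      list(dx = dy - p * rep(cs, each = nrow(p)), grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dy, grads = list())
      else list(dx = dy * cache$mask, grads = list())
    },
    batchnorm = {
      dym <- if (layer$conv) .batch_to_last(dy) else dy
      m1 <- rowMeans(dym)
      m2 <- rowMeans(dym * cache$xhat)
      dxm <- cache$inv * (dym - m1 - cache$xhat * m2)
      dx <- if (layer$conv) .batch_from_last(dxm, cache$dims) else dxm
      list(dx = dx, grads = list())
    },
    flatten = list(dx = .batch_from_last(dy, cache$dims), grads = list()),
    reshape = {
      a <- aperm(dy, c(1L, 2L, 4L, 3L))
      dim(a) <- c(length(a) / cache$n, cache$n)
      list(dx = a, grads = list())
    },
    stop("unknown layer type: ", layer$type)
  )
}
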