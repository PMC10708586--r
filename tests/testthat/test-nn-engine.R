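# The network engine: analytic gradients against numerical differentiation,
# batch-norm against a two-pass oracle, dropout statistics.

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + eps; xm[i] <- x[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution gradients match numerical differentiation", {
  set.seed(11)
  lossf <- function(y) sum(sin(y))
  # 2-D conv, both paddings and strides
  x <- array(rnorm(5 * 6 * 2 * 3), c(5, 6, 2, 3))
  w <- array(rnorm(4 * 4 * 3 * 2) * 0.3, c(4, 4, 3, 2))
  b <- rnorm(2)
  for (pad in c("same", "valid")) {
    s <- c(2L, 2L)
    y <- eegrecon:::conv2d_forward(x, w, b, s, pad)
    r <- eegrecon:::conv2d_backward(x, w, s, pad, cos(y), TRUE)
    expect_lt(max(abs(r$dx - num_grad(function(v)
      lossf(eegrecon:::conv2d_forward(v, w, b, s, pad)), x))), 1e-5)
    expect_lt(max(abs(r$dw - num_grad(function(v)
      lossf(eegrecon:::conv2d_forward(x, v, b, s, pad)), w))), 1e-5)
    expect_lt(max(abs(r$db - num_grad(function(v)
      lossf(eegrecon:::conv2d_forward(x, w, v, s, pad)), b))), 1e-5)
  }
  # transposed conv including the kernel-smaller-than-stride case
  xt <- array(rnorm(4 * 5 * 2 * 3), c(4, 5, 2, 3))
  for (kern in list(c(4L, 4L), c(1L, 4L))) {
    wt <- array(rnorm(prod(kern) * 3 * 2) * 0.3, c(kern, 3, 2))
    for (s in list(c(2L, 2L), c(3L, 3L))) {
      y <- eegrecon:::tconv2d_forward(xt, wt, NULL, s)
      expect_identical(dim(y)[1:2], c(dim(xt)[1] * s[1], dim(xt)[2] * s[2]))
      r <- eegrecon:::tconv2d_backward(xt, wt, s, cos(y), FALSE)
      expect_lt(max(abs(r$dx - num_grad(function(v)
        lossf(eegrecon:::tconv2d_forward(v, wt, NULL, s)), xt))), 1e-5)
      expect_lt(max(abs(r$dw - num_grad(function(v)
        lossf(eegrecon:::tconv2d_forward(xt, v, NULL, s)), wt))), 1e-5)
    }
  }
  # depthwise 1-D conv
  x1 <- array(rnorm(10 * 3 * 2 * 2), c(10, 3, 2, 2))
  w1 <- array(rnorm(5 * 2 * 3) * 0.3, c(5, 2, 3))
  y <- eegrecon:::conv1d_dw_forward(x1, w1, NULL)
  expect_identical(dim(y), c(10L, 3L, 2L, 3L))
  r <- eegrecon:::conv1d_dw_backward(x1, w1, cos(y), FALSE)
  expect_lt(max(abs(r$dx - num_grad(function(v)
    lossf(eegrecon:::conv1d_dw_forward(v, w1, NULL)), x1))), 1e-5)
  expect_lt(max(abs(r$dw - num_grad(function(v)
    lossf(eegrecon:::conv1d_dw_forward(x1, v, NULL)), w1))), 1e-5)
})

test_that("end-to-end backprop through a small network matches numerics", {
  set.seed(12)
  net <- eegrecon:::nn_sequential(
    list(eegrecon:::layer_dense(6L, 5L), eegrecon:::layer_leaky(0.1),
         eegrecon:::layer_batchnorm(5L), eegrecon:::layer_dense(5L, 3L),
         eegrecon:::layer_log_softmax()), "dense")
  x <- matrix(rnorm(6 * 8), 6, 8)
  labels <- sample(3L, 8L, replace = TRUE)
  fw <- eegrecon:::nn_forward(net, x, training = TRUE)
  l <- eegrecon:::nll_loss(fw$out, labels)
  bk <- eegrecon:::nn_backward(net, fw$caches, l$grad)
  p <- eegrecon:::nn_get_params(net)
  f <- function(wv) {
    n2 <- eegrecon:::nn_set_params(net, modifyList(p, list(`L01.w` = wv)))
    eegrecon:::nll_loss(eegrecon:::nn_forward(n2, x, training = TRUE)$out,
                        labels)$loss
  }
  expect_lt(max(abs(eegrecon:::nn_flatten_grads(bk$grads)$`L01.w` -
                      num_grad(f, p$`L01.w`))), 1e-4)
})

test_that("batch normalization matches the brute-force two-pass oracle", {
  set.seed(13)
  for (rep in 1:5) {
    batch <- matrix(rnorm(12 * 9, sd = runif(1, 0.5, 5)), 12, 9)
    out <- batch_normalize(batch, eps = 1e-5)
    oracle <- t(apply(batch, 1L, function(r) {
      mu <- sum(r) / length(r)
      v <- sum((r - mu)^2) / length(r)
      (r - mu) / sqrt(v + 1e-5)
    }))
    expect_lt(max(abs(out - oracle)), 1e-10)
    expect_lt(max(abs(rowMeans(out))), 1e-9)
  }
  # constant batch maps to zeros; two-point batches to ~(-1, +1)
  expect_true(all(batch_normalize(matrix(3, 4, 6)) == 0))
  two <- batch_normalize(matrix(c(-1, 1), 1, 2), eps = 1e-5)
  expect_equal(as.numeric(two), c(-1, 1), tolerance = 1e-4)
  expect_error(batch_normalize(matrix(numeric(0), 1, 0)), "empty")
})

test_that("dropout zeroes the expected fraction in training and none in eval", {
  lay <- eegrecon:::layer_dropout(0.2)
  x <- matrix(1, 200, 50)
  set.seed(14)
  y_tr <- eegrecon:::layer_forward(lay, x, training = TRUE)$out
  frac <- mean(y_tr == 0)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / length(x)))
  # retained units are rescaled so the expectation is preserved
  expect_equal(unique(y_tr[y_tr != 0]), 1 / 0.8)
  y_ev <- eegrecon:::layer_forward(lay, x, training = FALSE)$out
  expect_identical(y_ev, x)
})

test_that("gan losses agree with elementwise binary cross-entropy", {
  set.seed(15)
  for (rep in 1:10) {
    d_real <- runif(8, 0.01, 0.99)
    d_fake <- runif(8, 0.01, 0.99)
    gl <- gan_loss(d_real, d_fake)
    expect_lt(abs(gl$d_loss - (-mean(log(d_real)) - mean(log(1 - d_fake)))),
              1e-9)
    expect_lt(abs(gl$g_loss - (-mean(log(d_fake)))), 1e-9)
    expect_gte(gl$d_loss, 0)
    expect_gte(gl$g_loss, 0)
  }
  gl <- gan_loss(0.5, 0.5)
  expect_equal(gl$d_loss, 2 * log(2))
  expect_equal(gl$g_loss, log(2))
  expect_lt(gan_loss(1 - 1e-9, 1e-9)$d_loss, 1e-5)
  expect_lt(gan_loss(0.5, 1 - 1e-9)$g_loss, 1e-5)
})
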