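# Low-level tensor primitives for the network engine.
#
# Activation layouts (batch-size N):
#   dense : matrix (features, N)
#   conv1 : array  (T, C, N, F)   time x EEG-channel x batch x filter
#   conv2 : array  (H, W, N, C)   rows x cols x batch x channel
# Keeping the batch on the third axis of conv activations lets every
# kernel-offset slice flatten directly into an (positions*N, C_in) matrix in
# column-major order, so convolutions reduce to one BLAS matmul per offset.

# Asymmetric "same" padding (extra sample goes at the end): output ceil(n/s).
.same_pad <- function(n_in, k, s) {
  n_out <- as.integer(ceiling(n_in / s))
  pad <- max((n_out - 1L) * s + k - n_in, 0L)
  list(beg = pad %/% 2L, end = pad - pad %/% 2L, out = n_out)
}

.valid_out <- function(n_in, k, s) as.integer((n_in - k) %/% s + 1L)

.w_slice <- function(w, i, j) {
  # (kh, kw, cin, cout) -> (cin, cout) without accidental dim dropping
  matrix(w[i, j, , ], dim(w)[3L], dim(w)[4L])
}

# -- 2-D convolution (forward + backward) -------------------------------------

conv2d_forward <- function(x, w, b = NULL, stride = c(1L, 1L),
                           padding = c("same", "valid")) {
  padding <- match.arg(padding)
  d <- dim(x)
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cout <- dim(w)[4L]
  sh <- stride[1L]; sw <- stride[2L]
  if (dim(w)[3L] != d[4L]) stop("conv2d: channel mismatch")
  if (padding == "same") {
    ph <- .same_pad(d[1L], kh, sh); pw <- .same_pad(d[2L], kw, sw)
  } else {
    ph <- list(beg = 0L, end = 0L, out = .valid_out(d[1L], kh, sh))
    pw <- list(beg = 0L, end = 0L, out = .valid_out(d[2L], kw, sw))
  }
  hp <- d[1L] + ph$beg + ph$end; wp <- d[2L] + pw$beg + pw$end
  xp <- array(0, c(hp, wp, d[3L], d[4L]))
  xp[ph$beg + seq_len(d[1L]), pw$beg + seq_len(d[2L]), , ] <- x
  ho <- ph$out; wo <- pw$out
  ymat <- matrix(0, ho * wo * d[3L], cout)
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = sh, length.out = ho)
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = sw, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      dim(xs) <- c(ho * wo * d[3L], d[4L])
      ymat <- ymat + xs %*% .w_slice(w, i, j)
    }
  }
  if (!is.null(b)) ymat <- ymat + rep(b, each = ho * wo * d[3L])
  array(ymat, c(ho, wo, d[3L], cout))
}

conv2d_backward <- function(x, w, stride, padding, dy, has_bias = FALSE) {
  d <- dim(x)
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  sh <- stride[1L]; sw <- stride[2L]
  if (padding == "same") {
    ph <- .same_pad(d[1L], kh, sh); pw <- .same_pad(d[2L], kw, sw)
  } else {
    ph <- list(beg = 0L, end = 0L, out = .valid_out(d[1L], kh, sh))
    pw <- list(beg = 0L, end = 0L, out = .valid_out(d[2L], kw, sw))
  }
  hp <- d[1L] + ph$beg + ph$end; wp <- d[2L] + pw$beg + pw$end
  xp <- array(0, c(hp, wp, d[3L], d[4L]))
  xp[ph$beg + seq_len(d[1L]), pw$beg + seq_len(d[2L]), , ] <- x
  ho <- ph$out; wo <- pw$out
  dym <- dy; dim(dym) <- c(ho * wo * d[3L], cout)
  dxp <- array(0, dim(xp))
  dw <- array(0, dim(w))
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = sh, length.out = ho)
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = sw, length.out = wo)
      xs <- xp[rows, cols, , , drop = FALSE]
      dim(xs) <- c(ho * wo * d[3L], cin)
      dw[i, j, , ] <- crossprod(xs, dym)
      contrib <- dym %*% t(.w_slice(w, i, j))
      dim(contrib) <- c(ho, wo, d[3L], cin)
      dxp[rows, cols, , ] <- dxp[rows, cols, , , drop = FALSE] + contrib
    }
  }
  dx <- dxp[ph$beg + seq_len(d[1L]), pw$beg + seq_len(d[2L]), , , drop = FALSE]
  out <- list(dx = dx, dw = dw)
  if (has_bias) out$db <- colSums(dym)
  out
}

# -- 2-D transposed convolution ----------------------------------------------
# "Same"-style: output size = input * stride per dimension.  The full scatter
# output ((n-1)*s + k) is cropped symmetrically when k >= s and zero-extended
# at the end when k < s.

.tconv_fit <- function(n_in, k, s) {
  full <- (n_in - 1L) * s + k
  out <- n_in * s
  pad <- k - s
  beg <- if (pad > 0L) pad %/% 2L else 0L
  n_copy <- min(full - beg, out)
  list(full = full, out = out, src = beg + seq_len(n_copy), dst = seq_len(n_copy))
}

tconv2d_forward <- function(x, w, b = NULL, stride = c(1L, 1L)) {
  d <- dim(x)
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cout <- dim(w)[4L]
  sh <- stride[1L]; sw <- stride[2L]
  if (dim(w)[3L] != d[4L]) stop("tconv2d: channel mismatch")
  fh <- .tconv_fit(d[1L], kh, sh); fw <- .tconv_fit(d[2L], kw, sw)
  xm <- x; dim(xm) <- c(d[1L] * d[2L] * d[3L], d[4L])
  yfull <- array(0, c(fh$full, fw$full, d[3L], cout))
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = sh, length.out = d[1L])
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = sw, length.out = d[2L])
      contrib <- xm %*% .w_slice(w, i, j)
      dim(contrib) <- c(d[1L], d[2L], d[3L], cout)
      yfull[rows, cols, , ] <- yfull[rows, cols, , , drop = FALSE] + contrib
    }
  }
  y <- array(0, c(fh$out, fw$out, d[3L], cout))
  y[fh$dst, fw$dst, , ] <- yfull[fh$src, fw$src, , , drop = FALSE]
  if (!is.null(b)) y <- y + rep(b, each = fh$out * fw$out * d[3L])
  y
}

tconv2d_backward <- function(x, w, stride, dy, has_bias = FALSE) {
  d <- dim(x)
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  sh <- stride[1L]; sw <- stride[2L]
  fh <- .tconv_fit(d[1L], kh, sh); fw <- .tconv_fit(d[2L], kw, sw)
  dyfull <- array(0, c(fh$full, fw$full, d[3L], cout))
  dyfull[fh$src, fw$src, , ] <- dy[fh$dst, fw$dst, , , drop = FALSE]
  xm <- x; dim(xm) <- c(d[1L] * d[2L] * d[3L], cin)
  dxm <- matrix(0, nrow(xm), cin)
  dw <- array(0, dim(w))
  for (i in seq_len(kh)) {
    rows <- seq.int(i, by = sh, length.out = d[1L])
    for (j in seq_len(kw)) {
      cols <- seq.int(j, by = sw, length.out = d[2L])
      dys <- dyfull[rows, cols, , , drop = FALSE]
      dim(dys) <- c(d[1L] * d[2L] * d[3L], cout)
      dw[i, j, , ] <- crossprod(xm, dys)
      dxm <- dxm + dys %*% t(.w_slice(w, i, j))
    }
  }
  out <- list(dx = array(dxm, d), dw = dw)
  if (has_bias) {
    dym <- dy; dim(dym) <- c(length(dy) / cout, cout)
    out$db <- colSums(dym)
  }
  out
}

# -- Depthwise 1-D convolution over time -------------------------------------
# x: (T, C, N, F_in); w: (K, F_in, F_out).  The length-K kernel slides along
# the time axis, is shared across the C channel rows, and mixes the incoming
# filter axis.  Stride 1, same padding: T is preserved.

conv1d_dw_forward <- function(x, w, b = NULL) {
  d <- dim(x)
  k <- dim(w)[1L]; fin <- dim(w)[2L]; fout <- dim(w)[3L]
  if (fin != d[4L]) stop("conv1d: filter-axis mismatch")
  beg <- (k - 1L) %/% 2L; end <- k - 1L - beg
  xp <- array(0, c(d[1L] + k - 1L, d[2L], d[3L], fin))
  xp[beg + seq_len(d[1L]), , , ] <- x
  n <- d[1L] * d[2L] * d[3L]
  ymat <- matrix(0, n, fout)
  for (kk in seq_len(k)) {
    xs <- xp[seq.int(kk, length.out = d[1L]), , , , drop = FALSE]
    dim(xs) <- c(n, fin)
    ymat <- ymat + xs %*% matrix(w[kk, , ], fin, fout)
  }
  if (!is.null(b)) ymat <- ymat + rep(b, each = n)
  array(ymat, c(d[1L], d[2L], d[3L], fout))
}

conv1d_dw_backward <- function(x, w, dy, has_bias = FALSE) {
  d <- dim(x)
  k <- dim(w)[1L]; fin <- dim(w)[2L]; fout <- dim(w)[3L]
  beg <- (k - 1L) %/% 2L
  xp <- array(0, c(d[1L] + k - 1L, d[2L], d[3L], fin))
  xp[beg + seq_len(d[1L]), , , ] <- x
  n <- d[1L] * d[2L] * d[3L]
  dym <- dy; dim(dym) <- c(n, fout)
  dxp <- array(0, dim(xp))
  dw <- array(0, dim(w))
  for (kk in seq_len(k)) {
    idx <- seq.int(kk, length.out = d[1L])
    xs <- xp[idx, , , , drop = FALSE]
    dim(xs) <- c(n, fin)
    dw[kk, , ] <- crossprod(xs, dym)
    contrib <- dym %*% t(matrix(w[kk, , ], fin, fout))
    dim(contrib) <- c(d[1L], d[2L], d[3L], fin)
    dxp[idx, , , ] <- dxp[idx, , , , drop = FALSE] + contrib
  }
  dx <- dxp[beg + seq_len(d[1L]), , , , drop = FALSE]
  out <- list(dx = dx, dw = dw)
  if (has_bias) out$db <- colSums(dym)
  out
}
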