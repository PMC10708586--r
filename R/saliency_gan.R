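# Adversarial generator/discriminator pair mapping the classifier's feature
# vector to a saliency image.  Paper profile: 2500 -> dense 100 -> dense
# 20000 -> reshape (50,50,8) -> four 4x4 transposed convs (strides 2,3,1,1,
# six kernels) -> 2x2 valid conv -> 299x299x1.  Discriminator: three 4x4
# stride-2 convs with two kernels and dropout -> flatten 2888 -> dense 1 ->
# sigmoid.

#' Generator architecture specification
#'
#' The canonical output side is 299: with same-padded stride-2/3 transposed
#' convolutions the spatial chain runs 50 -> 100 -> 300 -> 300 -> 300, and the
#' final 2x2 stride-1 valid convolution lands exactly on 299.  Dense layers
#' and transposed convolutions are bias-free (matching the printed
#' 250,000 / 2,000,000 / 768 weight counts); the final convolution carries a
#' bias.  The `"desk"` profile keeps the stage structure on a 9x9x8 reshape
#' (side 53 = 9*2*3 - 1) with a 64-element input, for minutes-scale training.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param seed Initialization seed, default 42.
#' @param input_dim,dense_sizes,reshape,n_kernels Overrides for profile
#'   defaults.
#' @return A `generator_spec` list; `$side` is the output image side.
#' @export
generator_spec <- function(profile = c("paper", "desk"), seed = 42L,
                           input_dim = NULL, dense_sizes = NULL,
                           reshape = NULL, n_kernels = NULL) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    input_dim <- input_dim %||% 2500L
    reshape <- reshape %||% c(50L, 50L, 8L)
    dense_sizes <- dense_sizes %||% c(100L, prod(reshape))
    n_kernels <- n_kernels %||% 6L
  } else {
    input_dim <- input_dim %||% 64L
    reshape <- reshape %||% c(9L, 9L, 8L)
    dense_sizes <- dense_sizes %||% c(32L, prod(reshape))
    n_kernels <- n_kernels %||% 4L
  }
  if (dense_sizes[2L] != prod(reshape)) {
    stop("second dense size must equal prod(reshape)")
  }
  side <- reshape[1L] * 2L * 3L - 1L
  structure(list(profile = profile, input_dim = as.integer(input_dim),
                 dense_sizes = as.integer(dense_sizes),
                 reshape = as.integer(reshape),
                 n_kernels = as.integer(n_kernels),
                 strides = list(c(2L, 2L), c(3L, 3L), c(1L, 1L), c(1L, 1L)),
                 kernel = c(4L, 4L), final_kernel = c(2L, 2L),
                 leaky_alpha = 0.1, side = as.integer(side),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Discriminator architecture specification
#'
#' Three same-padded 4x4 stride-2 convolutions with two kernels each
#' (bias-free, matching the printed 32-weight first stage), dropout 0.2 after
#' each, then flatten and a biased dense head to a sigmoid probability.  On a
#' 299-pixel input the spatial chain is 299 -> 150 -> 75 -> 38 and the flatten
#' length 38*38*2 = 2888 (head: 2889 weights); on the 53-pixel desk side it is
#' 53 -> 27 -> 14 -> 7.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param seed Initialization seed, default 43.
#' @param side Input image side; defaults to the profile's canonical side.
#' @param n_kernels Kernels per conv stage, default 2.
#' @param dropout_rate Default 0.2.
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(profile = c("paper", "desk"), seed = 43L,
                               side = NULL, n_kernels = 2L,
                               dropout_rate = 0.2) {
  profile <- match.arg(profile)
  side <- side %||% (if (profile == "paper") 299L else 53L)
  chain <- as.integer(side)
  for (i in 1:3) chain <- c(chain, as.integer(ceiling(chain[length(chain)] / 2)))
  structure(list(profile = profile, side = as.integer(side),
                 n_kernels = as.integer(n_kernels), kernel = c(4L, 4L),
                 stride = c(2L, 2L), dropout_rate = dropout_rate,
                 leaky_alpha = 0.1, chain = chain,
                 flatten = as.integer(chain[4L]^2 * n_kernels),
                 seed = as.integer(seed)),
            class = "discriminator_spec")
}

#' Build the saliency generator network
#'
#' @param spec A [generator_spec()].
#' @return An `eegnet` mapping (input_dim x N) feature matrices to
#'   (side, side, N, 1) image tensors.
#' @export
build_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  ch <- spec$reshape[3L]
  nk <- spec$n_kernels
  layers <- list(
    layer_dense(spec$input_dim, spec$dense_sizes[1L], bias = FALSE),
    layer_dense(spec$dense_sizes[1L], spec$dense_sizes[2L], bias = FALSE),
    layer_leaky(spec$leaky_alpha),
    layer_reshape(spec$reshape))
  cin <- ch
  for (s in spec$strides) {
    layers <- c(layers, list(
      layer_tconv2d(cin, nk, spec$kernel, s, bias = FALSE),
      layer_leaky(spec$leaky_alpha)))
    cin <- nk
  }
  layers <- c(layers, list(
    layer_conv2d(cin, 1L, spec$final_kernel, c(1L, 1L), padding = "valid",
                 bias = TRUE),
    layer_leaky(spec$leaky_alpha)))
  nn_sequential(layers, input_kind = "dense",
                meta = list(kind = "generator", spec = spec,
                            profile = spec$profile, side = spec$side))
}

#' Build the saliency discriminator network
#'
#' @param spec A [discriminator_spec()].
#' @return An `eegnet` mapping (side, side, N, 1) images to a 1 x N matrix of
#'   real-image probabilities.
#' @export
build_discriminator <- function(spec) {
  stopifnot(inherits(spec, "discriminator_spec"))
  set.seed(spec$seed)
  layers <- list()
  cin <- 1L
  for (i in 1:3) {
    layers <- c(layers, list(
      layer_conv2d(cin, spec$n_kernels, spec$kernel, spec$stride,
                   padding = "same", bias = FALSE),
      layer_leaky(spec$leaky_alpha),
      layer_dropout(spec$dropout_rate)))
    cin <- spec$n_kernels
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(spec$flatten, 1L, bias = TRUE),
    layer_sigmoid()))
  nn_sequential(layers, input_kind = "conv2",
                meta = list(kind = "discriminator", spec = spec,
                            profile = spec$profile, side = spec$side))
}

#' GAN batch losses under binary cross-entropy
#'
#' Discriminator loss `-mean(log d_real) - mean(log(1 - d_fake))`; generator
#' loss in the non-saturating form `-mean(log d_fake)`.  Probabilities are
#' clamped at 1e-7.
#'
#' @param d_real,d_fake Discriminator probabilities on real and generated
#'   batches.
#' @param clamp Probability clamp, default 1e-7.
#' @return List `d_loss_real`, `d_loss_fake`, `d_loss`, `g_loss`.
#' @export
gan_loss <- function(d_real, d_fake, clamp = 1e-7) {
  r <- pmin(pmax(as.numeric(d_real), clamp), 1 - clamp)
  f <- pmin(pmax(as.numeric(d_fake), clamp), 1 - clamp)
  list(d_loss_real = -mean(log(r)), d_loss_fake = -mean(log(1 - f)),
       d_loss = -mean(log(r)) - mean(log(1 - f)), g_loss = -mean(log(f)))
}

# One optimizer update of `net` given loss gradient at the output.
.gan_update <- function(net, caches, dout, opt) {
  bk <- nn_backward(net, caches, dout)
  st <- optimizer_step(opt, nn_get_params(net), nn_flatten_grads(bk$grads))
  list(net = nn_set_params(net, st$params), opt = st$opt)
}

maps_to_tensor <- function(maps, side) {
  x <- array(0, c(side, side, length(maps), 1L))
  for (i in seq_along(maps)) {
    v <- if (inherits(maps[[i]], "saliency_map")) maps[[i]]$values
         else if (inherits(maps[[i]], "stimulus_image")) maps[[i]]$pixels
         else as.matrix(maps[[i]])
    mx <- max(v)
    x[, , i, 1L] <- if (mx > 0) v / mx else v   # unit-range targets
  }
  x
}

#' GAN training configuration
#'
#' @param iterations Alternating D/G steps, default 300.
#' @param batch_size Default 8.
#' @param lr Adam learning rate, default 1e-4.
#' @param seed RNG seed, default 42.
#' @param track_every Interval for SSIM/CC tracking when targets are tracked
#'   (0 = never), default 0.
#' @return A `gan_config` list.
#' @export
gan_config <- function(iterations = 300L, batch_size = 8L, lr = 1e-4,
                       seed = 42L, track_every = 0L) {
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), track_every = as.integer(track_every)),
            class = "gan_config")
}

#' Train the feature-to-saliency GAN
#'
#' Alternating single discriminator and generator Adam steps per iteration
#' (one D step, one G step), real label 1 / fake label 0, binary
#' cross-entropy.  Per-iteration generator and discriminator losses are
#' recorded; optionally mean SSIM/CC of generated maps against targets at
#' `track_every` intervals.  Deterministic given `config$seed`.
#'
#' @param features Feature matrix (input_dim x N) or list of feature vectors.
#' @param targets Index-aligned list of target maps/images (rescaled to unit
#'   range internally).
#' @param gen,disc Networks from [build_generator()]/[build_discriminator()];
#'   defaults are built from `profile`.
#' @param config A [gan_config()].
#' @param profile Used when `gen`/`disc` are not supplied.
#' @return An `eeg_gan`: list with `generator`, `discriminator`, `history`
#'   (iteration, d_loss, g_loss, and ssim/cc when tracked), `config`.
#' @export
train_gan <- function(features, targets, gen = NULL, disc = NULL,
                      config = gan_config(), profile = "desk") {
  if (is.list(features)) features <- do.call(cbind, features)
  features <- as.matrix(features)
  if (ncol(features) != length(targets)) {
    stop("features and targets must be aligned")
  }
  if (is.null(gen)) gen <- build_generator(generator_spec(profile))
  if (is.null(disc)) disc <- build_discriminator(discriminator_spec(profile))
  side <- gen$meta$side
  if (disc$meta$side != side) stop("generator/discriminator side mismatch")
  if (nrow(features) != gen$meta$spec$input_dim) {
    stop("feature length ", nrow(features), " does not match generator input ",
         gen$meta$spec$input_dim)
  }
  y <- maps_to_tensor(targets, side)
  n <- ncol(features)
  set.seed(config$seed)
  opt_d <- optimizer_adam(lr = config$lr)
  opt_g <- optimizer_adam(lr = config$lr)
  hist <- data.frame(iteration = seq_len(config$iterations),
                     d_loss = NA_real_, g_loss = NA_real_,
                     ssim = NA_real_, cc = NA_real_)
  for (it in seq_len(config$iterations)) {
    take <- sample(n, min(config$batch_size, n))
    xb <- features[, take, drop = FALSE]
    yb <- y[, , take, , drop = FALSE]

    # -- discriminator step
    fake <- nn_forward(gen, xb, training = FALSE, keep_cache = FALSE)$out
    fw_r <- nn_forward(disc, yb, training = TRUE)
    disc <- fw_r$net
    l_r <- bce_loss(fw_r$out, 1)
    upd <- .gan_update(disc, fw_r$caches, l_r$grad, opt_d)
    disc <- upd$net; opt_d <- upd$opt
    fw_f <- nn_forward(disc, fake, training = TRUE)
    disc <- fw_f$net
    l_f <- bce_loss(fw_f$out, 0)
    upd <- .gan_update(disc, fw_f$caches, l_f$grad, opt_d)
    disc <- upd$net; opt_d <- upd$opt

    # -- generator step (non-saturating: push D(fake) toward 1)
    fw_g <- nn_forward(gen, xb, training = TRUE)
    gen <- fw_g$net
    fw_d <- nn_forward(disc, fw_g$out, training = TRUE)
    l_g <- bce_loss(fw_d$out, 1)
    bk_d <- nn_backward(disc, fw_d$caches, l_g$grad)
    upd <- .gan_update(gen, fw_g$caches, bk_d$dx, opt_g)
    gen <- upd$net; opt_g <- upd$opt

    gl <- gan_loss(fw_r$out, fw_f$out)
    if (!is.finite(gl$d_loss) || !is.finite(l_g$loss)) {
      stop("divergence: non-finite GAN loss at iteration ", it)
    }
    hist$d_loss[it] <- gl$d_loss
    hist$g_loss[it] <- l_g$loss
    if (config$track_every > 0L &&
        (it %% config$track_every == 0L || it == config$iterations)) {
      m <- .gan_track_metrics(gen, features, y)
      hist$ssim[it] <- m[1L]
      hist$cc[it] <- m[2L]
    }
  }
  structure(list(generator = gen, discriminator = disc, history = hist,
                 config = config),
            class = "eeg_gan")
}

# Mean SSIM and CC of generated maps against target tensor y (unit-range).
.gan_track_metrics <- function(gen, features, y) {
  out <- nn_forward(gen, features, training = FALSE, keep_cache = FALSE)$out
  s_v <- numeric(dim(y)[3L]); c_v <- numeric(dim(y)[3L])
  for (i in seq_len(dim(y)[3L])) {
    g <- pmax(out[, , i, 1L], 0)
    mx <- max(g); if (mx > 0) g <- g / mx
    s_v[i] <- ssim(g, y[, , i, 1L])
    c_v[i] <- if (stats::sd(g) == 0 || stats::sd(y[, , i, 1L]) == 0) 0
              else stats::cor(as.vector(g), as.vector(y[, , i, 1L]))
  }
  c(mean(s_v), mean(c_v))
}

#' @export
print.eeg_gan <- function(x, ...) {
  cat("<eeg_gan> side", x$generator$meta$side, "-",
      attr(count_parameters(x$generator), "total"), "generator +",
      attr(count_parameters(x$discriminator), "total"),
      "discriminator weights\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("after %d iterations: d_loss %.4f, g_loss %.4f\n",
              last$iteration, last$d_loss, last$g_loss))
  invisible(x)
}

#' Generate a saliency map from a feature vector
#'
#' @param generator An `eeg_gan` or generator `eegnet`.
#' @param feature Feature vector (or matrix, one column per record).
#' @return A non-negative `saliency_map` (side x side); for matrix input a
#'   list of maps.
#' @export
generate_saliency <- function(generator, feature) {
  gen <- if (inherits(generator, "eeg_gan")) generator$generator else generator
  f <- as.matrix(feature)
  if (nrow(f) != gen$meta$spec$input_dim) {
    stop("feature length ", nrow(f), " does not match generator input ",
         gen$meta$spec$input_dim)
  }
  out <- nn_forward(gen, f, training = FALSE, keep_cache = FALSE)$out
  maps <- lapply(seq_len(ncol(f)), function(i) {
    saliency_map(pmax(out[, , i, 1L], 0))
  })
  if (ncol(f) == 1L) maps[[1L]] else maps
}
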