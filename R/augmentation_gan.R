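# Per-class GAN that synthesizes 14 x 250 EEG signals for dataset
# augmentation.  Generator: latent 100 -> dense 7*125*8 -> reshape (7,125,8)
# -> two stride-1 1x4 transposed convs (8 kernels) -> stride-2 transposed conv
# to (14,250,1).  Discriminator: three 1x4 convs (6 kernels, strides 1,2,1)
# with dropout -> flatten 5250 -> dense 1 -> sigmoid.

#' EEG-augmentation GAN architecture specification
#'
#' The final transposed convolution uses a 2x4 kernel: a kernel of height 1
#' with row stride 2 would leave every second channel row structurally zero,
#' which cannot emulate 14-channel EEG; height 2 equals the stride and covers
#' all rows.  The final stage emits a single channel so the output is a
#' 14 x 250 signal matrix.  Activations are leaky ReLU with slope 0.3.
#'
#' @param latent_dim Generator input dimension (standard normal), default 100.
#' @param seed Initialization seed, default 42.
#' @return An `eeg_gan_spec` list.
#' @export
eeg_gan_spec <- function(latent_dim = 100L, seed = 42L) {
  structure(list(latent_dim = as.integer(latent_dim),
                 dense_to = c(7L, 125L, 8L),
                 gen_kernels = c(8L, 8L, 1L),
                 disc_kernels = 6L,
                 leaky_alpha = 0.3, dropout_rate = 0.2,
                 n_channels = 14L, n_samples = 250L,
                 seed = as.integer(seed)),
            class = "eeg_gan_spec")
}

#' Build the EEG-signal generator
#'
#' @param spec An [eeg_gan_spec()].
#' @return An `eegnet` mapping (latent_dim x N) to (14, 250, N, 1).
#' @export
build_eeg_generator <- function(spec) {
  stopifnot(inherits(spec, "eeg_gan_spec"))
  set.seed(spec$seed)
  ch <- spec$dense_to[3L]
  layers <- list(
    layer_dense(spec$latent_dim, prod(spec$dense_to), bias = FALSE),
    layer_reshape(spec$dense_to),
    layer_tconv2d(ch, spec$gen_kernels[1L], c(1L, 4L), c(1L, 1L)),
    layer_leaky(spec$leaky_alpha),
    layer_tconv2d(spec$gen_kernels[1L], spec$gen_kernels[2L], c(1L, 4L),
                  c(1L, 1L)),
    layer_leaky(spec$leaky_alpha),
    layer_tconv2d(spec$gen_kernels[2L], spec$gen_kernels[3L], c(2L, 4L),
                  c(2L, 2L)))
  nn_sequential(layers, input_kind = "dense",
                meta = list(kind = "eeg_generator", spec = spec))
}

#' Build the EEG-signal discriminator
#'
#' Spatial chain (14,250) -> (14,250) -> (7,125) -> (7,125) for strides
#' 1, 2, 1; flatten length 7*125*6 = 5250.
#'
#' @param spec An [eeg_gan_spec()].
#' @return An `eegnet` mapping (14, 250, N, 1) to 1 x N probabilities.
#' @export
build_eeg_discriminator <- function(spec) {
  stopifnot(inherits(spec, "eeg_gan_spec"))
  set.seed(spec$seed + 1L)
  k <- spec$disc_kernels
  strides <- list(c(1L, 1L), c(2L, 2L), c(1L, 1L))
  layers <- list()
  cin <- 1L
  for (s in strides) {
    layers <- c(layers, list(
      layer_conv2d(cin, k, c(1L, 4L), s, padding = "same", bias = FALSE),
      layer_leaky(spec$leaky_alpha),
      layer_dropout(spec$dropout_rate)))
    cin <- k
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(7L * 125L * k, 1L, bias = TRUE),
    layer_sigmoid()))
  nn_sequential(layers, input_kind = "conv2",
                meta = list(kind = "eeg_discriminator", spec = spec))
}

# records (channels x time) -> (H=14, W=250, N, 1) tensor, per-record scaled
# to unit absolute range so the GAN trains on O(1) values; the scale is
# restored on generation via the training set's median scale.
.records_to_image_tensor <- function(records) {
  n <- length(records)
  x <- array(0, c(14L, ncol(records[[1L]]$signal), n, 1L))
  scales <- numeric(n)
  for (i in seq_len(n)) {
    s <- max(abs(records[[i]]$signal))
    scales[i] <- if (s > 0) s else 1
    x[, , i, 1L] <- records[[i]]$signal / scales[i]
  }
  list(x = x, scale = stats::median(scales))
}

#' Train the augmentation GAN on a single class
#'
#' Same alternating adversarial loop as [train_gan()] (Adam, real = 1,
#' fake = 0, binary cross-entropy), with a standard-normal latent input.
#' One GAN is trained per class.
#'
#' @param records Labeled `eeg_record`s of one single class.
#' @param spec An [eeg_gan_spec()].
#' @param config A [gan_config()]; the desk-scale default is 300 iterations
#'   (full-scale runs use far more).
#' @return An `eeg_aug_gan`: `generator`, `discriminator`, `history`,
#'   `label`, `scale` (microvolt scale restored on generation).
#' @export
train_augmentation_gan <- function(records, spec = eeg_gan_spec(),
                                   config = gan_config()) {
  labels <- record_labels(records)
  if (length(unique(labels)) != 1L) {
    stop("augmentation GAN expects records of a single class, got ",
         length(unique(labels)))
  }
  gen <- build_eeg_generator(spec)
  disc <- build_eeg_discriminator(spec)
  td <- .records_to_image_tensor(records)
  n <- length(records)
  set.seed(config$seed)
  opt_d <- optimizer_adam(lr = config$lr)
  opt_g <- optimizer_adam(lr = config$lr)
  hist <- data.frame(iteration = seq_len(config$iterations),
                     d_loss = NA_real_, g_loss = NA_real_)
  for (it in seq_len(config$iterations)) {
    take <- sample(n, min(config$batch_size, n))
    yb <- td$x[, , take, , drop = FALSE]
    zb <- matrix(stats::rnorm(spec$latent_dim * length(take)),
                 spec$latent_dim)

    fake <- nn_forward(gen, zb, training = FALSE, keep_cache = FALSE)$out
    fw_r <- nn_forward(disc, yb, training = TRUE)
    disc <- fw_r$net
    upd <- .gan_update(disc, fw_r$caches, bce_loss(fw_r$out, 1)$grad, opt_d)
    disc <- upd$net; opt_d <- upd$opt
    fw_f <- nn_forward(disc, fake, training = TRUE)
    disc <- fw_f$net
    upd <- .gan_update(disc, fw_f$caches, bce_loss(fw_f$out, 0)$grad, opt_d)
    disc <- upd$net; opt_d <- upd$opt

    fw_g <- nn_forward(gen, zb, training = TRUE)
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
  }
  structure(list(generator = gen, discriminator = disc, history = hist,
                 label = labels[1L], scale = td$scale, config = config),
            class = "eeg_aug_gan")
}

#' @export
print.eeg_aug_gan <- function(x, ...) {
  cat("<eeg_aug_gan> class", x$label, "-",
      nrow(x$history), "iterations trained\n")
  invisible(x)
}

#' Sample synthetic EEG records from a trained augmentation GAN
#'
#' @param gan An `eeg_aug_gan` (or a bare generator `eegnet` plus `label`).
#' @param n Number of records.
#' @param seed Latent seed.
#' @return List of `eeg_record`s labeled with the GAN's class and record ids
#'   flagged `gan-<class>-<i>`.
#' @export
sample_augmented_records <- function(gan, n = 1L, seed = 42L) {
  stopifnot(inherits(gan, "eeg_aug_gan"))
  spec <- gan$generator$meta$spec
  set.seed(seed)
  z <- matrix(stats::rnorm(spec$latent_dim * n), spec$latent_dim)
  out <- nn_forward(gan$generator, z, training = FALSE, keep_cache = FALSE)$out
  lapply(seq_len(n), function(i) {
    eeg_record(out[, , i, 1L] * gan$scale, label = gan$label,
               record_id = sprintf("gan-%d-%d", gan$label, i))
  })
}

#' Augment a dataset with GAN-generated records
#'
#' Appends `n_sets` generated records per class (one trained GAN per class)
#' with class labels and a `gan-` provenance prefix on the record id; the
#' returned manifest reflects the enlarged set.
#'
#' @param records Base dataset.
#' @param generators Named list of `eeg_aug_gan`s, names = class labels
#'   covering every class present in `records`.
#' @param n_sets Generated records per class.
#' @param seed Latent seed.
#' @return List with `records` (base + synthetic) and `manifest`.
#' @export
augment_dataset <- function(records, generators, n_sets, seed = 42L) {
  labels <- unique(record_labels(records))
  missing <- setdiff(as.character(labels), names(generators))
  if (length(missing) > 0L) {
    stop("missing generator for class(es): ", paste(missing, collapse = ", "))
  }
  extra <- list()
  if (n_sets > 0L) {
    for (cl in as.character(sort(labels))) {
      extra <- c(extra, sample_augmented_records(generators[[cl]], n_sets,
                                                 seed = seed + as.integer(cl)))
    }
  }
  all_records <- c(records, extra)
  list(records = all_records,
       manifest = build_manifest(all_records, source = "augmented"),
       n_generated = length(extra))
}
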