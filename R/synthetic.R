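# Class-conditioned synthetic data: EEG records with a per-class spectral
# signature, white-on-black digit stimulus images, and blurred-mask saliency
# targets standing in for eye-tracking-derived fixation maps.

#' Configuration for the synthetic paired dataset
#'
#' The generative model for class k puts, on channel c,
#' `amp_matrix[k, c] * sin(2*pi*class_freqs[k]*t + phi_c)` plus Gaussian noise
#' of standard deviation `noise_sd`, sampled at 128 Hz for 250 samples.  The
#' class identity is therefore a dominant oscillation frequency, which makes
#' separability analytically controllable: the per-channel periodogram of a
#' class-k record peaks at `class_freqs[k]`.  Channel phases `phi_c` are fixed
#' by the seed so channels are mutually distinguishable.
#'
#' @param n_per_class Records per class; default 912, the per-category count
#'   of the real corpus the generator stands in for.
#' @param n_classes Number of digit classes (<= 10), default 10.
#' @param seed Integer seed; every stream (signals, phases, noise) derives
#'   from it.
#' @param class_freqs Per-class oscillation frequencies in Hz; default spreads
#'   2..29 Hz (delta through beta band) across the classes, below the 64 Hz
#'   Nyquist limit.
#' @param amp_matrix `n_classes` x 14 amplitude matrix in microvolts; default
#'   10 uV everywhere (class identity is carried by frequency, not amplitude).
#' @param noise_sd Additive Gaussian noise sd in microvolts; default 2.
#' @param image_size Stimulus/saliency image side in pixels; default 299, the
#'   canonical generator output side.
#' @param blur_sigma Gaussian blur sd in pixels for the saliency proxy;
#'   default `image_size/20`.
#' @param n_samples Samples per channel; default 250.
#' @param sampling_rate Hz; default 128.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_per_class = 912L, n_classes = 10L, seed = 42L,
                         class_freqs = NULL, amp_matrix = NULL,
                         noise_sd = 2, image_size = 299L,
                         blur_sigma = image_size / 20,
                         n_samples = 250L, sampling_rate = 128) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L || n_classes > 10L) stop("n_classes must be in 1..10")
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (is.null(class_freqs)) {
    class_freqs <- if (n_classes == 1L) 10 else
      seq(2, 29, length.out = n_classes)
  }
  if (length(class_freqs) != n_classes) stop("need one frequency per class")
  if (any(class_freqs >= sampling_rate / 2)) {
    stop("class frequencies must lie below the Nyquist limit (",
         sampling_rate / 2, " Hz)")
  }
  if (is.null(amp_matrix)) amp_matrix <- matrix(10, n_classes, 14L)
  amp_matrix <- as.matrix(amp_matrix)
  if (!all(dim(amp_matrix) == c(n_classes, 14L))) {
    stop("amp_matrix must be n_classes x 14")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (image_size < 28L) stop("image_size must be >= 28")
  if (blur_sigma <= 0) stop("blur_sigma must be > 0")
  structure(list(n_per_class = as.integer(n_per_class),
                 n_classes = n_classes, seed = as.integer(seed),
                 class_freqs = class_freqs, amp_matrix = amp_matrix,
                 noise_sd = noise_sd, image_size = as.integer(image_size),
                 blur_sigma = blur_sigma, n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate),
            class = "synth_config")
}

#' Generate a class-conditioned synthetic EEG dataset
#'
#' @param config A [synth_config()].
#' @return A list of `n_per_class * n_classes` validated `eeg_record`s,
#'   grouped by class (class 0 first), deterministic given `config$seed`.
#' @export
generate_eeg_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  phi <- stats::runif(14L, 0, 2 * pi)   # per-channel phase offsets
  tt <- (seq_len(config$n_samples) - 1L) / config$sampling_rate
  records <- vector("list", config$n_per_class * config$n_classes)
  i <- 0L
  for (k in seq_len(config$n_classes)) {
    base <- config$amp_matrix[k, ] *
      sin(outer(phi, 2 * pi * config$class_freqs[k] * tt, `+`))
    for (r in seq_len(config$n_per_class)) {
      i <- i + 1L
      noise <- if (config$noise_sd > 0) {
        matrix(stats::rnorm(14L * config$n_samples, sd = config$noise_sd),
               14L, config$n_samples)
      } else 0
      records[[i]] <- eeg_record(base + noise, label = k - 1L,
                                 record_id = sprintf("synth-%d-%d", k - 1L, r),
                                 sampling_rate = config$sampling_rate)
    }
  }
  records
}

# 5x7 bitmap glyphs for digits 0-9 (rows top to bottom, '1' = foreground).
.DIGIT_GLYPHS <- list(
  c("01110","10001","10011","10101","11001","10001","01110"),
  c("00100","01100","00100","00100","00100","00100","01110"),
  c("01110","10001","00001","00110","01000","10000","11111"),
  c("01110","10001","00001","00110","00001","10001","01110"),
  c("00010","00110","01010","10010","11111","00010","00010"),
  c("11111","10000","11110","00001","00001","10001","01110"),
  c("01110","10001","10000","11110","10001","10001","01110"),
  c("11111","00001","00010","00100","01000","01000","01000"),
  c("01110","10001","10001","01110","10001","10001","01110"),
  c("01110","10001","10001","01111","00001","10001","01110"))

.digit_base_grid <- function(digit) {
  rows <- .DIGIT_GLYPHS[[digit + 1L]]
  g <- t(vapply(rows, function(r) as.numeric(strsplit(r, "")[[1]]),
                numeric(5L)))
  # center the 7x5 glyph on a 9x9 square canvas
  canvas <- matrix(0, 9L, 9L)
  canvas[2:8, 3:7] <- g
  canvas
}

#' Render a digit stimulus image
#'
#' A white glyph on a black background, from a built-in 5x7 bitmap glyph set
#' centered on a 9x9 canvas and nearest-neighbour upscaled to the requested
#' side.  Values are exactly 0 or 1.
#'
#' @param digit Integer 0-9.
#' @param image_size Output side in pixels (>= 9).
#' @return A `stimulus_image`: list with `pixels` (square matrix in \[0,1\])
#'   and `digit`.
#' @export
render_digit_image <- function(digit, image_size = 299L) {
  if (!(is.numeric(digit) && length(digit) == 1L && digit %in% 0:9)) {
    stop("digit must be a single integer in 0..9")
  }
  if (image_size < 9L) stop("image_size must be >= 9")
  base <- .digit_base_grid(as.integer(digit))
  idx <- ceiling(seq_len(image_size) * 9L / image_size)
  structure(list(pixels = base[idx, idx, drop = FALSE],
                 digit = as.integer(digit)),
            class = "stimulus_image")
}

# Separable Gaussian blur with zero padding; kernel truncated at 3 sigma.
.gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(mat) {  # convolve columns with k
    n <- nrow(mat)
    padded <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
    out <- matrix(0, n, ncol(mat))
    for (i in seq_along(k)) {
      out <- out + k[i] * padded[(i - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Construct a saliency map object
#'
#' @param values Non-negative 2-D matrix.
#' @param normalize Normalize to unit sum (requires a positive total).
#' @return A `saliency_map`: list with `values` and `normalized` flag.
#' @export
saliency_map <- function(values, normalize = FALSE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("saliency values must be non-negative")
  if (normalize) {
    s <- sum(values)
    if (s <= 0) stop("cannot normalize an all-zero map")
    values <- values / s
  }
  structure(list(values = values, normalized = normalize),
            class = "saliency_map")
}

#' Proxy saliency ground truth for a stimulus image
#'
#' A Gaussian blur of the binary glyph mask, normalized to unit sum.  This is
#' a synthetic stand-in for fixation-derived saliency maps: it concentrates
#' mass on and around the glyph strokes, which is the qualitative property the
#' saliency generator is trained to reproduce.
#'
#' @param image A `stimulus_image`.
#' @param blur_sigma Blur standard deviation in pixels.
#' @return A unit-sum `saliency_map` of the same side as the image.
#' @export
make_saliency_ground_truth <- function(image, blur_sigma) {
  stopifnot(inherits(image, "stimulus_image"))
  if (blur_sigma <= 0) stop("blur_sigma must be > 0")
  saliency_map(.gaussian_blur(image$pixels, blur_sigma), normalize = TRUE)
}

#' Generate the index-aligned synthetic triple dataset
#'
#' Produces EEG records, the stimulus image of each record's class, and the
#' corresponding blurred-mask saliency target, all index-aligned, plus a
#' manifest.
#'
#' @param config A [synth_config()].
#' @return List with `records`, `images`, `saliency` (per-record lists) and
#'   `manifest`.
#' @export
generate_paired_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  records <- generate_eeg_dataset(config)
  class_images <- lapply(seq_len(config$n_classes) - 1L, render_digit_image,
                         image_size = config$image_size)
  class_maps <- lapply(class_images, make_saliency_ground_truth,
                       blur_sigma = config$blur_sigma)
  labels <- vapply(records, function(r) r$label, 0L)
  list(records = records,
       images = class_images[labels + 1L],
       saliency = class_maps[labels + 1L],
       manifest = build_manifest(records, source = "synthetic"))
}
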