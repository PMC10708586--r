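# Shared fixtures, built in code and cached per test session so the expensive
# trainings run once.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small 3-class paired dataset (10 records/class, desk image side).
fx_paired <- function() {
  fx_cached("paired", function() {
    generate_paired_dataset(synth_config(n_per_class = 10L, n_classes = 3L,
                                         seed = 7L, noise_sd = 2,
                                         image_size = 53L))
  })
}

fx_records_norm <- function() {
  fx_cached("records_norm", function() {
    lapply(fx_paired()$records, normalize_record)
  })
}

# Briefly trained desk classifier on the small dataset.
fx_classifier <- function() {
  fx_cached("classifier", function() {
    train_classifier(fx_records_norm(),
                     spec = classifier_spec("desk", n_classes = 3L, seed = 5L),
                     config = train_config(iterations = 100L, seed = 5L))
  })
}

fx_features <- function() {
  fx_cached("features", function() {
    extract_features(fx_classifier(), fx_records_norm())
  })
}

# Briefly trained desk saliency GAN on the small dataset's features.
fx_gan <- function() {
  fx_cached("gan", function() {
    train_gan(fx_features(), fx_paired()$saliency,
              config = gan_config(iterations = 300L, seed = 3L),
              profile = "desk")
  })
}

# Mean SSIM of a generator's outputs against a list of target maps/images.
fx_mean_ssim <- function(generator, features, targets) {
  maps <- generate_saliency(generator, features)
  if (inherits(maps, "saliency_map")) maps <- list(maps)
  rescale <- function(v) { mx <- max(v); if (mx > 0) v / mx else v }
  vals <- vapply(seq_along(maps), function(i) {
    tv <- if (inherits(targets[[i]], "saliency_map")) targets[[i]]$values
          else if (inherits(targets[[i]], "stimulus_image")) targets[[i]]$pixels
          else as.matrix(targets[[i]])
    ssim(rescale(maps[[i]]$values), rescale(tv))
  }, 0)
  mean(vals)
}

# Dominant nonzero frequency (Hz) of one channel via periodogram argmax.
fx_peak_freq <- function(x, fs = 128) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2)]
  (which.max(sp)) * fs / n
}
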