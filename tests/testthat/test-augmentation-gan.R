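# Per-class EEG-augmentation GAN: architecture, training, dataset growth.

test_that("generator and discriminator reproduce the printed grids", {
  spec <- eeg_gan_spec(seed = 1L)
  g <- build_eeg_generator(spec)
  z <- matrix(rnorm(100), 100, 1)
  x <- z
  shapes <- list()
  for (i in seq_along(g$layers)) {
    x <- eegrecon:::layer_forward(g$layers[[i]], x, training = FALSE)$out
    shapes[[i]] <- dim(x)
  }
  expect_identical(shapes[[2]], c(7L, 125L, 1L, 8L))     # reshape (7,125,8)
  expect_identical(shapes[[3]], c(7L, 125L, 1L, 8L))     # stride-1 stage
  expect_identical(dim(x), c(14L, 250L, 1L, 1L))         # 14 x 250 signal
  # deterministic output for fixed latent + weights
  y2 <- eegrecon:::nn_forward(g, z, training = FALSE, keep_cache = FALSE)$out
  expect_identical(as.numeric(x), as.numeric(y2))

  d <- build_eeg_discriminator(spec)
  xs <- x
  for (i in seq_along(d$layers)) {
    xs <- eegrecon:::layer_forward(d$layers[[i]], xs, training = FALSE)$out
    if (d$layers[[i]]$type == "flatten") expect_identical(nrow(xs), 5250L)
    if (d$layers[[i]]$type == "conv2d" && i == 1L) {
      expect_identical(dim(xs), c(14L, 250L, 1L, 6L))    # stage 1
    }
  }
  expect_true(xs[1, 1] > 0 && xs[1, 1] < 1)
  # time-axis chain 250 -> 125 -> 125 for strides 1, 2, 1
  widths <- c(250L, 125L, 125L)
  xs <- x
  j <- 0L
  for (i in seq_along(d$layers)) {
    xs <- eegrecon:::layer_forward(d$layers[[i]], xs, training = FALSE)$out
    if (d$layers[[i]]$type == "conv2d") {
      j <- j + 1L
      expect_identical(dim(xs)[2], widths[j])
    }
  }
})

test_that("training a class-specific GAN recovers its spectral signature", {
  cfg <- synth_config(n_per_class = 30L, n_classes = 1L, seed = 3L,
                      noise_sd = 0, class_freqs = 12)
  recs <- generate_eeg_dataset(cfg)
  gan <- train_augmentation_gan(recs,
                                config = gan_config(iterations = 250L,
                                                    batch_size = 8L,
                                                    seed = 2L))
  expect_identical(nrow(gan$history), 250L)
  expect_true(all(is.finite(gan$history$d_loss)))
  gen <- sample_augmented_records(gan, n = 10L, seed = 5L)
  # generated records are shape-valid EEG
  for (r in gen) expect_s3_class(validate_record(r), "eeg_record")
  # FFT oracle: mean spectral peak of generated signals near the class
  # frequency (bins are 0.512 Hz; 6 Hz is a tenth of the 0-64 Hz band)
  peaks <- sapply(gen, function(r) {
    active <- apply(r$signal, 1L, sd) > 0
    mean(apply(r$signal[active, , drop = FALSE], 1L, fx_peak_freq))
  })
  expect_lt(abs(mean(peaks) - 12), 6)
  # mixed-class input is rejected
  two <- generate_eeg_dataset(synth_config(n_per_class = 2L, n_classes = 2L,
                                           seed = 4L))
  expect_error(train_augmentation_gan(two), "single class")
})

test_that("untrained generators still emit shape-valid records", {
  spec <- eeg_gan_spec(seed = 9L)
  gan <- structure(list(generator = build_eeg_generator(spec),
                        discriminator = build_eeg_discriminator(spec),
                        label = 4L, scale = 10,
                        history = data.frame()), class = "eeg_aug_gan")
  recs <- sample_augmented_records(gan, n = 3L, seed = 1L)
  for (r in recs) {
    expect_s3_class(validate_record(r), "eeg_record")
    expect_identical(dim(r$signal), c(14L, 250L))
    expect_identical(r$label, 4L)
  }
})

test_that("augmentation grows the dataset with labeled, flagged records", {
  base <- generate_eeg_dataset(synth_config(n_per_class = 5L, n_classes = 2L,
                                            seed = 6L))
  spec <- eeg_gan_spec(seed = 7L)
  mk <- function(lbl) {
    recs <- base[vapply(base, function(r) r$label == lbl, TRUE)]
    train_augmentation_gan(recs, spec,
                           config = gan_config(iterations = 10L, seed = 8L))
  }
  gens <- list(`0` = mk(0L), `1` = mk(1L))
  aug <- augment_dataset(base, gens, n_sets = 3L)
  expect_identical(aug$manifest$total, 10L + 6L)
  expect_identical(aug$n_generated, 6L)
  flagged <- vapply(aug$records, function(r) startsWith(r$record_id, "gan-"),
                    TRUE)
  expect_identical(sum(flagged), 6L)
  labs <- vapply(aug$records[flagged], `[[`, 0L, "label")
  expect_identical(as.integer(table(labs)), c(3L, 3L))
  # n_sets = 0 leaves the dataset unchanged
  expect_identical(augment_dataset(base, gens, n_sets = 0L)$manifest$total,
                   10L)
  expect_error(augment_dataset(base, gens["0"], n_sets = 1L),
               "missing generator")
})
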