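# Depthwise CNN classifier: architecture shapes, training behaviour,
# feature extraction, cross-validation mechanics.

test_that("paper-profile stage shapes and feature length match the design", {
  spec <- classifier_spec("paper", seed = 1L)
  net <- build_classifier(spec)
  rec <- eeg_record(matrix(rnorm(14 * 250), 14, 250), label = 0L)
  x <- eegrecon:::records_to_tensor(list(rec))
  shapes <- list()
  for (i in seq_along(net$layers)) {
    x <- eegrecon:::layer_forward(net$layers[[i]], x, training = FALSE)$out
    shapes[[i]] <- dim(x) %||% length(x)
  }
  # conv stage activations: (time, channels, batch, filters)
  expect_identical(shapes[[1]], c(250L, 14L, 1L, 14L))   # stage 1: 14 filters
  expect_identical(shapes[[5]], c(250L, 14L, 1L, 10L))   # stage 2: 10 filters
  expect_identical(shapes[[9]], c(250L, 14L, 1L, 10L))   # stage 3: 10 filters
  expect_identical(shapes[[13]], c(35000L, 1L))          # flatten 10*14*250
  expect_identical(shapes[[14]], c(3500L, 1L))           # dense 1
  expect_identical(shapes[[16]], c(2500L, 1L))           # feature vector
  expect_identical(shapes[[17]], c(10L, 1L))             # class head
  feat <- extract_features(net, rec)
  expect_identical(nrow(feat), 2500L)
  rm(net); gc(verbose = FALSE)
})

test_that("log-probabilities normalize and decompose through the feature head", {
  fit <- fx_classifier()
  recs <- fx_records_norm()[c(1, 15, 25)]
  lp <- classify(fit, recs)
  expect_identical(dim(lp), c(3L, 3L))
  expect_lt(max(abs(colSums(exp(lp)) - 1)), 1e-6)
  # decomposition oracle: feature vector + stored dense head applied manually
  feats <- extract_features(fit, recs)
  net <- fit$network
  head_i <- net$meta$feature_layer + 1L
  z <- net$layers[[head_i]]$params$w %*% feats + net$layers[[head_i]]$params$b
  manual <- apply(z, 2L, function(col) col - log(sum(exp(col))))
  expect_equal(unname(lp), unname(manual), tolerance = 1e-10)
  expect_identical(max.col(t(lp)), max.col(t(manual)))
})

test_that("training separates noiseless classes and is seed-deterministic", {
  cfg <- synth_config(n_per_class = 10L, n_classes = 3L, seed = 51L,
                      noise_sd = 0)
  recs <- lapply(generate_eeg_dataset(cfg), normalize_record)
  tc <- train_config(iterations = 80L, seed = 2L)
  fit <- train_classifier(recs, classifier_spec("desk", n_classes = 3L,
                                                seed = 2L), tc)
  expect_equal(fit$history$accuracy[nrow(fit$history)], 1)
  expect_true(all(predict(fit, recs) == sapply(recs, `[[`, "label")))
  # determinism: identical loss histories for the same seed
  fit2 <- train_classifier(recs, classifier_spec("desk", n_classes = 3L,
                                                 seed = 2L), tc)
  expect_identical(fit$history, fit2$history)
  # divergence and degenerate-input guards
  expect_error(train_classifier(recs[1:10], classifier_spec("desk"),
                                tc), "two classes")
})

test_that("indistinguishable classes stay at chance accuracy", {
  # one class's identical signals relabeled into two classes
  cfg <- synth_config(n_per_class = 40L, n_classes = 1L, seed = 52L,
                      noise_sd = 0, class_freqs = 10)
  recs <- lapply(generate_eeg_dataset(cfg), normalize_record)
  for (i in seq_along(recs)) recs[[i]]$label <- (i - 1L) %% 2L
  fit <- train_classifier(recs, classifier_spec("desk", n_classes = 2L,
                                                seed = 3L),
                          train_config(iterations = 60L, seed = 3L))
  acc <- mean(predict(fit, recs) == sapply(recs, `[[`, "label"))
  # chance 0.5; 3 sigma of a fair coin over 40 draws
  expect_lte(acc, 0.5 + 3 * sqrt(0.25 / 40))
})

test_that("class separability is monotone in the noise level", {
  accs <- sapply(c(0, 1), function(nsd) {
    mean(sapply(c(61L, 62L, 63L), function(seed) {
      cfg <- synth_config(n_per_class = 8L, n_classes = 3L, seed = seed,
                          noise_sd = nsd, amp_matrix = matrix(0.5, 3, 14))
      recs <- lapply(generate_eeg_dataset(cfg), normalize_record)
      fit <- train_classifier(recs,
                              classifier_spec("desk", n_classes = 3L,
                                              seed = seed),
                              train_config(iterations = 40L, seed = seed))
      mean(predict(fit, recs) == sapply(recs, `[[`, "label"))
    }))
  })
  expect_gte(accs[1], accs[2])
})

test_that("stratified folds partition the data with balanced sizes", {
  recs <- fx_records_norm()   # 3 classes x 10
  tiny <- train_config(iterations = 5L, seed = 4L)
  cv <- crossvalidate(recs, k = 3L,
                      spec = classifier_spec("desk", n_classes = 3L, seed = 4L),
                      config = tiny)
  labels <- sapply(recs, `[[`, "label")
  # union of test folds is the dataset exactly once
  expect_identical(sort(unique(cv$assignments)), 1:3)
  expect_length(cv$assignments, length(recs))
  # per class, fold sizes differ by <= 1
  for (cl in 0:2) {
    sizes <- table(cv$assignments[labels == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_identical(nrow(cv$folds), 3L)
  expect_identical(cv$summary$metric,
                   c("accuracy", "precision", "recall", "f1", "kappa"))
  # k = 2 on 4 records: both partitions enumerable
  four <- recs[c(1, 2, 11, 12)]
  cv2 <- crossvalidate(four, k = 2L,
                       spec = classifier_spec("desk", n_classes = 3L,
                                              seed = 4L),
                       config = tiny)
  expect_identical(as.integer(table(cv2$assignments)), c(2L, 2L))
  lab4 <- sapply(four, `[[`, "label")
  for (f in 1:2) expect_identical(sort(lab4[cv2$assignments == f]), c(0L, 1L))
  expect_error(crossvalidate(four, k = 3L,
                             spec = classifier_spec("desk", n_classes = 3L),
                             config = tiny), "fewer than k")
})

test_that("parameter counting follows each layer's bias convention", {
  # dense 2500 -> 100 without bias
  lay <- eegrecon:::layer_dense(2500L, 100L, bias = FALSE)
  expect_identical(sum(vapply(lay$params, length, 1L)), 250000L)
  # dense 2888 -> 1 with bias
  lay2 <- eegrecon:::layer_dense(2888L, 1L, bias = TRUE)
  expect_identical(sum(vapply(lay2$params, length, 1L)), 2889L)
  # 1x1 conv, 1 in, 1 out, no bias
  lay3 <- eegrecon:::layer_conv2d(1L, 1L, c(1L, 1L), c(1L, 1L), bias = FALSE)
  expect_identical(sum(vapply(lay3$params, length, 1L)), 1L)
  # the classifier's conv weights are kernel * f_in * f_out
  net <- build_classifier(classifier_spec("desk", seed = 1L))
  tab <- count_parameters(net)
  expect_identical(tab$n_weights[tab$type == "conv1d"],
                   c(5L * 1L * 4L, 5L * 4L * 4L, 5L * 4L * 4L))
})
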