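# Depthwise 1-D CNN classifier: three conv stages (conv -> leaky ReLU ->
# batch norm -> dropout) along the time axis, shared across the 14 channel
# rows, then flatten -> dense -> dense (the feature vector) -> dense head with
# log-softmax.

#' Classifier architecture specification
#'
#' The `"paper"` profile is the full architecture: conv filters (14, 10, 10),
#' kernel 5 along time, leaky-ReLU slope 0.1, dropout 0.2, dense sizes
#' (3500, 2500), 10 classes; the flattened 10 x 14 x 250 activation feeds a
#' ~122M-weight dense layer, so it is expensive to train.  The `"desk"`
#' profile shrinks filter/dense sizes (4, 4, 4; dense 128, 64) without
#' changing the stage structure, for minutes-scale CPU training; its feature
#' vector has 64 elements.
#'
#' @param profile `"paper"` or `"desk"`.
#' @param n_classes Number of output classes, default 10.
#' @param seed Initialization seed, default 42.
#' @param conv_filters,dense_sizes,kernel_size,dropout_rate,leaky_alpha
#'   Overrides for the profile defaults.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(profile = c("paper", "desk"), n_classes = 10L,
                            seed = 42L, conv_filters = NULL,
                            dense_sizes = NULL, kernel_size = 5L,
                            dropout_rate = 0.2, leaky_alpha = 0.1) {
  profile <- match.arg(profile)
  if (is.null(conv_filters)) {
    conv_filters <- if (profile == "paper") c(14L, 10L, 10L) else c(4L, 4L, 4L)
  }
  if (is.null(dense_sizes)) {
    dense_sizes <- if (profile == "paper") c(3500L, 2500L) else c(128L, 64L)
  }
  if (length(conv_filters) != 3L) stop("exactly three conv stages required")
  if (length(dense_sizes) != 2L) stop("exactly two dense layers required")
  structure(list(profile = profile, conv_filters = as.integer(conv_filters),
                 dense_sizes = as.integer(dense_sizes),
                 kernel_size = as.integer(kernel_size),
                 dropout_rate = dropout_rate, leaky_alpha = leaky_alpha,
                 n_classes = as.integer(n_classes), n_channels = 14L,
                 n_samples = 250L, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Build the classifier network
#'
#' Stage chain: three times (depthwise time-axis conv, same padding ->
#' leaky ReLU -> batch normalization -> dropout), then flatten ->
#' dense -> leaky ReLU -> dense (linear; this activation is the feature
#' vector) -> dense head -> log-softmax.  Convolutions keep the 250-sample
#' time axis and the 14 channel rows; the filter count forms the leading
#' activation axis, so stage outputs are (filters, 14, 250).
#'
#' @param spec A [classifier_spec()].
#' @return An `eegnet` with meta fields `kind = "classifier"`,
#'   `feature_layer` (index of the feature activation) and `shapes`.
#' @export
build_classifier <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  set.seed(spec$seed)
  f <- spec$conv_filters
  d <- spec$dense_sizes
  flat <- f[3L] * spec$n_channels * spec$n_samples
  layers <- list()
  fin <- 1L
  for (i in 1:3) {
    layers <- c(layers, list(
      layer_conv1d(fin, f[i], spec$kernel_size),
      layer_leaky(spec$leaky_alpha),
      layer_batchnorm(f[i] * spec$n_channels * spec$n_samples, conv = TRUE),
      layer_dropout(spec$dropout_rate)))
    fin <- f[i]
  }
  layers <- c(layers, list(
    layer_flatten(),
    layer_dense(flat, d[1L]),
    layer_leaky(spec$leaky_alpha),
    layer_dense(d[1L], d[2L]),          # feature vector
    layer_dense(d[2L], spec$n_classes),
    layer_log_softmax()))
  shapes <- c(lapply(f, function(ff) c(ff, spec$n_channels, spec$n_samples))[
                rep(1:3, each = 4)],
              list(flat, d[1L], d[1L], d[2L], spec$n_classes, spec$n_classes))
  nn_sequential(layers, input_kind = "conv1",
                meta = list(kind = "classifier", spec = spec,
                            profile = spec$profile,
                            feature_layer = length(layers) - 2L,
                            shapes = shapes))
}

# Stack records into the (T, C, N, 1) input tensor.
records_to_tensor <- function(records) {
  n <- length(records)
  tlen <- ncol(records[[1L]]$signal)
  x <- array(0, c(tlen, 14L, n, 1L))
  for (i in seq_len(n)) x[, , i, 1L] <- t(records[[i]]$signal)
  x
}

record_labels <- function(records) {
  vapply(records, function(r) {
    if (identical(r$label, "unlabeled")) stop("unlabeled record in dataset")
    as.integer(r$label)
  }, 1L)
}

#' Batch normalization as a standalone operation
#'
#' Standardizes each feature over the batch: `(y - mu_B)/sqrt(s2_B + eps)`
#' with per-feature batch mean and (population) variance.  No learned affine
#' by default; `gamma`/`beta` apply an optional affine if supplied.
#'
#' @param batch Matrix, features x batch.
#' @param eps Variance guard, default 1e-5.
#' @param gamma,beta Optional per-feature affine parameters.
#' @return The normalized batch.
#' @export
batch_normalize <- function(batch, eps = 1e-5, gamma = NULL, beta = NULL) {
  batch <- as.matrix(batch)
  if (ncol(batch) < 1L) stop("empty batch")
  mu <- rowMeans(batch)
  v <- rowMeans((batch - mu)^2)
  out <- (batch - mu) / sqrt(v + eps)
  if (!is.null(gamma)) out <- out * gamma
  if (!is.null(beta)) out <- out + beta
  out
}

#' Training configuration for the classifier
#'
#' Defaults follow the documented optimum: SGD, learning rate 0.001, weight
#' decay 5e-5, cross-entropy on log-softmax outputs.
#'
#' @param iterations Number of SGD steps (mini-batches), default 300.
#' @param batch_size Mini-batch size, default 16.
#' @param lr Learning rate, default 0.001.
#' @param weight_decay L2 weight decay, default 5e-5.
#' @param seed RNG seed for shuffling/dropout, default 42.
#' @param eval_every Evaluate held-out accuracy every this many iterations
#'   (0 = never), default 25.
#' @return A `train_config` list.
#' @export
train_config <- function(iterations = 300L, batch_size = 16L, lr = 0.001,
                         weight_decay = 5e-5, seed = 42L, eval_every = 25L) {
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Train the EEG digit classifier
#'
#' Stochastic gradient descent with weight decay on the cross-entropy loss.
#' Mini-batches are drawn by shuffled epochs; per-iteration training loss and
#' accuracy (and held-out accuracy at `eval_every` intervals) are recorded.
#' Deterministic given `config$seed`.
#'
#' @param records Labeled, trimmed, normalized `eeg_record`s (>= 2 classes).
#' @param spec A [classifier_spec()]; its `n_classes` must cover the labels.
#' @param config A [train_config()].
#' @param eval_records Optional held-out records for accuracy tracking.
#' @return An `eeg_cnn` model: list with `network`, `spec`, `config`,
#'   `history` (data.frame iteration/loss/accuracy/eval_accuracy) and
#'   `classes`.
#' @export
train_classifier <- function(records, spec = classifier_spec("desk"),
                             config = train_config(), eval_records = NULL) {
  labels <- record_labels(records)
  if (length(unique(labels)) < 2L) {
    stop("training requires at least two classes")
  }
  if (max(labels) + 1L > spec$n_classes) stop("labels exceed spec$n_classes")
  net <- build_classifier(spec)
  set.seed(config$seed)
  x_all <- records_to_tensor(records)
  y_all <- labels + 1L
  x_eval <- if (!is.null(eval_records)) records_to_tensor(eval_records)
  y_eval <- if (!is.null(eval_records)) record_labels(eval_records) + 1L
  n <- length(records)
  opt <- optimizer_sgd(lr = config$lr, weight_decay = config$weight_decay)
  history <- data.frame(iteration = seq_len(config$iterations), loss = NA_real_,
                        accuracy = NA_real_, eval_accuracy = NA_real_)
  perm <- sample(n)
  pos <- 1L
  for (it in seq_len(config$iterations)) {
    if (pos + config$batch_size - 1L > n) { perm <- sample(n); pos <- 1L }
    take <- perm[pos:(pos + min(config$batch_size, n) - 1L)]
    pos <- pos + config$batch_size
    xb <- x_all[, , take, , drop = FALSE]
    yb <- y_all[take]
    fw <- nn_forward(net, xb, training = TRUE)
    net <- fw$net
    l <- nll_loss(fw$out, yb)
    if (!is.finite(l$loss)) {
      stop("divergence: non-finite loss at iteration ", it)
    }
    bk <- nn_backward(net, fw$caches, l$grad)
    st <- optimizer_step(opt, nn_get_params(net), nn_flatten_grads(bk$grads))
    opt <- st$opt
    net <- nn_set_params(net, st$params)
    history$loss[it] <- l$loss
    history$accuracy[it] <- mean(max.col(t(fw$out)) == yb)
    if (!is.null(eval_records) && config$eval_every > 0L &&
        (it %% config$eval_every == 0L || it == config$iterations)) {
      pe <- nn_forward(net, x_eval, training = FALSE, keep_cache = FALSE)$out
      history$eval_accuracy[it] <- mean(max.col(t(pe)) == y_eval)
    }
  }
  structure(list(network = net, spec = spec, config = config,
                 history = history, classes = 0:(spec$n_classes - 1L)),
            class = "eeg_cnn")
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat("<eeg_cnn> profile", x$spec$profile, "-", x$spec$n_classes, "classes,",
      attr(count_parameters(x$network), "total"), "weights\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("after %d iterations: loss %.4f, train accuracy %.3f\n",
              last$iteration, last$loss, last$accuracy))
  invisible(x)
}

#' Class log-probabilities for EEG records
#'
#' @param network An `eeg_cnn` model or bare `eegnet` classifier.
#' @param records One `eeg_record` or a list of them.
#' @return Matrix (n_classes x n_records) of log-probabilities; per record
#'   the exponentials sum to 1.
#' @export
classify <- function(network, records) {
  net <- if (inherits(network, "eeg_cnn")) network$network else network
  if (inherits(records, "eeg_record")) records <- list(records)
  x <- records_to_tensor(records)
  nn_forward(net, x, training = FALSE, keep_cache = FALSE)$out
}

#' @export
predict.eeg_cnn <- function(object, records, type = c("class", "logprob"),
                            ...) {
  type <- match.arg(type)
  lp <- classify(object, records)
  if (type == "logprob") return(lp)
  object$classes[max.col(t(lp))]
}

#' Extract the classifier's internal feature vectors
#'
#' The activation after the second dense layer (2500 elements in the paper
#' profile), before the classifier head -- the representation the saliency
#' generator consumes.
#'
#' @param network An `eeg_cnn` or `eegnet` classifier.
#' @param records One `eeg_record` or a list.
#' @return Matrix (feature_dim x n_records).
#' @export
extract_features <- function(network, records) {
  net <- if (inherits(network, "eeg_cnn")) network$network else network
  if (inherits(records, "eeg_record")) records <- list(records)
  x <- records_to_tensor(records)
  upto <- net$meta$feature_layer
  for (i in seq_len(upto)) {
    x <- layer_forward(net$layers[[i]], x, training = FALSE)$out
  }
  x
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Records are split per class into k folds (sizes differing by at most one);
#' each fold serves once as the test set.  Per-fold accuracy, macro precision,
#' recall, F1 and kappa are computed from the fold confusion matrix.
#'
#' @param records Labeled records; every class needs >= k members.
#' @param k Number of folds, default 10.
#' @param spec,config Passed to [train_classifier()].
#' @return List with `folds` (per-fold metric data.frame), `summary`
#'   (mean and sd per metric) and `assignments` (fold index per record).
#' @export
crossvalidate <- function(records, k = 10L, spec = classifier_spec("desk"),
                          config = train_config()) {
  labels <- record_labels(records)
  set.seed(config$seed)
  fold_of <- integer(length(records))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has ", length(idx), " records, fewer than k = ", k)
    }
    fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  rows <- lapply(seq_len(k), function(f) {
    test <- which(fold_of == f)
    fit <- train_classifier(records[-test], spec = spec, config = config)
    pred <- predict(fit, records[test])
    m <- classification_metrics(confusion_matrix(labels[test], pred,
                                                 labels = fit$classes))
    data.frame(fold = f, accuracy = m$overall_accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               kappa = m$kappa)
  })
  folds <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("accuracy", "precision", "recall", "f1", "kappa"),
    mean = vapply(folds[-1L], mean, 0, na.rm = TRUE),
    sd = vapply(folds[-1L], stats::sd, 0, na.rm = TRUE))
  list(folds = folds, summary = summ, assignments = fold_of)
}
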