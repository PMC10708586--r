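# Sequential network container, autodiff driver, parameter bookkeeping.

nn_sequential <- function(layers, input_kind, meta = list()) {
  structure(list(layers = layers, input_kind = input_kind, meta = meta),
            class = "eegnet")
}

# Forward pass.  Returns the output, per-layer caches for backprop, and the
# network itself (batch-norm running statistics are refreshed when training).
nn_forward <- function(net, x, training = FALSE, keep_cache = training) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    lay <- net$layers[[i]]
    r <- layer_forward(lay, x, training = training)
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
    if (training && lay$type == "batchnorm") {
      m <- lay$momentum
      net$layers[[i]]$buffers$r_mean <- m * lay$buffers$r_mean + (1 - m) * r$cache$mu
      net$layers[[i]]$buffers$r_var  <- m * lay$buffers$r_var  + (1 - m) * r$cache$v
    }
  }
  list(out = x, caches = caches, net = net)
}

# Backward pass given the caches of a training-mode forward.  Returns per-layer
# gradient lists (same names as each layer's params).
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dy <- dout
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], caches[[i]], dy)
    grads[[i]] <- r$grads
    dy <- r$dx
  }
  list(grads = grads, dx = dy)
}

nn_get_params <- function(net) {
  out <- list()
  for (i in seq_along(net$layers)) {
    for (nm in names(net$layers[[i]]$params)) {
      out[[sprintf("L%02d.%s", i, nm)]] <- net$layers[[i]]$params[[nm]]
    }
  }
  out
}

nn_set_params <- function(net, params) {
  for (key in names(params)) {
    i <- as.integer(sub("^L(\\d+)\\..*$", "\\1", key))
    nm <- sub("^L\\d+\\.", "", key)
    stopifnot(nm %in% names(net$layers[[i]]$params))
    old <- net$layers[[i]]$params[[nm]]
    new <- params[[key]]
    if (!identical(dim(old), dim(new)) || length(old) != length(new)) {
      stop("parameter shape mismatch at ", key)
    }
    net$layers[[i]]$params[[nm]] <- new
  }
  net
}

nn_flatten_grads <- function(grads) {
  out <- list()
  for (i in seq_along(grads)) {
    for (nm in names(grads[[i]])) {
      out[[sprintf("L%02d.%s", i, nm)]] <- grads[[i]][[nm]]
    }
  }
  out
}

#' Count trainable weights per layer
#'
#' Tabulates the number of trainable scalars in every layer of a network
#' (convolution kernels, dense weight matrices, biases where the layer carries
#' one).  Batch-normalization running statistics are not trainable and count
#' zero, matching the architecture tables' bias conventions.
#'
#' @param network An `eegnet` network as produced by [build_classifier()],
#'   [build_generator()], [build_discriminator()], [build_eeg_generator()] or
#'   [build_eeg_discriminator()].
#' @return A `data.frame` with columns `layer`, `type`, `n_weights` and an
#'   attribute `total`; `print`ing shows the total as well.
#' @examples
#' g <- build_generator(generator_spec("desk"))
#' count_parameters(g)
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "eegnet"))
  n <- vapply(network$layers,
              function(l) sum(vapply(l$params, length, 1L)), 1L)
  types <- vapply(network$layers, function(l) l$type, "")
  out <- data.frame(layer = seq_along(n), type = types, n_weights = n)
  attr(out, "total") <- sum(n)
  class(out) <- c("weight_count_table", "data.frame")
  out
}

#' @export
print.weight_count_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat("total trainable weights:", attr(x, "total"), "\n")
  invisible(x)
}

#' @export
print.eegnet <- function(x, ...) {
  cat("<eegnet>", length(x$layers), "layers,",
      attr(count_parameters(x), "total"), "trainable weights\n")
  if (!is.null(x$meta$profile)) cat("profile:", x$meta$profile, "\n")
  invisible(x)
}

# Negative log-likelihood on log-probabilities (cross-entropy with log-softmax
# outputs).  `logp` is (K, N); `labels` are 1-based class indices.
nll_loss <- function(logp, labels) {
  n <- ncol(logp)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(logp[idx])
  dlogp <- matrix(0, nrow(logp), n)
  dlogp[idx] <- -1 / n
  list(loss = loss, grad = dlogp)
}

# Binary cross-entropy on probabilities with clamping; `target` is 0 or 1.
bce_loss <- function(p, target, clamp = 1e-7) {
  p <- pmin(pmax(p, clamp), 1 - clamp)
  loss <- -mean(target * log(p) + (1 - target) * log(1 - p))
  grad <- (-(target / p) + (1 - target) / (1 - p)) / length(p)
  list(loss = loss, grad = grad)
}
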