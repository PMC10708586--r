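# Optimizers over flat named parameter lists (as from nn_get_params()).

optimizer_sgd <- function(lr = 0.001, weight_decay = 0) {
  structure(list(kind = "sgd", lr = lr, weight_decay = weight_decay,
                 state = NULL), class = "eegnet_optimizer")
}

optimizer_adam <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(kind = "adam", lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, state = NULL), class = "eegnet_optimizer")
}

optimizer_step <- function(opt, params, grads) {
  stopifnot(identical(names(params), names(grads)))
  if (opt$kind == "sgd") {
    for (k in names(params)) {
      g <- grads[[k]]
      if (opt$weight_decay > 0) g <- g + opt$weight_decay * params[[k]]
      params[[k]] <- params[[k]] - opt$lr * g
    }
  } else if (opt$kind == "adam") {
    if (is.null(opt$state)) {
      opt$state <- list(t = 0L,
                        m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
                        v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
    }
    opt$state$t <- opt$state$t + 1L
    bc1 <- 1 - opt$beta1^opt$state$t
    bc2 <- 1 - opt$beta2^opt$state$t
    for (k in names(params)) {
      g <- grads[[k]]
      opt$state$m[[k]] <- opt$beta1 * opt$state$m[[k]] + (1 - opt$beta1) * g
      opt$state$v[[k]] <- opt$beta2 * opt$state$v[[k]] + (1 - opt$beta2) * g^2
      mhat <- opt$state$m[[k]] / bc1
      vhat <- opt$state$v[[k]] / bc2
      upd <- params[[k]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
      dim(upd) <- dim(params[[k]])   # keep scalar biases dimensionless
      params[[k]] <- upd
    }
  } else stop("unknown optimizer")
  list(params = params, opt = opt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
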