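# Checkpoints (single-file archives written at run time) and network
# inspection.

#' Save a model checkpoint
#'
#' Serializes any of the package's model objects (`eeg_cnn`, `eeg_gan`,
#' `eeg_aug_gan`, or a named list of them) together with a format tag.
#'
#' @param object Model object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(list(format = "eegrecon-checkpoint-1", object = object), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The stored object.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  x <- readRDS(path)
  if (!identical(x$format, "eegrecon-checkpoint-1")) {
    stop("not an eegrecon checkpoint: ", path)
  }
  x$object
}

# Collect every eegnet inside a model object, named.
.collect_networks <- function(object, prefix = "") {
  if (inherits(object, "eegnet")) {
    out <- list(object)
    names(out) <- if (nzchar(prefix)) prefix else object$meta$kind %||% "network"
    return(out)
  }
  if (is.list(object)) {
    out <- list()
    for (nm in names(object)) {
      sub <- .collect_networks(object[[nm]],
                               if (nzchar(prefix)) paste0(prefix, ".", nm)
                               else nm)
      out <- c(out, sub)
    }
    return(out)
  }
  list()
}

#' Per-layer weight-count table for a model or checkpoint
#'
#' Walks every network inside the object (a classifier stores one network, a
#' GAN two, an experiment checkpoint several) and stacks their
#' [count_parameters()] tables.
#'
#' @param object A model object, or a path to a checkpoint file.
#' @return A data.frame with columns `network`, `layer`, `type`, `n_weights`.
#' @export
inspect_networks <- function(object) {
  if (is.character(object) && length(object) == 1L) {
    object <- load_checkpoint(object)
  }
  nets <- .collect_networks(object)
  if (length(nets) == 0L) stop("no networks found in object")
  do.call(rbind, lapply(names(nets), function(nm) {
    tab <- count_parameters(nets[[nm]])
    data.frame(network = nm, layer = tab$layer, type = tab$type,
               n_weights = tab$n_weights)
  }))
}
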