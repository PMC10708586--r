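# Weight transfer and fine-tuning: the saliency GAN's trained weights
# initialize a second adversarial run whose targets are the original digit
# stimulus images, and the full experiment orchestrates every stage.

#' Copy trained weights between GAN pairs
#'
#' All weight tensors of generator and discriminator are copied exactly, so a
#' forward pass of the destination equals the source to the last bit; the
#' destination remains trainable.  Specs must match layer for layer.
#'
#' @param source,destination `eeg_gan` pairs (or lists with `generator` and
#'   `discriminator` `eegnet`s).
#' @return The destination pair with the source's weights.
#' @export
transfer_weights <- function(source, destination) {
  copy_net <- function(src, dst, what) {
    if (length(src$layers) != length(dst$layers)) {
      stop("transfer error (", what, "): ", length(src$layers), " vs ",
           length(dst$layers), " layers")
    }
    sp <- nn_get_params(src)
    dp <- nn_get_params(dst)
    bad <- names(sp)[!vapply(names(sp), function(k) {
      !is.null(dp[[k]]) && identical(dim(sp[[k]]), dim(dp[[k]])) &&
        length(sp[[k]]) == length(dp[[k]])
    }, TRUE)]
    if (!identical(sort(names(sp)), sort(names(dp))) || length(bad) > 0L) {
      stop("transfer error (", what, "): mismatched layers ",
           paste(unique(c(bad, setdiff(names(dp), names(sp)))), collapse = ", "))
    }
    nn_set_params(dst, sp)
  }
  destination$generator <- copy_net(source$generator, destination$generator,
                                    "generator")
  destination$discriminator <- copy_net(source$discriminator,
                                        destination$discriminator,
                                        "discriminator")
  destination
}

#' Fine-tune a transferred GAN to reconstruct the original stimulus images
#'
#' Runs the same adversarial loop as [train_gan()] starting from the
#' transferred weights, with the fine-tune learning rate `lr_factor` times the
#' base rate (default 0.1) and both networks trainable.  The history tracks
#' four series: generator loss, discriminator loss, and mean SSIM and CC of
#' the generated images against the stimulus targets.
#'
#' @param pair An `eeg_gan` (typically initialized by [transfer_weights()]).
#' @param features Feature matrix aligned with `images`.
#' @param images Stimulus images (targets), resampled to the pair's canonical
#'   side.
#' @param config A [gan_config()]; `track_every` defaults to 25 here.
#' @param lr_factor Fine-tune learning-rate multiplier, default 0.1.
#' @return An `eeg_gan` with the tuned pair and the four-series history.
#' @export
finetune_for_original_images <- function(pair, features, images,
                                         config = gan_config(),
                                         lr_factor = 0.1) {
  stopifnot(inherits(pair, "eeg_gan") || !is.null(pair$generator))
  cfg <- config
  cfg$lr <- config$lr * lr_factor
  if (cfg$track_every <= 0L) cfg$track_every <- 25L
  train_gan(features, images, gen = pair$generator,
            disc = pair$discriminator, config = cfg)
}

#' Full-experiment configuration
#'
#' Profiles must be consistent across stages: the classifier's feature length
#' equals the generator's input dimension, and saliency/stimulus targets share
#' the canonical image side.
#'
#' @param profile `"desk"` (default) or `"paper"`.
#' @param seed Master seed; stage seeds derive from it.
#' @param n_per_class,n_classes,noise_sd Synthetic-data settings (desk
#'   defaults: 60 records for each of 3 classes, noise sd 2).
#' @param classifier_iterations,gan_iterations,finetune_iterations Stage
#'   iteration budgets.
#' @param cv_k Cross-validation folds for the classifier stage, default 2.
#' @param holdout_fraction Held-out fraction for the final classifier fit,
#'   default 0.25.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(profile = c("desk", "paper"), seed = 42L,
                              n_per_class = 60L, n_classes = 3L,
                              noise_sd = 2,
                              classifier_iterations = 150L,
                              gan_iterations = 250L,
                              finetune_iterations = 150L,
                              cv_k = 2L, holdout_fraction = 0.25) {
  profile <- match.arg(profile)
  side <- if (profile == "paper") 299L else 53L
  structure(list(profile = profile, seed = as.integer(seed),
                 n_per_class = as.integer(n_per_class),
                 n_classes = as.integer(n_classes), noise_sd = noise_sd,
                 classifier_iterations = as.integer(classifier_iterations),
                 gan_iterations = as.integer(gan_iterations),
                 finetune_iterations = as.integer(finetune_iterations),
                 cv_k = as.integer(cv_k), holdout_fraction = holdout_fraction,
                 side = side),
            class = "experiment_config")
}

#' Run the full decoding-and-reconstruction experiment
#'
#' Executes, fully seeded: synthetic-data generation; classifier
#' cross-validation and a final train/held-out fit; feature extraction;
#' saliency-GAN training; per-class SSIM/CC evaluation of the generated
#' saliency maps; weight transfer and fine-tuning on the original stimulus
#' images; and the per-class evaluation of the reconstructed images.  All
#' stage results are collected in a structured report; artifacts (checkpoint,
#' report JSON, sample images) are written when `out_dir` is given.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return An `experiment_report` list with sections `data`, `crossval`,
#'   `classifier`, `features`, `saliency_gan`, `transfer`, and `config`.
#' @export
run_full_experiment <- function(config = experiment_config(),
                                out_dir = NULL) {
  profile <- config$profile
  sc <- synth_config(n_per_class = config$n_per_class,
                     n_classes = config$n_classes, seed = config$seed,
                     noise_sd = config$noise_sd, image_size = config$side)
  paired <- generate_paired_dataset(sc)
  records <- lapply(paired$records, function(r) normalize_record(r))
  labels <- record_labels(records)

  cspec <- classifier_spec(profile, n_classes = config$n_classes,
                           seed = config$seed)
  ccfg <- train_config(iterations = config$classifier_iterations,
                       seed = config$seed)
  cv <- crossvalidate(records, k = config$cv_k, spec = cspec, config = ccfg)

  # final fit on a stratified split
  set.seed(config$seed)
  test_idx <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(config$holdout_fraction * length(idx))))
  }))
  fit <- train_classifier(records[-test_idx], spec = cspec, config = ccfg,
                          eval_records = records[test_idx])
  pred <- predict(fit, records[test_idx])
  cmx <- confusion_matrix(labels[test_idx], pred, labels = fit$classes)
  cmet <- classification_metrics(cmx)

  feats <- extract_features(fit, records)
  gcfg <- gan_config(iterations = config$gan_iterations, seed = config$seed)
  gan <- train_gan(feats, paired$saliency, config = gcfg, profile = profile)

  gen_maps <- generate_saliency(gan, feats)
  if (inherits(gen_maps, "saliency_map")) gen_maps <- list(gen_maps)
  sal_table <- evaluate_saliency_per_class(gen_maps, paired$saliency, labels)

  fresh <- list(generator = build_generator(generator_spec(profile,
                                                           seed = config$seed + 7L)),
                discriminator = build_discriminator(discriminator_spec(profile,
                                                                       seed = config$seed + 8L)))
  moved <- transfer_weights(gan, fresh)
  fcfg <- gan_config(iterations = config$finetune_iterations,
                     seed = config$seed + 1L)
  tuned <- finetune_for_original_images(moved, feats, paired$images, fcfg)
  rec_maps <- generate_saliency(tuned, feats)
  if (inherits(rec_maps, "saliency_map")) rec_maps <- list(rec_maps)
  img_table <- evaluate_saliency_per_class(rec_maps, paired$images, labels)

  report <- structure(list(
    config = unclass(config),
    data = list(manifest_counts = as.list(paired$manifest$counts),
                total = paired$manifest$total,
                n_samples = ncol(records[[1L]]$signal)),
    crossval = list(folds = cv$folds, summary = cv$summary),
    classifier = list(history_tail = utils::tail(fit$history, 1L),
                      test_accuracy = cmet$overall_accuracy,
                      test_kappa = cmet$kappa,
                      confusion = unclass(cmx),
                      predictions = data.frame(true = labels[test_idx],
                                               predicted = pred)),
    features = list(dim = nrow(feats)),
    saliency_gan = list(history_tail = utils::tail(gan$history, 1L),
                        per_class = sal_table),
    transfer = list(history = tuned$history[
                      !is.na(tuned$history$ssim), , drop = FALSE],
                    per_class = img_table)),
    class = "experiment_report")

  result <- list(report = report, classifier = fit, gan = gan, tuned = tuned,
                 paired = paired)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(result[c("classifier", "gan", "tuned")],
                    file.path(out_dir, "experiment_checkpoint.rds"))
    writeLines(jsonlite::toJSON(.report_to_json(report), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
               file.path(out_dir, "report.json"))
    write_manifest(paired$manifest, file.path(out_dir, "manifest.tsv"))
    for (k in seq_len(min(config$n_classes, 4L))) {
      i <- which(labels == k - 1L)[1L]
      .write_map_png(gen_maps[[i]]$values,
                     file.path(out_dir, sprintf("salient_class%d.png", k - 1L)))
      .write_map_png(rec_maps[[i]]$values,
                     file.path(out_dir, sprintf("reconstructed_class%d.png",
                                                k - 1L)))
    }
  }
  result
}

.report_to_json <- function(report) {
  rapply(unclass(report), function(x) {
    if (is.data.frame(x) || is.matrix(x)) as.data.frame(x) else x
  }, how = "replace")
}

.write_map_png <- function(values, path) {
  mx <- max(values)
  png::writePNG(if (mx > 0) values / mx else values, path)
  invisible(path)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> profile", x$config$profile, "\n")
  cat("data:", x$data$total, "records,", x$data$n_samples, "samples/channel\n")
  cat(sprintf("classifier: CV accuracy %.3f, held-out accuracy %.3f\n",
              x$crossval$summary$mean[x$crossval$summary$metric == "accuracy"],
              x$classifier$test_accuracy))
  sal <- x$saliency_gan$per_class
  cat(sprintf("saliency: average SSIM %.1f, CC %.1f\n",
              sal$ssim[sal$category == "Average"],
              sal$cc[sal$category == "Average"]))
  img <- x$transfer$per_class
  cat(sprintf("reconstruction: average SSIM %.1f, CC %.1f\n",
              img$ssim[img$category == "Average"],
              img$cc[img$category == "Average"]))
  invisible(x)
}
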