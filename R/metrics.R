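# Classification metrics (confusion matrix, accuracy/precision/recall/F1,
# Cohen's kappa) and saliency metrics (SIM, SSIM, CC).

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred Equal-length label vectors over a common class set.
#' @param labels Optional ordered class set; defaults to the sorted union.
#' @return A `confusion_matrix`: square count matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  ft <- factor(y_true, levels = labels)
  fp <- factor(y_pred, levels = labels)
  if (anyNA(ft) || anyNA(fp)) stop("labels outside the declared class set")
  m <- unclass(table(ft, fp))
  dimnames(m) <- list(true = as.character(labels),
                      predicted = as.character(labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

# One-vs-rest binary counts for class index i
.ovr_counts <- function(cm, i) {
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Binary kappa: 2(TP*TN - FN*FP) / ((TP+FP)(FP+TN) + (TP+FN)(FN+TN))
.binary_kappa <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  if (den == 0) return(NA_real_)
  2 * (tp * tn - fn * fp) / den
}

#' Classification metrics from a confusion matrix
#'
#' Per class (one-vs-rest): accuracy (TP+TN)/total, precision TP/(TP+FP),
#' recall TP/(TP+FN), and two F1 variants -- `f1` = (precision+recall)/2 (the
#' arithmetic-mean form this package adopts as its headline F1) and
#' `f1_harmonic` = 2PR/(P+R) (the conventional definition); both are always
#' reported.  Cohen's kappa is computed per class from the binary counts and
#' macro-averaged for more than two classes.  Zero-denominator metrics are
#' reported as `NA` (flagged undefined, never coerced to 0).
#'
#' @param cm A `confusion_matrix` or square count matrix.
#' @return A `classification_metrics` list: `overall_accuracy`,
#'   `per_class` data.frame, and macro means `precision`, `recall`, `f1`,
#'   `f1_harmonic`, `kappa`.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (nrow(cm) != ncol(cm) || nrow(cm) == 0L) stop("cm must be square")
  if (any(cm < 0)) stop("cm must be non-negative")
  k <- nrow(cm)
  total <- sum(cm)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  rows <- lapply(seq_len(k), function(i) {
    ct <- .ovr_counts(cm, i)
    prec <- div(ct["tp"], ct["tp"] + ct["fp"])
    rec <- div(ct["tp"], ct["tp"] + ct["fn"])
    f1h <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
           else 2 * prec * rec / (prec + rec)
    data.frame(class = rownames(cm)[i] %||% as.character(i - 1L),
               tp = ct[["tp"]], tn = ct[["tn"]], fp = ct[["fp"]],
               fn = ct[["fn"]],
               accuracy = div(ct["tp"] + ct["tn"], total),
               precision = unname(prec), recall = unname(rec),
               f1 = unname((prec + rec) / 2), f1_harmonic = unname(f1h),
               kappa = .binary_kappa(ct["tp"], ct["tn"], ct["fp"], ct["fn"]))
  })
  per_class <- do.call(rbind, rows)
  macro <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(list(overall_accuracy = div(sum(diag(cm)), total),
                 per_class = per_class,
                 precision = macro(per_class$precision),
                 recall = macro(per_class$recall),
                 f1 = macro(per_class$f1),
                 f1_harmonic = macro(per_class$f1_harmonic),
                 kappa = macro(per_class$kappa)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  kappa %.4f\n",
              x$overall_accuracy, x$precision, x$recall, x$f1, x$kappa))
  invisible(x)
}

.as_map_values <- function(m) {
  if (inherits(m, "saliency_map")) m$values
  else if (inherits(m, "stimulus_image")) m$pixels
  else as.matrix(m)
}

#' Histogram-intersection similarity of two saliency distributions
#'
#' Both maps are normalized to unit sum, then SIM is the sum of pixelwise
#' minima: 1 for identical distributions, 0 for disjoint supports.
#'
#' @param sm,fm Saliency maps (matrices or `saliency_map`s) of equal shape
#'   with positive sums.
#' @return A number in \[0, 1\].
#' @export
sim <- function(sm, fm) {
  a <- .as_map_values(sm); b <- .as_map_values(fm)
  if (!identical(dim(a), dim(b))) stop("maps must have equal shapes")
  if (any(a < 0) || any(b < 0)) stop("maps must be non-negative")
  sa <- sum(a); sb <- sum(b)
  if (sa <= 0 || sb <= 0) stop("cannot normalize an all-zero map")
  sum(pmin(a / sa, b / sb))
}

#' SSIM window/constant parameters
#'
#' @param L Odd window side in pixels (default 11).
#' @param K Pixel-intensity range `2^bits - 1`; default `NULL` infers 255 for
#'   data exceeding 1 and 1.0 for unit-range data.
#' @param d1,d2 Stabilization fractions, defaults 0.01 and 0.03; the additive
#'   constants are `k1 = (d1*K)^2` and `k2 = (d2*K)^2`.
#' @return An `ssim_params` list.
#' @export
ssim_params <- function(L = 11L, K = NULL, d1 = 0.01, d2 = 0.03) {
  L <- as.integer(L)
  if (L < 3L || L %% 2L == 0L) stop("L must be odd and >= 3")
  if (!is.null(K) && K <= 0) stop("K must be positive")
  structure(list(L = L, K = K, d1 = d1, d2 = d2), class = "ssim_params")
}

# Box sums over L x L sliding windows (valid positions) via an integral image.
.box_sums <- function(m, L) {
  s <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # transposed integral image
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  n <- nrow(m) - L + 1L; k <- ncol(m) - L + 1L
  s[(1L + L):(n + L), (1L + L):(k + L)] - s[1:n, (1L + L):(k + L)] -
    s[(1L + L):(n + L), 1:k] + s[1:n, 1:k]
}

#' Mean structural similarity of two images
#'
#' SSIM evaluated on every L x L sliding window (uniform weights, stride 1,
#' valid positions) and averaged:
#' `(2*mu_m*mu_n + k1)(2*cov_mn + k2) / ((mu_m^2 + mu_n^2 + k1)(var_m + var_n + k2))`.
#'
#' @param m,n Equal-shaped numeric matrices with sides >= L.
#' @param params An [ssim_params()].
#' @return Mean SSIM in \[-1, 1\]; 1 iff the images are identical.
#' @export
ssim <- function(m, n, params = ssim_params()) {
  m <- .as_map_values(m); n <- .as_map_values(n)
  if (!identical(dim(m), dim(n))) stop("images must have equal shapes")
  L <- params$L
  if (nrow(m) < L || ncol(m) < L) stop("image smaller than the SSIM window")
  K <- params$K
  if (is.null(K)) K <- if (max(abs(m), abs(n)) > 1) 255 else 1
  k1 <- (params$d1 * K)^2
  k2 <- (params$d2 * K)^2
  np <- L * L
  mu_m <- .box_sums(m, L) / np
  mu_n <- .box_sums(n, L) / np
  # population variance/covariance per window
  var_m <- .box_sums(m * m, L) / np - mu_m^2
  var_n <- .box_sums(n * n, L) / np - mu_n^2
  cov_mn <- .box_sums(m * n, L) / np - mu_m * mu_n
  num <- (2 * mu_m * mu_n + k1) * (2 * cov_mn + k2)
  den <- (mu_m^2 + mu_n^2 + k1) * (var_m + var_n + k2)
  mean(num / den)
}

#' Pearson correlation between two maps
#'
#' Covariance over the product of standard deviations, computed over all
#' pixels.  Invariant under positive affine transforms of either argument.
#'
#' @param fm,sm Equal-shaped maps with nonzero variance.
#' @return Correlation in \[-1, 1\]; `NA` (with a warning) if either map has
#'   zero variance.
#' @export
cc <- function(fm, sm) {
  a <- .as_map_values(fm); b <- .as_map_values(sm)
  if (!identical(dim(a), dim(b))) stop("maps must have equal shapes")
  av <- as.vector(a); bv <- as.vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    warning("zero-variance input: CC undefined")
    return(NA_real_)
  }
  stats::cor(av, bv)
}

#' Per-class saliency evaluation table
#'
#' Mean SSIM and CC per digit class plus an overall average row.  Maps are
#' rescaled to \[0, 1\] by their own maxima before SSIM so the unit-range
#' constants apply; CC is scale-invariant.  Values are reported as
#' percentages.
#'
#' @param pred_maps,truth_maps Index-aligned lists of maps.
#' @param labels Per-item class labels.
#' @return A data.frame with columns `category`, `n`, `ssim`, `cc`, the last
#'   row being `"Average"` (the mean over the class rows).
#' @export
evaluate_saliency_per_class <- function(pred_maps, truth_maps, labels) {
  if (length(pred_maps) != length(truth_maps) ||
      length(pred_maps) != length(labels)) {
    stop("pred_maps, truth_maps and labels must be aligned")
  }
  rescale <- function(v) { mx <- max(v); if (mx > 0) v / mx else v }
  classes <- sort(unique(labels))
  rows <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    s_vals <- vapply(idx, function(i) {
      ssim(rescale(.as_map_values(pred_maps[[i]])),
           rescale(.as_map_values(truth_maps[[i]])))
    }, 0)
    c_vals <- vapply(idx, function(i) {
      cc(pred_maps[[i]], truth_maps[[i]])
    }, 0)
    data.frame(category = as.character(cl), n = length(idx),
               ssim = 100 * mean(s_vals), cc = 100 * mean(c_vals))
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(category = "Average", n = sum(tab$n),
                        ssim = mean(tab$ssim), cc = mean(tab$cc)))
}
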