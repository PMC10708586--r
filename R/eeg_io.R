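# Reading, writing and validating 14-channel EEG records in the MindBigData
# tab-separated line dialect: one line per (event, channel) with fields
#   id <TAB> event <TAB> device <TAB> channel <TAB> code <TAB> size <TAB> data
# where data is a comma-separated list of voltage samples.

#' Emotiv EPOC channel order
#'
#' The fixed channel ordering used for signal-matrix rows: the seven
#' left-hemisphere electrodes (AF3, F7, F3, FC5, T7, P7, O1) followed by their
#' right-hemisphere counterparts (AF4, F8, F4, FC6, T8, P8, O2).
#' @export
EPOC_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                   "AF4", "F8", "F4", "FC6", "T8", "P8", "O2")

#' Construct a labeled EEG record
#'
#' An `eeg_record` holds one 14-channel voltage matrix (channels x time, in
#' microvolts), the channel names in row order, the sampling rate and a digit
#' label (0-9) or `"unlabeled"`.
#'
#' @param signal Numeric matrix, channels x time.
#' @param label Digit class 0-9 (integer) or `"unlabeled"`.
#' @param record_id Opaque identifier string.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Row labels; defaults to [EPOC_CHANNELS].
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, label = "unlabeled", record_id = "r0",
                       sampling_rate = 128, channel_names = EPOC_CHANNELS) {
  signal <- as.matrix(signal)
  rownames(signal) <- channel_names
  rec <- structure(list(signal = signal, channel_names = channel_names,
                        sampling_rate = sampling_rate, label = label,
                        record_id = as.character(record_id)),
                   class = "eeg_record")
  validate_record(rec)
}

#' Validate an EEG record
#'
#' Checks the invariants: exactly 14 channel rows in the canonical order, a
#' positive sampling rate, and a label in 0..9 or `"unlabeled"`.
#'
#' @param record An `eeg_record`.
#' @return The record, invisibly unchanged, or an error.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  if (nrow(record$signal) != length(record$channel_names)) {
    stop("signal rows do not match channel names")
  }
  if (length(record$channel_names) != 14L) {
    stop("an EEG record must have exactly 14 channels, got ",
         length(record$channel_names))
  }
  if (!is.numeric(record$sampling_rate) || record$sampling_rate <= 0) {
    stop("sampling_rate must be positive")
  }
  lb <- record$label
  ok <- identical(lb, "unlabeled") ||
    (is.numeric(lb) && length(lb) == 1L && lb %in% 0:9)
  if (!ok) stop("label must be a digit 0-9 or \"unlabeled\"")
  if (anyNA(record$signal)) stop("signal contains NA")
  record
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record %s> %d x %d @ %g Hz, label %s\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$sampling_rate,
              as.character(x$label)))
  invisible(x)
}

#' Read EEG records from a MindBigData-dialect TSV file
#'
#' Each line carries `id`, `event`, `device`, `channel`, `class code`,
#' `sample count` and comma-separated samples.  Lines are grouped by event id;
#' events missing any of the 14 EPOC channels are dropped with a warning.
#' Unknown channel labels are skipped with a warning; malformed lines are an
#' error naming the line number.
#'
#' @param path Path to the file.
#' @return A list of `eeg_record` objects, in order of first appearance.
#' @export
read_mindbig_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  events <- list()   # event id -> list(channel -> samples)
  codes <- list()
  order_seen <- character(0)
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 7L) {
      stop("malformed line ", ln, ": expected 7 tab-separated fields, got ",
           length(f))
    }
    chan <- f[[4]]
    if (!chan %in% EPOC_CHANNELS) {
      warning("line ", ln, ": unknown channel label '", chan, "', skipped")
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(f[[7]], ",", fixed = TRUE)[[1]]))
    if (anyNA(vals)) stop("malformed line ", ln, ": non-numeric sample value")
    nsize <- suppressWarnings(as.integer(f[[6]]))
    if (is.na(nsize) || nsize != length(vals)) {
      stop("malformed line ", ln, ": declared size ", f[[6]],
           " does not match ", length(vals), " samples")
    }
    ev <- f[[2]]
    if (is.null(events[[ev]])) {
      events[[ev]] <- list()
      order_seen <- c(order_seen, ev)
    }
    events[[ev]][[chan]] <- vals
    codes[[ev]] <- f[[5]]
  }
  records <- list()
  for (ev in order_seen) {
    chans <- events[[ev]]
    missing <- setdiff(EPOC_CHANNELS, names(chans))
    if (length(missing) > 0L) {
      warning("event ", ev, " dropped: missing channel(s) ",
              paste(missing, collapse = ", "))
      next
    }
    nt <- length(chans[[EPOC_CHANNELS[1]]])
    if (any(vapply(chans, length, 1L) != nt)) {
      warning("event ", ev, " dropped: unequal channel lengths")
      next
    }
    sig <- do.call(rbind, chans[EPOC_CHANNELS])
    code <- suppressWarnings(as.integer(codes[[ev]]))
    label <- if (!is.na(code) && code %in% 0:9) code else "unlabeled"
    records[[length(records) + 1L]] <-
      eeg_record(sig, label = label, record_id = ev)
  }
  records
}

#' Write EEG records in the MindBigData line dialect
#'
#' The output is re-readable by [read_mindbig_tsv()] with bit-identical sample
#' values (samples are serialized at full double precision).
#'
#' @param records List of validated `eeg_record` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mindbig_tsv <- function(records, path) {
  lapply(records, validate_record)
  con <- file(path, "w")
  on.exit(close(con))
  id <- 0L
  for (rec in records) {
    code <- if (identical(rec$label, "unlabeled")) -1L else as.integer(rec$label)
    for (c_i in seq_along(rec$channel_names)) {
      id <- id + 1L
      samples <- paste(formatC(rec$signal[c_i, ], format = "g", digits = 17),
                       collapse = ",")
      writeLines(paste(id, rec$record_id, "EP", rec$channel_names[c_i],
                       code, ncol(rec$signal), samples, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Trim a record to a fixed number of time samples
#'
#' Keeps the first `n_samples` columns of every channel (the nominal 2-s,
#' 128-Hz epochs carry ~256 samples; processing uses the first 250).
#'
#' @param record An `eeg_record`.
#' @param n_samples Target length, default 250.
#' @return The trimmed record.
#' @export
trim_record <- function(record, n_samples = 250L) {
  validate_record(record)
  if (ncol(record$signal) < n_samples) {
    stop("record has ", ncol(record$signal), " samples, fewer than ",
         n_samples)
  }
  record$signal <- record$signal[, seq_len(n_samples), drop = FALSE]
  record
}

#' Standardize each channel to zero mean and unit standard deviation
#'
#' Per channel, output = (x - mean) / sd.  Channels with (near-)zero standard
#' deviation map to all zeros (the divisor is guarded by a small epsilon).
#'
#' @param record An `eeg_record`.
#' @param eps Standard-deviation guard for constant channels; default 1e-8.
#' @return The normalized record.
#' @export
normalize_record <- function(record, eps = 1e-8) {
  validate_record(record)
  m <- rowMeans(record$signal)
  s <- apply(record$signal, 1L, stats::sd)
  centered <- record$signal - m
  centered[s < eps, ] <- 0
  s[s < eps] <- 1
  record$signal <- centered / s
  record
}

#' Tabulate per-class record counts
#'
#' @param records List of `eeg_record` objects.
#' @param source Provenance string stored in the manifest.
#' @return A `dataset_manifest`: list with `counts` (named integer vector,
#'   class -> count), `total` and `source`.
#' @export
build_manifest <- function(records, source = "memory") {
  labels <- vapply(records, function(r) as.character(r$label), "")
  counts <- table(labels)
  out <- structure(list(counts = stats::setNames(as.integer(counts),
                                                 names(counts)),
                        total = length(records), source = source),
                   class = "dataset_manifest")
  stopifnot(sum(out$counts) == out$total)
  out
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest>", x$total, "records from", x$source, "\n")
  print(x$counts)
  invisible(x)
}

#' Export a manifest as a delimited class/count table
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- data.frame(class = names(manifest$counts),
                   count = as.integer(manifest$counts))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
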