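#' Construct a 12-lead ECG record
#'
#' The unit of classification: one labelled (or unlabelled) variable-length
#' 12-lead signal. Signals are stored as a `12 x T` matrix in millivolts with
#' one row per lead, sampled at `fs` Hz.
#'
#' @param record_id Character scalar identifier.
#' @param signal Numeric `12 x T` matrix (rows = leads, columns = samples, mV).
#' @param fs Sampling rate in samples/second (corpus standard: 500).
#' @param label Integer class index in `0..8` (see [ecg_classes()]), or `NA`
#'   for unlabelled (inference-mode) records.
#' @return An object of class `ecg_record`: a list with fields `record_id`,
#'   `signal`, `fs`, `label`, `class_name`.
#' @export
ecg_record <- function(record_id, signal, fs = 500, label = NA_integer_) {
  signal <- as.matrix(signal)
  if (nrow(signal) != N_LEADS) {
    stop(sprintf("record '%s': expected %d channels, got %d",
                 record_id, N_LEADS, nrow(signal)), call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop(sprintf("record '%s': fs must be a positive sampling rate", record_id),
         call. = FALSE)
  }
  label <- as.integer(label)
  if (!is.na(label) && (label < 0L || label > 8L)) {
    stop(sprintf("record '%s': label %d outside 0..8", record_id, label),
         call. = FALSE)
  }
  structure(list(
    record_id = as.character(record_id),
    signal = signal,
    fs = fs,
    label = label,
    class_name = if (is.na(label)) NA_character_ else ecg_classes()[label + 1L]
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d x %d @ %g Hz (%.1f s), label = %s>\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs,
              if (is.na(x$label)) "NA" else
                sprintf("%d (%s)", x$label, x$class_name)))
  invisible(x)
}

new_dataset <- function(records) {
  structure(records, class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  labs <- vapply(x, function(r) r$label, integer(1))
  cat(sprintf("<ecg_dataset: %d records; labels: %s>\n", length(x),
              paste(sprintf("%s=%d", ecg_classes()[sort(unique(labs)) + 1L],
                            table(labs)), collapse = " ")))
  invisible(x)
}

#' @export
`[.ecg_dataset` <- function(x, i) {
  new_dataset(unclass(x)[i])
}

dataset_labels <- function(dataset) {
  vapply(dataset, function(r) r$label, integer(1))
}
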