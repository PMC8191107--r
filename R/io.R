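# Dataset and configuration I/O.
#
# Datasets are stored as a directory with one full-precision CSV per record
# (columns = the 12 leads, rows = samples) plus manifest.csv (record_id,
# label, class_name, fs, n_samples, duration, file). Configurations are flat
# key = value text files.

#' Write a dataset to a directory
#'
#' @param dataset An `ecg_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    fname <- paste0(rec$record_id, ".csv")
    df <- as.data.frame(t(rec$signal))
    names(df) <- LEAD_NAMES
    utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     file.path(dir, fname), row.names = FALSE, quote = FALSE)
    rows[[i]] <- data.frame(
      record_id = rec$record_id, label = rec$label,
      class_name = ifelse(is.na(rec$label), NA, rec$class_name),
      fs = rec$fs, n_samples = ncol(rec$signal),
      duration = ncol(rec$signal) / rec$fs, file = fname)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates channel count and sampling rate per record; unreadable or
#' invalid records are reported (with their ids) and skipped, and reading
#' continues with a summary.
#'
#' @param path Dataset directory containing `manifest.csv`.
#' @param format Storage format; only `"csv-manifest"` is supported.
#' @return An `ecg_dataset`. Records without a manifest label are unlabelled.
#' @export
read_records <- function(path, format = c("csv-manifest", "wfdb", "mat")) {
  format <- match.arg(format)
  if (format != "csv-manifest") {
    stop(sprintf("format '%s' is not supported by this build; use 'csv-manifest'",
                 format), call. = FALSE)
  }
  mf_path <- file.path(path, "manifest.csv")
  if (!file.exists(mf_path)) {
    stop(sprintf("no manifest.csv under '%s'", path), call. = FALSE)
  }
  mf <- utils::read.csv(mf_path)
  has_label <- "label" %in% names(mf)
  records <- list()
  failed <- character(0)
  for (i in seq_len(nrow(mf))) {
    rid <- as.character(mf$record_id[i])
    rec <- tryCatch({
      df <- utils::read.csv(file.path(path, mf$file[i]))
      if (is.null(mf$fs[i]) || is.na(mf$fs[i])) {
        stop("missing sampling rate in manifest")
      }
      sig <- t(as.matrix(df))
      if (nrow(sig) != N_LEADS) {
        stop(sprintf("expected %d channels, got %d", N_LEADS, nrow(sig)))
      }
      label <- if (has_label) mf$label[i] else NA_integer_
      ecg_record(rid, sig, fs = mf$fs[i], label = label)
    }, error = function(e) {
      message(sprintf("record '%s': %s -- skipped", rid, conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) failed <- c(failed, rid) else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(failed) > 0) {
    message(sprintf("loaded %d/%d records (%d failed: %s)", length(records),
                    nrow(mf), length(failed), paste(failed, collapse = ", ")))
  }
  ds <- new_dataset(records)
  attr(ds, "labelled") <- has_label
  ds
}

#' Write a flat key = value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    sprintf("%s = %s", nm, paste(format(v, digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' Values are parsed as numeric where possible, logical for TRUE/FALSE, and
#' kept as strings otherwise; comma-separated values become vectors. Unknown
#' keys (when `known` is given) are rejected by name.
#'
#' @param path Configuration file.
#' @param known Optional character vector of accepted key names.
#' @return Named list.
#' @export
read_config <- function(path, known = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(kv[1])
    if (!is.null(known) && !key %in% known) {
      stop(sprintf("unknown configuration key '%s'", key), call. = FALSE)
    }
    vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num
      else if (all(vals %in% c("TRUE", "FALSE"))) as.logical(vals)
      else vals
  }
  out
}

#' Write a training log to CSV
#'
#' @param log Data frame from [train_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
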