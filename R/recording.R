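#' Construct an EEG recording
#'
#' The container every pipeline stage transforms: a channels x samples
#' potential matrix (microvolts) with its sampling rate, channel labels, a
#' per-channel retention mask over the *original* montage, and a log of
#' trimmed segments. Sample intervals in `segment_log` are 0-based and
#' half-open, `[start, end)`, expressed in the coordinates of the recording
#' they were removed from.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_labels optional character vector, defaults to ch001, ...
#' @param channel_mask logical vector over the original montage; `TRUE`
#'   entries correspond to the rows of `data`.
#' @param segment_log list of removed `c(start, end)` sample intervals.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          channel_mask = NULL, segment_log = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) ms_abort("recording contains non-finite values", "msvalid_invalid_argument")
  if (!is_number(sampling_rate) || sampling_rate <= 0) {
    ms_abort("sampling_rate must be a positive number", "msvalid_invalid_argument")
  }
  nch <- nrow(data)
  channel_mask <- channel_mask %||% rep(TRUE, nch)
  if (sum(channel_mask) != nch) {
    ms_abort("channel_mask must have one TRUE entry per data row", "msvalid_invalid_argument")
  }
  channel_labels <- channel_labels %||% sprintf("ch%03d", seq_len(nch))
  if (length(channel_labels) != nch) {
    ms_abort("channel_labels length must match retained channel count", "msvalid_invalid_argument")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels),
         channel_mask = as.logical(channel_mask), segment_log = segment_log),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$sampling_rate,
              x$sampling_rate))
  dropped <- sum(!x$channel_mask)
  if (dropped > 0) cat(sprintf("  %d channel(s) masked out of %d\n", dropped, length(x$channel_mask)))
  if (length(x$segment_log) > 0) cat(sprintf("  %d trimmed segment(s)\n", length(x$segment_log)))
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

## replace the data matrix, keeping metadata consistent
update_recording <- function(rec, data, channel_mask = rec$channel_mask,
                             channel_labels = rec$channel_labels,
                             segment_log = rec$segment_log) {
  eeg_recording(data, rec$sampling_rate, channel_labels = channel_labels,
                channel_mask = channel_mask, segment_log = segment_log)
}

#' Read and write recordings as delimited text with a JSON sidecar
#'
#' The on-disk format is a tab-separated table with one row per sample and a
#' header of channel labels, plus a `<path>.json` sidecar carrying the
#' sampling rate, channel mask, segment log, and any extra metadata (seed,
#' generator configuration, ...).
#'
#' @param rec an `eeg_recording`.
#' @param path path of the `.tsv` data file; the sidecar is `<path>.json`.
#' @param meta optional named list merged into the sidecar.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the reconstructed `eeg_recording` (the sidecar's extra metadata
#'   is attached as attribute `"meta"`).
#' @export
write_recording <- function(rec, path, meta = list()) {
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channel_labels)
  data.table::fwrite(dt, path, sep = "\t")
  sidecar <- c(
    list(sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels,
         channel_mask = rec$channel_mask,
         segment_log = rec$segment_log),
    meta
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  seg <- side$segment_log
  if (is.matrix(seg)) seg <- lapply(seq_len(nrow(seg)), function(i) seg[i, ])
  if (is.null(seg) || length(seg) == 0) seg <- list()
  rec <- eeg_recording(t(as.matrix(dt)), side$sampling_rate,
                       channel_labels = names(dt),
                       channel_mask = side$channel_mask,
                       segment_log = seg)
  extra <- side[setdiff(names(side), c("sampling_rate", "channel_labels",
                                       "channel_mask", "segment_log"))]
  attr(rec, "meta") <- extra
  rec
}

#' Read and write microstate template sets as delimited text
#'
#' Templates are stored as a tab-separated table (one row per template, a
#' `label` column followed by one column per channel) with a JSON sidecar
#' holding `k`, level and GEV.
#'
#' @param templates an `ms_template_set`.
#' @param path path of the `.tsv` file.
#' @return `write_templates` returns `path` invisibly; `read_templates`
#'   returns the `ms_template_set`.
#' @export
write_templates <- function(templates, path) {
  dt <- data.table::as.data.table(templates$maps)
  data.table::setnames(dt, sprintf("ch%03d", seq_len(templates$n_channels)))
  dt <- cbind(data.table::data.table(label = templates$labels), dt)
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(
    list(k = templates$k, level = templates$level, gev = templates$gev),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- dt$label
  maps <- as.matrix(dt[, -1])
  ms_template_set(maps, labels = labels, level = side$level,
                  gev = side$gev %||% NA_real_, normalize = FALSE)
}
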