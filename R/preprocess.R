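#' Zero-phase Butterworth band-pass and power-line notch filter
#'
#' Applies a 4th-order Butterworth band-pass (defaults 0.3--70 Hz) followed
#' by a second-order IIR notch (default 50 Hz, quality factor 30), both
#' forward--backward (zero phase) so microstate segment boundaries are not
#' delayed. Filtering is linear and applied independently per channel.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band-pass cutoffs, Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @param notch notch frequency, Hz, or `NULL` to disable.
#' @param notch_q notch quality factor (centre frequency / -3 dB width).
#' @return the filtered recording.
#' @export
bandpass_notch_filter <- function(rec, low = 0.3, high = 70, notch = 50,
                                  notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    ms_abort("cutoffs must satisfy 0 < low < high < Nyquist", "msvalid_invalid_argument")
  }
  if (!is.null(notch) && (notch < low || notch > high)) {
    ms_abort("notch must lie inside the pass band (or be NULL)", "msvalid_invalid_argument")
  }
  bp <- signal::butter(2, c(low, high) / nyq, type = "pass")
  flt <- function(x) {
    y <- signal::filtfilt(bp, x)
    if (!is.null(notch)) {
      nf <- design_notch(rec$sampling_rate, notch, notch_q)
      y <- signal::filtfilt(nf, y)
    }
    y
  }
  data <- t(apply(rec$data, 1, flt))
  update_recording(rec, data)
}

## RBJ biquad notch: zeros on the unit circle at the notch frequency,
## poles pulled inward by the quality factor
design_notch <- function(fs, f0, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Mask bad channels explicitly or by a robust-amplitude rule
#'
#' With an explicit logical `mask`, retained channels are subset verbatim.
#' In automatic mode a channel is dropped when its robust amplitude (median
#' absolute deviation of the channel over time) has a robust z-score across
#' channels greater than `z_threshold`, or when its variance is zero
#' (isoelectric / saturated flat channel).
#'
#' @param rec an [eeg_recording()].
#' @param mask logical vector over the currently retained channels, or
#'   `NULL` for automatic mode.
#' @param z_threshold robust z-score threshold (default 5).
#' @return the recording with offending channels removed; the original
#'   montage positions are recorded in `channel_mask`.
#' @export
apply_channel_mask <- function(rec, mask = NULL, z_threshold = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  nch <- n_channels(rec)
  if (is.null(mask)) {
    if (!is_number(z_threshold) || z_threshold <= 0) {
      ms_abort("z_threshold must be positive", "msvalid_invalid_argument")
    }
    amp <- apply(rec$data, 1, stats::mad)
    v <- apply(rec$data, 1, stats::var)
    s <- stats::mad(amp)
    z <- if (s > 0) (amp - stats::median(amp)) / s else rep(0, nch)
    mask <- !(z > z_threshold | v == 0)
  } else {
    mask <- as.logical(mask)
    if (length(mask) != nch) {
      ms_abort("mask length must equal the retained channel count", "msvalid_invalid_argument")
    }
  }
  if (sum(mask) < 2L) {
    ms_abort("fewer than 2 channels would survive masking", "msvalid_degenerate_recording")
  }
  if (all(mask)) return(rec)
  full <- rec$channel_mask
  full[which(full)[!mask]] <- FALSE
  update_recording(rec, rec$data[mask, , drop = FALSE], channel_mask = full,
                   channel_labels = rec$channel_labels[mask])
}

#' Trim windows where most electrodes are excessively noisy
#'
#' The record is scanned in 1-second windows (the trailing partial window
#' included); a window is removed when the proportion of channels whose peak
#' absolute amplitude exceeds `amp_threshold` is strictly greater than
#' `fraction` (default: more than half the electrodes). Removed intervals
#' are appended to `segment_log` as 0-based half-open `[start, end)` sample
#' pairs; surviving samples are concatenated bit-exactly.
#'
#' @param rec an [eeg_recording()].
#' @param amp_threshold peak-amplitude criterion, microvolts.
#' @param fraction proportion of channels that must exceed the threshold
#'   (strictly) for removal, in (0, 1].
#' @return the trimmed recording.
#' @export
trim_noisy_segments <- function(rec, amp_threshold = 100, fraction = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is_number(amp_threshold) || amp_threshold <= 0) {
    ms_abort("amp_threshold must be positive", "msvalid_invalid_argument")
  }
  if (!is_number(fraction) || fraction <= 0 || fraction > 1) {
    ms_abort("fraction must be in (0, 1]", "msvalid_invalid_argument")
  }
  total <- n_samples(rec)
  win <- max(1L, round(rec$sampling_rate))
  starts <- seq.int(1L, total, by = win)
  keep <- rep(TRUE, total)
  log_new <- rec$segment_log
  for (s in starts) {
    e <- min(s + win - 1L, total)
    peaks <- apply(abs(rec$data[, s:e, drop = FALSE]), 1, max)
    if (mean(peaks > amp_threshold) > fraction) {
      keep[s:e] <- FALSE
      log_new[[length(log_new) + 1L]] <- c(s - 1L, e)  # 0-based half-open
    }
  }
  if (!any(keep)) ms_abort("all windows removed", "msvalid_empty_recording")
  if (all(keep)) return(rec)
  update_recording(rec, rec$data[, keep, drop = FALSE], segment_log = log_new)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across retained channels, so each
#' column of the output sums to zero. Idempotent, and it leaves the GFP
#' trace unchanged (GFP is reference-free by construction).
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L) {
    ms_abort("average reference needs at least 2 channels", "msvalid_degenerate_recording")
  }
  update_recording(rec, sweep(rec$data, 2, colMeans(rec$data)))
}
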