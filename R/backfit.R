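#' Backfit global templates to a recording
#'
#' Assigns each GFP-peak map to the template with maximal squared spatial
#' correlation (polarity ignored), then labels every non-peak sample with
#' its temporally nearest peak's template (ties go to the earlier peak;
#' samples before the first and after the last peak inherit that peak's
#' label). Zero-GFP peak maps are skipped and logged. With
#' `at = "samples"`, assignment is instead computed at every sample
#' directly (useful when the GFP trace is flat, e.g. constant-envelope
#' surrogates, and for sensitivity analyses); degenerate zero-GFP samples
#' then inherit the nearest assigned sample's label.
#'
#' @param rec an [eeg_recording()] sharing the templates' channel space.
#' @param templates an `ms_template_set`.
#' @param at `"peaks"` (default) or `"samples"`.
#' @return an object of class `ms_segmentation`: per-sample `labels`
#'   (template indices), `peak_indices`, `peak_labels`, `sampling_rate`,
#'   `k`, `template_labels`, and the number of skipped peaks.
#' @export
backfit <- function(rec, templates, at = c("peaks", "samples")) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(templates, "ms_template_set"))
  at <- match.arg(at)
  if (n_channels(rec) != templates$n_channels) {
    ms_abort("recording and templates must share the channel space", "msvalid_invalid_argument")
  }
  trace <- compute_gfp(rec)
  peaks <- if (at == "samples") seq_len(n_samples(rec)) else find_gfp_peaks(trace)
  if (!length(peaks)) ms_abort("backfitting needs at least one GFP peak", "msvalid_empty_result")
  P <- peak_maps(rec, peaks)
  rn2 <- rowSums(P * P)
  skipped <- sum(rn2 == 0)
  if (skipped > 0) {
    keep <- rn2 > 0
    peaks <- peaks[keep]
    P <- P[keep, , drop = FALSE]
    rn2 <- rn2[keep]
    if (!length(peaks)) ms_abort("all peak maps have zero GFP", "msvalid_empty_result")
  }
  Tm <- template_maps_unit_norm(templates)
  A2 <- (P %*% t(Tm))^2
  peak_labels <- max.col(A2, ties.method = "first")
  total <- n_samples(rec)
  labels <- fill_nearest_peak(peaks, peak_labels, total)
  structure(
    list(labels = labels, peak_indices = peaks, peak_labels = peak_labels,
         sampling_rate = rec$sampling_rate, k = templates$k,
         template_labels = templates$labels, skipped_peaks = skipped),
    class = "ms_segmentation"
  )
}

## nearest-peak label interpolation; sample s between peaks p_i < p_{i+1}
## belongs to p_i iff s - p_i <= p_{i+1} - s, i.e. up to the (floored)
## midpoint, so equidistant samples take the earlier peak's label
fill_nearest_peak <- function(peaks, peak_labels, total) {
  m <- length(peaks)
  if (m == 1L) return(rep.int(peak_labels, total))
  cuts <- floor((peaks[-m] + peaks[-1]) / 2)  # last sample owned by peak i
  bounds <- c(cuts, total)
  rep.int(peak_labels, diff(c(0L, bounds)))
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples at %g Hz, %d templates, %d GFP peaks\n",
              length(x$labels), x$sampling_rate, x$k, length(x$peak_indices)))
  invisible(x)
}

#' Duration, occurrence and coverage of each microstate
#'
#' Runs are maximal constant-label intervals, boundary (truncated) runs
#' included. For template X: duration is the mean run length in ms;
#' occurrence is the number of runs per second of recording; coverage is
#' the percentage of samples labeled X. Coverage always sums to 100. A
#' template that never appears gets duration `NaN`, occurrence 0,
#' coverage 0.
#'
#' @param seg an `ms_segmentation`.
#' @return data.frame with one row per template: `template`, `duration_ms`,
#'   `occurrence_hz`, `coverage_pct`.
#' @export
compute_metrics <- function(seg) {
  stopifnot(inherits(seg, "ms_segmentation"))
  labels <- seg$labels
  if (!length(labels)) ms_abort("empty segmentation", "msvalid_invalid_argument")
  r <- rle(labels)
  total_s <- length(labels) / seg$sampling_rate
  k <- seg$k
  duration <- occurrence <- coverage <- numeric(k)
  for (x in seq_len(k)) {
    lens <- r$lengths[r$values == x]
    duration[x] <- mean(lens) * 1000 / seg$sampling_rate
    occurrence[x] <- length(lens) / total_s
    coverage[x] <- 100 * sum(lens) / length(labels)
  }
  data.frame(template = seg$template_labels, duration_ms = duration,
             occurrence_hz = occurrence, coverage_pct = coverage)
}

#' Transition percentages between microstates
#'
#' Transitions are counted between consecutive distinct runs of the label
#' sequence (self-transitions are impossible by construction), and each
#' ordered cell is expressed as a percentage of all transitions. With k
#' templates the off-diagonal enumerates k(k-1) ordered transition types
#' (12 for the canonical four-template set).
#'
#' @param seg an `ms_segmentation` with at least 2 runs.
#' @return k x k matrix of percentages with zero diagonal, summing to 100.
#' @export
transition_percentages <- function(seg) {
  stopifnot(inherits(seg, "ms_segmentation"))
  v <- rle(seg$labels)$values
  if (length(v) < 2L) {
    ms_abort("single-run segmentation: transitions undefined", "msvalid_undefined_transitions")
  }
  k <- seg$k
  counts <- matrix(0, k, k, dimnames = list(seg$template_labels, seg$template_labels))
  from <- v[-length(v)]
  to <- v[-1]
  for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  100 * counts / sum(counts)
}

#' Directional predominance between microstate pairs
#'
#' For each unordered template pair \{X, Y\}, the signed difference
#' `P(X -> Y) - P(Y -> X)` in percentage points: positive means transitions
#' run predominantly X to Y. With k templates there are k(k-1)/2 pairs
#' (6 for the canonical four), and `predominance(X,Y) = -predominance(Y,X)`.
#'
#' @param transition_pct a k x k transition-percentage matrix from
#'   [transition_percentages()].
#' @return data.frame with `from`, `to`, `pair`, `predominance_pct`.
#' @export
directional_predominance <- function(transition_pct) {
  transition_pct <- as.matrix(transition_pct)
  k <- nrow(transition_pct)
  if (k != ncol(transition_pct)) ms_abort("transition matrix must be square", "msvalid_invalid_argument")
  labs <- rownames(transition_pct) %||% make_template_labels(k)
  pairs <- utils::combn(k, 2)
  data.frame(
    from = labs[pairs[1, ]],
    to = labs[pairs[2, ]],
    pair = paste0(labs[pairs[1, ]], "<->", labs[pairs[2, ]]),
    predominance_pct = transition_pct[t(pairs)] - transition_pct[t(pairs[2:1, ])]
  )
}

#' All sequence metrics of a segmentation in one object
#'
#' Convenience wrapper bundling [compute_metrics()],
#' [transition_percentages()] and [directional_predominance()]. When the
#' segmentation has a single run the transition-dependent entries are
#' `NULL`.
#'
#' @param seg an `ms_segmentation`.
#' @return list of class `ms_metrics` with `summary`, `transition_pct`,
#'   `predominance`.
#' @export
microstate_metrics <- function(seg) {
  trans <- tryCatch(transition_percentages(seg),
                    msvalid_undefined_transitions = function(e) NULL)
  structure(
    list(summary = compute_metrics(seg),
         transition_pct = trans,
         predominance = if (is.null(trans)) NULL else directional_predominance(trans)),
    class = "ms_metrics"
  )
}
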