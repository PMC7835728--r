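#' Global dissimilarity between two scalp maps
#'
#' `GD = sqrt(mean((u/GFP_u - v/GFP_v)^2))` over channels, with each map
#' average-referenced before GFP normalization. GD is bounded in \[0, 2\]:
#' 0 means identical topographies (up to positive scaling), 2 means exactly
#' polarity-reversed topographies. Maps with zero GFP are an error.
#'
#' @param u,v numeric vectors of per-channel potentials, equal length.
#' @return the dissimilarity, a number in \[0, 2\].
#' @export
global_dissimilarity <- function(u, v) {
  if (length(u) != length(v)) {
    ms_abort("maps must have the same number of channels", "msvalid_invalid_argument")
  }
  u <- u - mean(u)
  v <- v - mean(v)
  gu <- sqrt(mean(u * u))
  gv <- sqrt(mean(v * v))
  if (gu == 0 || gv == 0) {
    ms_abort("zero-GFP map: dissimilarity undefined", "msvalid_undefined_dissimilarity")
  }
  sqrt(mean((u / gu - v / gv)^2))
}

## deterministic-sign principal axis of a stack of maps (rows); used to
## aggregate same-label individual templates into one group map
aggregate_label_maps <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) == 1L) {
    v <- M[1, ] - mean(M[1, ])
    v <- v / sqrt(sum(v * v))
  } else {
    M <- M - rowMeans(M)
    v <- power_axis(crossprod(M), M[1, ])
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Topographic permutation (TANOVA) test on same-label templates
#'
#' The observed effect size is the global dissimilarity between the two
#' groups' aggregated templates for one label (each group aggregated by the
#' sign-invariant principal axis of its members, the two aggregates
#' sign-aligned before GD, as in the group-template alignment step). The
#' null distribution is built by reassigning the pooled individual templates
#' to pseudo-groups of the original sizes `n_perm` times and recomputing the
#' aggregate GD. The p-value is the fraction of permuted GD values strictly
#' greater than the observed one (set `strictly_greater = FALSE` for the
#' conventional inclusive variant). Following the inverted-null convention
#' of template-identity testing, `p < 0.01` is reported as "statistically
#' identical" in `reported_identical`.
#'
#' @param group_a_sets,group_b_sets lists of `ms_template_set` (each
#'   containing `template_label`), or numeric matrices whose rows are the
#'   individual same-label maps.
#' @param template_label which template to compare (default `"A"`; ignored
#'   for matrix input).
#' @param n_perm number of permutations (default 10000; fewer than 100
#'   draws a warning). When both groups have a single member the 2-point
#'   null is enumerated exactly instead of sampled.
#' @param seed integer seed.
#' @param strictly_greater count only strictly greater permuted values.
#' @return list of class `ms_tanova`: `observed_gd`, `p_value`,
#'   `n_permutations`, `null_quantiles`, `reported_identical`, `exact`.
#' @export
tanova_permutation <- function(group_a_sets, group_b_sets, template_label = "A",
                               n_perm = 10000, seed = 1L,
                               strictly_greater = TRUE) {
  A <- extract_label_maps(group_a_sets, template_label)
  B <- extract_label_maps(group_b_sets, template_label)
  if (!nrow(A) || !nrow(B)) ms_abort("both groups must be non-empty", "msvalid_invalid_argument")
  if (ncol(A) != ncol(B)) ms_abort("groups must share the channel space", "msvalid_invalid_argument")
  if (n_perm < 100) ms_warn("fewer than 100 permutations", "msvalid_low_permutations")
  obs <- aggregate_gd(A, B)
  pool <- rbind(A, B)
  na <- nrow(A)
  n <- nrow(pool)
  exact <- (na == 1L && n == 2L)
  null_gd <- if (exact) {
    vapply(1:2, function(i) {
      aggregate_gd(pool[i, , drop = FALSE], pool[-i, , drop = FALSE])
    }, numeric(1))
  } else {
    withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(p) {
        ## sort so a drawn subset is a canonical partition: permutations
        ## of the same split reproduce the same aggregate bit for bit
        idx <- sort(sample.int(n, na))
        aggregate_gd(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
      }, numeric(1))
    })
  }
  p <- if (strictly_greater) mean(null_gd > obs) else mean(null_gd >= obs)
  structure(
    list(observed_gd = obs, p_value = p, n_permutations = length(null_gd),
         null_quantiles = stats::quantile(null_gd, c(0, 0.25, 0.5, 0.75, 0.95, 1)),
         reported_identical = p < 0.01, exact = exact,
         note = paste("inverted-null convention: p < 0.01 means the two",
                      "templates are reported as statistically identical")),
    class = "ms_tanova"
  )
}

#' @export
print.ms_tanova <- function(x, ...) {
  cat(sprintf("<ms_tanova> observed GD %.4f, p = %.4g (%s permutations)\n",
              x$observed_gd, x$p_value,
              if (x$exact) "exact" else format(x$n_permutations)))
  cat(" ", x$note, "\n")
  invisible(x)
}

extract_label_maps <- function(sets, template_label) {
  if (is.matrix(sets)) return(sets)
  if (inherits(sets, "ms_template_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    j <- match(template_label, s$labels)
    if (is.na(j)) ms_abort(sprintf("template '%s' missing from an individual set", template_label),
                           "msvalid_invalid_argument")
    s$maps[j, ]
  })
  do.call(rbind, rows)
}

aggregate_gd <- function(A, B) {
  u <- aggregate_label_maps(A)
  v <- aggregate_label_maps(B)
  if (spatial_correlation(u, v) < 0) v <- -v  # sign alignment step
  global_dissimilarity(u, v)
}

#' Cronbach's alpha
#'
#' `alpha = m/(m-1) * (1 - sum(var(item_j)) / var(sum of items))` with
#' sample variances (denominator n-1), for a cases x items matrix. Values
#' above 0.70 are conventionally read as high reliability.
#'
#' @param items_by_cases numeric matrix, cases in rows, items (>= 2) in
#'   columns; at least 3 cases.
#' @return the alpha coefficient.
#' @export
cronbach_alpha <- function(items_by_cases) {
  X <- as.matrix(items_by_cases)
  if (ncol(X) < 2L) ms_abort("need at least 2 items", "msvalid_invalid_argument")
  if (nrow(X) < 3L) ms_abort("need at least 3 cases", "msvalid_invalid_argument")
  if (!all(is.finite(X))) ms_abort("measurements must be finite", "msvalid_invalid_argument")
  vt <- stats::var(rowSums(X))
  if (vt == 0) ms_abort("zero total variance: reliability undefined", "msvalid_undefined_reliability")
  m <- ncol(X)
  m / (m - 1) * (1 - sum(apply(X, 2, stats::var)) / vt)
}

#' Two-tailed paired t-test
#'
#' Standard paired t on the differences with `n - 1` degrees of freedom;
#' zero-variance differences raise an undefined-test error instead of a
#' division by zero.
#'
#' @param x,y paired measurement vectors, equal length >= 3.
#' @return list with `t`, `df`, `p`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) ms_abort("x and y must have equal length", "msvalid_invalid_argument")
  if (length(x) < 3L) ms_abort("need at least 3 pairs", "msvalid_invalid_argument")
  d <- x - y
  if (stats::var(d) == 0) {
    ms_abort("zero-variance differences: t-test undefined", "msvalid_undefined_test")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Split a recording into first and second halves
#'
#' The first half takes samples `1..ceiling(n/2)`, the second the rest, so
#' concatenating the halves reproduces the input bit-exactly; a 10-minute
#' recording yields two 5-minute halves.
#'
#' @param rec an [eeg_recording()] with at least 2 samples.
#' @return list with `first` and `second` recordings.
#' @export
split_half <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  if (n < 2L) ms_abort("recording too short to split", "msvalid_invalid_argument")
  n1 <- ceiling(n / 2)
  list(
    first = update_recording(rec, rec$data[, seq_len(n1), drop = FALSE], segment_log = list()),
    second = update_recording(rec, rec$data[, (n1 + 1):n, drop = FALSE], segment_log = list())
  )
}
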