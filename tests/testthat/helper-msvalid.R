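# shared fixtures and independent oracles, built in code at test time

# random average-referenced map
random_zero_mean_map <- function(n) {
  m <- rnorm(n)
  m - mean(m)
}

# straight-line GEV for a fixed hard assignment: templates as first
# principal axes of each cluster via eigen(), no power iteration, no
# package internals — the exhaustive-partition oracle builds on this
oracle_partition_gev <- function(X, assign, k) {
  X <- X - rowMeans(X)
  num <- 0
  for (j in seq_len(k)) {
    idx <- which(assign == j)
    if (!length(idx)) return(NA_real_)
    S <- crossprod(X[idx, , drop = FALSE])
    v <- eigen(S, symmetric = TRUE)$vectors[, 1]
    num <- num + sum((X[idx, , drop = FALSE] %*% v)^2)
  }
  num / sum(X * X)
}

# exhaustive search over all assignments of P maps to k labeled clusters
# (partitions recovered by ignoring label order); optimal GEV
oracle_best_gev <- function(X, k) {
  P <- nrow(X)
  best <- -Inf
  assign <- rep(1L, P)
  total <- k^P
  for (code in 0:(total - 1)) {
    a <- integer(P)
    c0 <- code
    for (i in seq_len(P)) {
      a[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    if (length(unique(a)) < k) next
    g <- oracle_partition_gev(X, a, k)
    if (is.finite(g) && g > best) best <- g
  }
  best
}

# independent aggregate-and-GD computation mirroring the TANOVA statistic:
# principal axis by eigen(), sign-aligned GD evaluated from its formula
oracle_aggregate_gd <- function(A, B) {
  axis <- function(M) {
    M <- M - rowMeans(M)
    if (nrow(M) == 1L) v <- M[1, ] else v <- eigen(crossprod(M), symmetric = TRUE)$vectors[, 1]
    v
  }
  gd <- function(u, v) {
    u <- u - mean(u); v <- v - mean(v)
    sqrt(mean((u / sqrt(mean(u^2)) - v / sqrt(mean(v^2)))^2))
  }
  u <- axis(A); v <- axis(B)
  if (sum((u - mean(u)) * (v - mean(v))) < 0) v <- -v
  gd(u, v)
}

# build an ms_segmentation directly from a label vector
segmentation_from_labels <- function(labels, sampling_rate, k,
                                     template_labels = LETTERS[seq_len(k)]) {
  structure(
    list(labels = as.integer(labels), peak_indices = seq_along(labels),
         peak_labels = as.integer(labels), sampling_rate = sampling_rate,
         k = as.integer(k), template_labels = template_labels,
         skipped_peaks = 0L),
    class = "ms_segmentation"
  )
}

# hand-built ICA decomposition object with known algebra (identity PCA);
# the unmixing matrix is not needed by reprojection and is left NULL
manual_decomposition <- function(mixing, sources, sampling_rate = 250) {
  structure(
    list(mixing = mixing, unmixing = NULL,
         sources = sources, center = rep(0, nrow(mixing)),
         n_ics = ncol(mixing), pca_rank = ncol(mixing),
         sampling_rate = sampling_rate,
         channel_labels = sprintf("ch%03d", seq_len(nrow(mixing))),
         channel_mask = rep(TRUE, nrow(mixing)),
         seed = 1L, iterations = 0L, converged = TRUE),
    class = "ica_decomposition"
  )
}

# count well-separated pulse events in a source time course: local maxima
# above half the global maximum
count_source_events <- function(tc) {
  thr <- 0.5 * max(tc)
  locmax <- which(diff(sign(diff(tc))) == -2) + 1L
  sum(tc[locmax] > thr)
}
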