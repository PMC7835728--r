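#' Global field power trace of a recording
#'
#' For each sample, GFP is the population standard deviation of the
#' potentials across retained channels, `sqrt(mean((v - mean(v))^2))` — a
#' reference-free index of field strength whose local maxima mark moments of
#' maximal topographic stability.
#'
#' @param rec an [eeg_recording()] (at least 2 retained channels).
#' @return an object of class `gfp_trace` with fields `gfp` (per-sample
#'   values) and `peak_indices` (filled by [find_gfp_peaks()], `NULL` here).
#' @export
compute_gfp <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L) ms_abort("GFP needs at least 2 channels", "msvalid_degenerate_recording")
  m <- colMeans(rec$data)
  g2 <- colMeans(rec$data * rec$data) - m * m
  structure(list(gfp = sqrt(pmax(g2, 0)), peak_indices = NULL,
                 sampling_rate = rec$sampling_rate),
            class = "gfp_trace")
}

#' Locate GFP peaks
#'
#' A peak is an interior sample `i` with `gfp[i-1] < gfp[i]` and
#' `gfp[i] > gfp[i+1]`; a plateau of exactly tied values counts once, at its
#' first sample, provided the plateau rises from the left and falls to the
#' right. Endpoints are never peaks. An empty result is signalled with a
#' warning because downstream clustering needs at least `k` peaks.
#'
#' @param trace a `gfp_trace` or a numeric GFP vector (length >= 3).
#' @return integer vector of 1-based peak sample indices (also stored into
#'   the trace's `peak_indices` when a `gfp_trace` was supplied — use the
#'   return value).
#' @export
find_gfp_peaks <- function(trace) {
  gfp <- if (inherits(trace, "gfp_trace")) trace$gfp else as.numeric(trace)
  n <- length(gfp)
  if (n < 3L) ms_abort("GFP trace must have at least 3 samples", "msvalid_invalid_argument")
  r <- rle(gfp)
  m <- length(r$values)
  peaks <- integer(0)
  if (m >= 3L) {
    j <- 2:(m - 1L)
    is_peak <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
    starts <- cumsum(r$lengths) - r$lengths + 1L
    peaks <- starts[j][is_peak]
  }
  if (!length(peaks)) {
    ms_warn("no GFP peaks found", "msvalid_empty_result")
  }
  peaks
}

#' Extract average-referenced scalp maps at given samples
#'
#' Returns the maps at the requested samples (typically GFP peaks) as a
#' maps x channels matrix, each row average-referenced — the input format
#' of [modified_kmeans()], [select_k_kl()] and [explained_variance()].
#'
#' @param rec an [eeg_recording()].
#' @param samples integer sample indices (e.g. from [find_gfp_peaks()]).
#' @return numeric matrix, `length(samples)` x channels.
#' @export
maps_at_peaks <- function(rec, samples) {
  m <- t(rec$data[, samples, drop = FALSE])
  m - rowMeans(m)
}

## historical internal alias
peak_maps <- maps_at_peaks

## shared preparation for clustering: average-reference rows, squared norms
prepare_maps <- function(maps) {
  if (inherits(maps, "ms_template_set")) maps <- maps$maps
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  rn2 <- rowSums(maps * maps)
  if (any(rn2 == 0)) ms_abort("zero-GFP map(s) cannot be clustered", "msvalid_invalid_argument")
  list(X = maps, rn2 = rn2)
}

## dominant eigenvector of a PSD matrix by warm-started power iteration;
## crossprod inputs are PSD so the iteration cannot oscillate in sign
power_axis <- function(S, v0, tol = 1e-12, max_iter = 1000L) {
  nv <- sqrt(sum(v0 * v0))
  v <- if (nv > 0) v0 / nv else {
    v0[1] <- 1
    v0
  }
  for (i in seq_len(max_iter)) {
    w <- as.numeric(S %*% v)
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(v)  # degenerate cluster; keep previous axis
    w <- w / nw
    if (sum(abs(w - v)) < tol) return(w)
    v <- w
  }
  v
}

## one modified-k-means run from a fixed initialization.
## X: P x N average-referenced maps; rn2: squared row norms; Tm: k x N
## unit-L2 templates. Assignment maximizes squared spatial correlation
## (polarity-blind); template update is the first principal axis of the
## assigned maps. Both steps are monotone in GEV.
ms_kmeans_core <- function(X, rn2, Tm, max_iter = 500L, tol = 1e-7) {
  P <- nrow(X)
  k <- nrow(Tm)
  denom <- sum(rn2)
  assign_prev <- rep(0L, P)
  gev_prev <- -Inf
  gev <- 0
  assign <- assign_prev
  empty_events <- 0L
  for (it in seq_len(max_iter)) {
    A <- X %*% t(Tm)
    A2 <- A * A
    assign <- max.col(A2, ties.method = "first")
    present <- tabulate(assign, nbins = k) > 0L
    if (!all(present)) {
      ## reseed each empty template from the currently worst-fitted map
      fit <- A2[cbind(seq_len(P), assign)] / rn2
      ord <- order(fit)
      used <- integer(0)
      for (j in which(!present)) {
        pick <- ord[!(ord %in% used)][1]
        used <- c(used, pick)
        Tm[j, ] <- X[pick, ] / sqrt(rn2[pick])
        empty_events <- empty_events + 1L
      }
      A <- X %*% t(Tm)
      A2 <- A * A
      assign <- max.col(A2, ties.method = "first")
    }
    gev <- sum(A2[cbind(seq_len(P), assign)]) / denom
    if (identical(assign, assign_prev) ||
        abs(gev - gev_prev) < tol * max(abs(gev_prev), .Machine$double.eps)) {
      break
    }
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      S <- crossprod(X[idx, , drop = FALSE])
      Tm[j, ] <- power_axis(S, Tm[j, ])
    }
    assign_prev <- assign
    gev_prev <- gev
  }
  list(Tm = Tm, assign = assign, gev = gev, iterations = it,
       empty_reseeds = empty_events)
}

#' Polarity-invariant modified k-means clustering of scalp maps
#'
#' Each map is assigned to the template maximizing the *squared* spatial
#' correlation, so map polarity is ignored, and each template is updated as
#' the first principal axis of its assigned maps (the sign-invariant
#' analogue of the cluster mean). Iteration stops at an assignment fixpoint
#' or when the relative GEV change falls below `tol`. The best of
#' `n_restarts` random map initializations (by GEV) is returned; ties keep
#' the earliest restart, and equal correlations assign to the lowest
#' template index, so the fit is deterministic for a fixed seed. Empty
#' clusters are reseeded from the worst-fitted map and logged.
#'
#' @param maps numeric matrix of maps (rows) x channels, or an
#'   `ms_template_set`; typically the maps at GFP peaks.
#' @param k number of templates (1 <= k <= number of maps).
#' @param n_restarts random initializations (default 50).
#' @param seed integer seed.
#' @param max_iter,tol per-run iteration cap and relative GEV tolerance.
#' @param init_templates optional list of k x N matrices used as additional
#'   (deterministic) initializations before the random restarts.
#' @return a list of class `ms_kmeans_fit`: `templates` (an
#'   [ms_template_set()]), `assignments`, `gev`, `dispersion` (the
#'   GFP-squared-weighted within-cluster dispersion W), restart diagnostics.
#' @export
modified_kmeans <- function(maps, k, n_restarts = 50, seed = 1L,
                            max_iter = 500L, tol = 1e-7, init_templates = NULL) {
  prep <- prepare_maps(maps)
  X <- prep$X
  rn2 <- prep$rn2
  P <- nrow(X)
  if (!is_count(k, 1L) || k > P) {
    ms_abort("k must satisfy 1 <= k <= number of maps", "msvalid_invalid_argument")
  }
  if (!is_count(n_restarts, 1L)) ms_abort("n_restarts must be >= 1", "msvalid_invalid_argument")
  Xn <- X / sqrt(rn2)
  inits <- lapply(init_templates %||% list(), function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(k, ncol(X)))) {
      ms_abort("init_templates entries must be k x n_channels", "msvalid_invalid_argument")
    }
    unit_norm_rows(m - rowMeans(m))
  })
  n_random <- if (k == 1L) min(n_restarts, 1L) else n_restarts
  rand_idx <- withr::with_seed(seed, {
    lapply(seq_len(n_random), function(i) sample.int(P, k))
  })
  inits <- c(inits, lapply(rand_idx, function(ii) Xn[ii, , drop = FALSE]))
  best <- NULL
  for (ini in inits) {
    run <- ms_kmeans_core(X, rn2, ini, max_iter = max_iter, tol = tol)
    if (is.null(best) || run$gev > best$gev + 1e-15) best <- run
  }
  W <- sum(rn2) / ncol(X) * (1 - best$gev)
  structure(
    list(templates = ms_template_set(best$Tm, level = "individual", gev = best$gev),
         assignments = best$assign, gev = best$gev, dispersion = W,
         k = as.integer(k), iterations = best$iterations,
         empty_reseeds = best$empty_reseeds, n_restarts = length(inits)),
    class = "ms_kmeans_fit"
  )
}

#' Select the number of microstate templates by the Krzanowski--Lai criterion
#'
#' Runs [modified_kmeans()] for each `k` in `k_min:k_max` and evaluates the
#' dispersion curve `W(k)` (the squared-GFP-weighted within-cluster
#' dispersion). With `N` channels, `DIFF(k) = (k-1)^(2/N) W(k-1) -
#' k^(2/N) W(k)` and `KL(k) = |DIFF(k)| / |DIFF(k+1)|`; the optimum is the
#' `k` maximizing KL over the interior of the range (KL is undefined at both
#' ends), with ties resolved toward the smaller `k`. Each `k` additionally
#' receives a warm-start initialization built from the previous optimum plus
#' its worst-fitted map, which guarantees `W(k)` is non-increasing.
#'
#' @param maps maps x channels matrix (more maps than `k_max`).
#' @param k_min,k_max cluster-count range (defaults 1 and 12).
#' @param n_restarts,seed,max_iter,tol passed to [modified_kmeans()].
#' @param keep_fits return the per-k fits (default `TRUE`).
#' @return list with `k_opt`, `kl_curve`, `dispersion_curve`, `gev_curve`,
#'   and (optionally) `fits`, a list of `ms_kmeans_fit` indexed by k.
#' @export
select_k_kl <- function(maps, k_min = 1, k_max = 12, n_restarts = 50, seed = 1L,
                        max_iter = 500L, tol = 1e-7, keep_fits = TRUE) {
  prep <- prepare_maps(maps)
  if (!is_count(k_min, 1L) || !is_count(k_max, 1L) || k_min >= k_max) {
    ms_abort("need 1 <= k_min < k_max", "msvalid_invalid_argument")
  }
  if (nrow(prep$X) <= k_max) {
    ms_abort("need more maps than k_max", "msvalid_invalid_argument")
  }
  N <- ncol(prep$X)
  ks <- k_min:k_max
  W <- stats::setNames(numeric(length(ks)), ks)
  gev <- W
  fits <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    init <- NULL
    if (!is.null(prev)) {
      ## previous optimum + its worst-fitted map: guarantees monotone W
      pt <- template_maps_unit_norm(prev$templates)
      Xn <- prep$X / sqrt(prep$rn2)
      fit_q <- (Xn %*% t(pt))^2
      worst <- which.min(apply(fit_q, 1, max))
      init <- list(rbind(pt, Xn[worst, ]))
    }
    f <- modified_kmeans(prep$X, k, n_restarts = n_restarts,
                         seed = ms_seed(seed, k), max_iter = max_iter,
                         tol = tol, init_templates = init)
    W[i] <- f$dispersion
    gev[i] <- f$gev
    fits[[i]] <- f
    prev <- f
  }
  if (diff(range(W)) == 0) {
    ms_abort("dispersion curve is flat: cannot select k", "msvalid_selection_failure")
  }
  ## DIFF(k) needs W(k-1); defined for k_min+1 .. k_max
  diff_k <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (i in seq_along(ks)[-1]) {
    k <- ks[i]
    diff_k[i] <- (k - 1)^(2 / N) * W[i - 1] - k^(2 / N) * W[i]
  }
  kl <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k <= k_min || k >= k_max) next
    num <- abs(diff_k[i])
    den <- abs(diff_k[i + 1])
    kl[i] <- if (den > 0) num / den else if (num > 0) Inf else NA_real_
  }
  window <- ks >= max(2, k_min + 1) & ks <= k_max - 1
  cand <- which(window & !is.na(kl))
  if (!length(cand)) {
    ms_abort("KL criterion undefined everywhere in the search window", "msvalid_selection_failure")
  }
  k_opt <- ks[cand[which.max(kl[cand])]]  # which.max: first max -> smallest k
  list(k_opt = as.integer(k_opt), kl_curve = kl, dispersion_curve = W,
       gev_curve = gev, fits = if (keep_fits) stats::setNames(fits, ks) else NULL)
}

#' Global explained variance of a template set
#'
#' `GEV = sum((gfp_p * |cor_p|)^2) / sum(gfp_p^2)` over peak maps, where
#' each map is assigned to the template with maximal squared spatial
#' correlation and `gfp_p` is the map's field strength. Returned as a
#' proportion in \[0, 1\].
#'
#' @param templates an `ms_template_set` (or template matrix).
#' @param maps maps x channels matrix (e.g. the maps at GFP peaks).
#' @param gfp optional per-map GFP weights; defaults to the maps' own GFP.
#' @return proportion of explained variance.
#' @export
explained_variance <- function(templates, maps, gfp = NULL) {
  Tm <- template_maps_unit_norm(templates)
  prep <- prepare_maps(maps)
  if (ncol(Tm) != ncol(prep$X)) {
    ms_abort("templates and maps must share the channel space", "msvalid_invalid_argument")
  }
  N <- ncol(prep$X)
  corr <- (prep$X / sqrt(prep$rn2)) %*% t(Tm)
  best <- apply(corr * corr, 1, max)
  g <- if (is.null(gfp)) sqrt(prep$rn2 / N) else as.numeric(gfp)
  if (length(g) != nrow(prep$X)) {
    ms_abort("gfp weights must match the number of maps", "msvalid_invalid_argument")
  }
  tot <- sum(g * g)
  if (tot == 0) ms_abort("zero total GFP: GEV undefined", "msvalid_undefined")
  sum(g * g * best) / tot
}

## all permutations of 1..k (k <= 6 in practice: 720 rows)
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                   sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

## best label permutation (member row j -> global slot perm[j]) and signs
## maximizing total |correlation|; exhaustive for k <= 6, greedy otherwise
align_to_global <- function(member_unit, global_unit) {
  k <- nrow(member_unit)
  C <- member_unit %*% t(global_unit)
  aC <- abs(C)
  if (k <= 6L) {
    perms <- all_permutations(k)
    scores <- perms
    tot <- vapply(seq_len(nrow(perms)), function(r) {
      sum(aC[cbind(seq_len(k), perms[r, ])])
    }, numeric(1))
    perm <- perms[which.max(tot), ]
  } else {
    perm <- integer(k)
    left_r <- seq_len(k)
    left_c <- seq_len(k)
    tmp <- aC
    for (step in seq_len(k)) {
      pos <- arrayInd(which.max(tmp[left_r, left_c, drop = FALSE]),
                      c(length(left_r), length(left_c)))
      perm[left_r[pos[1]]] <- left_c[pos[2]]
      left_r <- left_r[-pos[1]]
      left_c <- left_c[-pos[2]]
    }
  }
  signs <- sign(C[cbind(seq_len(k), perm)])
  signs[signs == 0] <- 1
  list(perm = perm, signs = signs)
}

#' Aggregate individual template sets into group-level global templates
#'
#' Iterative alignment-and-average: starting from the first individual set,
#' each iteration (a) finds, for every individual set, the label permutation
#' and per-template sign maximizing its total absolute spatial correlation
#' with the current global set (exhaustively over permutations for k <= 6,
#' greedily above), and (b) recomputes each global template as the first
#' principal axis of its aligned members. Iteration stops at an alignment
#' fixpoint. Global templates are ordered by descending total squared
#' correlation with their aligned members and labeled A, B, C, ...
#'
#' @param individual_sets list of `ms_template_set`, all with the same k.
#' @param k optional expected k (checked against the sets).
#' @param seed unused randomness hook kept for interface stability.
#' @param max_iter alignment iteration cap (default 100).
#' @return an `ms_template_set` with `level = "global"`.
#' @export
build_group_templates <- function(individual_sets, k = NULL, seed = 1L,
                                  max_iter = 100L) {
  if (!length(individual_sets)) ms_abort("need at least one set", "msvalid_invalid_argument")
  ks <- vapply(individual_sets, function(s) s$k, integer(1))
  if (length(unique(ks)) != 1L || (!is.null(k) && ks[1] != k)) {
    ms_abort("all individual sets must share the same k", "msvalid_invalid_argument")
  }
  k <- ks[1]
  members <- lapply(individual_sets, template_maps_unit_norm)
  G <- members[[1]]
  n_sets <- length(members)
  align_prev <- NULL
  for (it in seq_len(max_iter)) {
    aligns <- lapply(members, align_to_global, global_unit = G)
    if (!is.null(align_prev) && identical(aligns, align_prev)) break
    for (g in seq_len(k)) {
      stack <- t(vapply(seq_len(n_sets), function(i) {
        j <- which(aligns[[i]]$perm == g)
        aligns[[i]]$signs[j] * members[[i]][j, ]
      }, numeric(ncol(G))))
      if (n_sets == 1L) stack <- matrix(stack, 1L)
      G[g, ] <- power_axis(crossprod(stack), G[g, ])
    }
    align_prev <- aligns
  }
  aligns <- align_prev %||% lapply(members, align_to_global, global_unit = G)
  score <- numeric(k)
  for (i in seq_len(n_sets)) {
    C <- members[[i]] %*% t(G)
    score <- score + C[cbind(order(aligns[[i]]$perm), seq_len(k))]^2
  }
  ord <- order(score, decreasing = TRUE)
  ms_template_set(G[ord, , drop = FALSE], level = "global")
}
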