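#' Decompose a recording into independent components
#'
#' Channels are centered, reduced to `n_ics` dimensions by PCA prewhitening,
#' and unmixed with the extended Infomax algorithm (full-batch natural
#' gradient with kurtosis-based switching between super- and sub-Gaussian
#' score functions). `mixing %*% sources` plus the stored channel means
#' reconstructs the rank-`n_ics` PCA projection of the input to within
#' numerical precision, whether or not ICA rotates the subspace well.
#' A fixed 50-component decomposition is the conventional default for
#' montages of 64 channels or more; smaller recordings must lower `n_ics`.
#'
#' @param rec an [eeg_recording()].
#' @param n_ics number of components (2 <= n_ics <= channels).
#' @param seed integer seed (the algorithm is deterministic given the data;
#'   the seed is kept in the object for provenance).
#' @param max_iter,tol iteration cap and normalized-gradient tolerance for
#'   the natural-gradient iteration.
#' @param lrate learning rate for the natural-gradient updates.
#' @param on_nonconvergence `"error"` (default) raises a convergence-failure
#'   condition with diagnostics; `"warn"` keeps the last iterate.
#' @return an object of class `ica_decomposition` with fields `mixing`
#'   (channels x n_ics), `unmixing` (n_ics x channels), `sources`
#'   (n_ics x samples), `center`, `n_ics`, `pca_rank`, and convergence info.
#' @export
decompose_ica <- function(rec, n_ics = 50, seed = 1L, max_iter = 5000,
                          tol = 1e-5, lrate = 0.05,
                          on_nonconvergence = c("error", "warn")) {
  stopifnot(inherits(rec, "eeg_recording"))
  on_nonconvergence <- match.arg(on_nonconvergence)
  nch <- n_channels(rec)
  if (!is_count(n_ics, 2L)) ms_abort("n_ics must be an integer >= 2", "msvalid_invalid_argument")
  if (n_ics > nch) ms_abort("n_ics cannot exceed the retained channel count", "msvalid_invalid_argument")
  X <- rec$data
  total <- ncol(X)
  center <- rowMeans(X)
  Xc <- X - center
  cv <- tcrossprod(Xc) / total
  eg <- eigen(cv, symmetric = TRUE)
  d <- eg$values[seq_len(n_ics)]
  if (any(d <= .Machine$double.eps * max(eg$values) * nch)) {
    ms_abort("requested n_ics exceeds the numerical rank of the data", "msvalid_invalid_argument")
  }
  E <- eg$vectors[, seq_len(n_ics), drop = FALSE]
  whiten <- (1 / sqrt(d)) * t(E)       # n_ics x channels
  dewhiten <- E * rep(sqrt(d), each = nch)
  Z <- whiten %*% Xc
  fit <- infomax_extended(Z, max_iter = max_iter, tol = tol, lrate = lrate)
  if (!fit$converged) {
    msg <- sprintf("extended Infomax did not converge in %d iterations (last relative weight change %.3g)",
                   max_iter, fit$last_change)
    if (on_nonconvergence == "error") ms_abort(msg, "msvalid_convergence_failure")
    ms_warn(msg, "msvalid_convergence_failure")
  }
  W <- fit$W
  sources <- W %*% Z
  structure(
    list(mixing = dewhiten %*% solve(W), unmixing = W %*% whiten,
         sources = sources, center = center, n_ics = as.integer(n_ics),
         pca_rank = as.integer(n_ics), sampling_rate = rec$sampling_rate,
         channel_labels = rec$channel_labels, channel_mask = rec$channel_mask,
         seed = as.integer(seed), iterations = fit$iterations,
         converged = fit$converged),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d ICs from %d channels x %d samples (%s after %d iterations)\n",
              x$n_ics, length(x$center), ncol(x$sources),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

## Extended Infomax on whitened data: natural-gradient ascent of the
## information-maximization objective, with the per-component sign matrix K
## (+1 super-Gaussian, -1 sub-Gaussian) estimated from the sample kurtosis
## each iteration. Full-batch updates with a fixed learning rate keep the
## fit deterministic; the rate is halved (and the iteration restarted)
## only if the weights blow up. Convergence is declared when the Frobenius
## norm of the natural gradient, divided by the component count, falls
## below `tol` — at the Infomax fixed point that gradient is exactly zero.
infomax_extended <- function(Z, max_iter = 5000, tol = 1e-5, lrate = 0.05) {
  n <- nrow(Z)
  total <- ncol(Z)
  lr <- lrate
  W <- diag(n)
  I_n <- diag(n)
  gn <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    m2 <- rowMeans(U * U)
    m4 <- rowMeans(U^4)
    ksign <- ifelse(m4 / pmax(m2 * m2, .Machine$double.eps) - 3 >= 0, 1, -1)
    Y <- tanh(U)
    G <- I_n - (ksign * Y) %*% t(U) / total - U %*% t(U) / total
    gn <- sqrt(sum(G * G)) / n
    if (gn < tol) { converged <- TRUE; break }
    W <- W + lr * (G %*% W)
    if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
      lr <- lr / 2           # blown up: restart smaller
      W <- diag(n)
      gn <- Inf
      it <- 0L
      if (lr < 1e-6) break
    }
  }
  list(W = W, iterations = it, converged = converged, last_change = gn)
}

#' Remove components and reproject to sensor space
#'
#' Reconstructs the recording from the retained components only:
#' `mixing[, keep] %*% sources[keep, ]` plus the stored channel means.
#' Removing the empty set reproduces the rank-`n_ics` reconstruction, and
#' removal is linear in the retained set (removing A then B equals removing
#' the union).
#'
#' @param dec an `ica_decomposition`.
#' @param remove integer indices of components to discard.
#' @param allow_empty permit removing every component (returns the
#'   mean-only recording) instead of raising an empty-model error.
#' @return the denoised [eeg_recording()].
#' @export
remove_ics_and_reproject <- function(dec, remove = integer(0), allow_empty = FALSE) {
  stopifnot(inherits(dec, "ica_decomposition"))
  remove <- as.integer(remove)
  if (length(remove) && (any(remove < 1L) || any(remove > dec$n_ics))) {
    ms_abort("remove indices must lie in 1..n_ics", "msvalid_invalid_argument")
  }
  keep <- setdiff(seq_len(dec$n_ics), remove)
  if (!length(keep) && !allow_empty) {
    ms_abort("removing every component leaves an empty model", "msvalid_empty_model")
  }
  data <- if (length(keep)) {
    dec$mixing[, keep, drop = FALSE] %*% dec$sources[keep, , drop = FALSE] + dec$center
  } else {
    matrix(dec$center, length(dec$center), ncol(dec$sources))
  }
  eeg_recording(data, dec$sampling_rate, channel_labels = dec$channel_labels,
                channel_mask = dec$channel_mask)
}

#' Label components against ground-truth artifact sources
#'
#' A component is flagged artifactual when the absolute temporal correlation
#' between its source time course and any injected artifact source exceeds
#' `threshold`; the flag is recorded under that artifact's class (with
#' eyeblink and eye movement merged into the conventional `eye` class).
#' This stands in for an automated classifier when the truth is known.
#'
#' @param dec an `ica_decomposition`.
#' @param truth an `ms_artifact_truth` from [inject_artifacts()].
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return an `ic_label_vector`: a data.frame with one row per component and
#'   binary columns `eye`, `myogenic`, `cardiac`, `artifact`, plus a
#'   `provenance` attribute of `"ground_truth"`.
#' @export
label_ics_from_ground_truth <- function(dec, truth, threshold = 0.8) {
  stopifnot(inherits(dec, "ica_decomposition"), inherits(truth, "ms_artifact_truth"))
  out <- ic_label_vector(dec$n_ics, provenance = "ground_truth")
  if (nrow(truth$sources) == 0) return(out)
  active <- which(truth$amplitudes > 0)
  for (i in active) {
    r <- abs(as.numeric(stats::cor(t(dec$sources), truth$sources[i, ])))
    hit <- which(r > threshold)
    col <- label_class_column(truth$classes[i])
    out[hit, col] <- 1L
  }
  out
}

label_class_column <- function(class) {
  switch(class, eyeblink = "eye", eye_movement = "eye", cardiac = "cardiac",
         myogenic = "myogenic", "artifact")
}

#' @rdname label_ics_from_ground_truth
#' @param n_ics number of components.
#' @param provenance one of `"expert"`, `"automated"`, `"ground_truth"`.
#' @export
ic_label_vector <- function(n_ics, provenance = c("expert", "automated", "ground_truth")) {
  provenance <- match.arg(provenance)
  out <- data.frame(ic = seq_len(n_ics), eye = 0L, myogenic = 0L,
                    cardiac = 0L, artifact = 0L)
  attr(out, "provenance") <- provenance
  class(out) <- c("ic_label_vector", "data.frame")
  out
}

#' @rdname label_ics_from_ground_truth
#' @param labels an `ic_label_vector`.
#' @export
flagged_ics <- function(labels) {
  which(rowSums(labels[, c("eye", "myogenic", "cardiac", "artifact")]) > 0)
}

#' Concatenate per-recording label vectors for paired testing
#'
#' Binds one class column from several recordings' label vectors into a
#' single binary vector, mirroring the convention of pooling datasets x
#' components per condition before a McNemar comparison.
#'
#' @param label_list list of `ic_label_vector` objects.
#' @param class one of `"eye"`, `"myogenic"`, `"cardiac"`, `"artifact"`.
#' @return integer vector of 0/1 flags.
#' @export
concat_ic_labels <- function(label_list, class = c("eye", "myogenic", "cardiac", "artifact")) {
  class <- match.arg(class)
  unlist(lapply(label_list, function(l) as.integer(l[[class]])), use.names = FALSE)
}

#' McNemar test with continuity correction on paired binary label vectors
#'
#' With `b` the count of pairs labeled 1 only in `labels_a` and `c` the
#' count labeled 1 only in `labels_b`, the statistic is
#' `(|b - c| - 1)^2 / (b + c)`, referred to a chi-square law with one degree
#' of freedom. When no discordant pairs exist the test is undefined and a
#' typed error is raised rather than returning 0.
#'
#' @param labels_a,labels_b equal-length binary vectors.
#' @return list with `chi2`, `p`, and the discordant counts `b` and `c`.
#' @export
mcnemar_compare <- function(labels_a, labels_b) {
  labels_a <- as.integer(labels_a)
  labels_b <- as.integer(labels_b)
  if (length(labels_a) != length(labels_b)) {
    ms_abort("label vectors must have equal length", "msvalid_invalid_argument")
  }
  if (!all(labels_a %in% c(0L, 1L)) || !all(labels_b %in% c(0L, 1L))) {
    ms_abort("labels must be binary", "msvalid_invalid_argument")
  }
  b <- sum(labels_a == 1L & labels_b == 0L)
  cc <- sum(labels_a == 0L & labels_b == 1L)
  if (b + cc == 0L) {
    ms_abort("no discordant pairs: McNemar test undefined", "msvalid_undefined_test")
  }
  chi2 <- (abs(b - cc) - 1)^2 / (b + cc)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       b = b, c = cc)
}
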