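#' Global field power of a single scalp map
#'
#' GFP is the population standard deviation of the instantaneous potentials
#' across electrodes, `sqrt(mean((x - mean(x))^2))`. It is reference-free:
#' adding a constant to every channel leaves it unchanged.
#'
#' @param x numeric vector of per-channel potentials (microvolts).
#' @return a single non-negative number.
#' @seealso [compute_gfp()] for the per-sample GFP trace of a recording.
#' @export
map_gfp <- function(x) {
  x <- x - mean(x)
  sqrt(mean(x * x))
}

#' Spatial correlation between two scalp maps
#'
#' Pearson correlation across channels after removing each map's mean
#' (i.e., after average-referencing both maps). Returns 0 when either map
#' has zero dispersion. Microstate assignment uses the square of this
#' quantity, so map polarity never matters there.
#'
#' @param u,v numeric vectors of equal length.
#' @return correlation in \[-1, 1\].
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) {
    ms_abort("maps must have the same number of channels", "msvalid_invalid_argument")
  }
  u <- u - mean(u)
  v <- v - mean(v)
  du <- sqrt(sum(u * u))
  dv <- sqrt(sum(v * v))
  if (du == 0 || dv == 0) return(0)
  sum(u * v) / (du * dv)
}

make_template_labels <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)] else paste0("T", seq_len(k))
}

#' Construct a microstate template set
#'
#' A template set holds `k` average-referenced, unit-GFP scalp maps (rows of
#' `maps`) with ordered labels. All clustering and backfitting functions in
#' the package produce and consume this class.
#'
#' @param maps numeric matrix, k templates x n_channels.
#' @param labels optional character labels, defaults to A, B, C, ...
#' @param level `"individual"`, `"global"`, or `"truth"`.
#' @param gev proportion of variance explained by the set, if known.
#' @param normalize average-reference and scale each row to unit GFP
#'   (default `TRUE`); rows with zero dispersion are an error.
#' @return an object of class `ms_template_set`.
#' @export
ms_template_set <- function(maps, labels = NULL, level = c("individual", "global", "truth"),
                            gev = NA_real_, normalize = TRUE) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  storage.mode(maps) <- "double"
  k <- nrow(maps)
  if (k < 1L) ms_abort("a template set needs at least one map", "msvalid_invalid_argument")
  if (ncol(maps) < 2L) ms_abort("templates need at least 2 channels", "msvalid_invalid_argument")
  if (normalize) {
    maps <- maps - rowMeans(maps)
    g <- sqrt(rowMeans(maps * maps))
    if (any(g == 0)) ms_abort("template with zero GFP", "msvalid_invalid_argument")
    maps <- maps / g
  }
  labels <- labels %||% make_template_labels(k)
  if (anyDuplicated(labels)) ms_abort("template labels must be unique", "msvalid_invalid_argument")
  structure(
    list(k = k, maps = maps, labels = as.character(labels), level = level,
         gev = gev, n_channels = ncol(maps)),
    class = "ms_template_set"
  )
}

#' @export
print.ms_template_set <- function(x, ...) {
  cat(sprintf("<ms_template_set> %d %s template(s), %d channels",
              x$k, x$level, x$n_channels))
  if (!is.na(x$gev)) cat(sprintf(", GEV %.1f%%", 100 * x$gev))
  cat("\n  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

## rows scaled to unit L2 norm (internal convention for clustering algebra;
## unit L2 and unit GFP differ by the constant sqrt(n_channels))
unit_norm_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  if (any(n == 0)) ms_abort("zero map cannot be normalized", "msvalid_invalid_argument")
  m / n
}

template_maps_unit_norm <- function(templates) {
  m <- if (inherits(templates, "ms_template_set")) templates$maps else as.matrix(templates)
  unit_norm_rows(m - rowMeans(m))
}
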