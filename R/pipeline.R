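#' Configuration for a full two-variant validation study
#'
#' Describes the end-to-end design: a synthetic cohort per rest condition,
#' two denoising variants distinguished by how artifactual components are
#' labeled, microstate extraction options, and statistical settings. The
#' defaults mirror a high-density resting study scaled to 64 channels:
#' 10-minute recordings at 250 Hz, four ground-truth templates with
#' ~90 ms segments, a fixed 50-component decomposition, k searched over
#' 1..12, and 10,000 TANOVA permutations. Tests and examples pass smaller
#' values; every quantity is configurable.
#'
#' @param n_per_condition recordings per condition.
#' @param conditions condition labels (default eyes-open / eyes-closed).
#' @param n_channels,sampling_rate,duration,k_true,mean_segment_ms,noise_sigma,envelope_peak
#'   forwarded to [generator_config()].
#' @param artifacts named artifact specification for [inject_artifacts()].
#' @param filter band-pass/notch settings (list with `low`, `high`,
#'   `notch`), or `NULL` to skip filtering.
#' @param trim noisy-segment trimming settings (list with `amp_threshold`,
#'   `fraction`), or `NULL` to skip.
#' @param n_ics number of independent components (capped at the channel
#'   count at run time).
#' @param ic_label_thresholds named numeric vector of absolute-correlation
#'   thresholds, one per denoising variant (default expert 0.8,
#'   automated 0.7).
#' @param k_min,k_max,n_restarts microstate model-order search settings.
#' @param n_perm TANOVA permutations.
#' @param alpha_threshold reliability threshold reported alongside alphas.
#' @param split_half run the split-half test--retest arm (default `TRUE`).
#' @param seed master seed; every stage derives its own seed from it.
#' @return an object of class `ms_study_config`.
#' @export
study_config <- function(n_per_condition = 10, conditions = c("EO", "EC"),
                         n_channels = 64, sampling_rate = 250, duration = 600,
                         k_true = 4, mean_segment_ms = 90, noise_sigma = 2,
                         envelope_peak = 10,
                         artifacts = list(
                           eyeblink = list(amplitude = 40, rate = 0.2),
                           eye_movement = list(amplitude = 20, rate = 0.1),
                           cardiac = list(amplitude = 15, rate = 1)
                         ),
                         filter = list(low = 0.3, high = 70, notch = 50),
                         trim = list(amp_threshold = 100, fraction = 0.5),
                         n_ics = 50,
                         ic_label_thresholds = c(expert = 0.8, automated = 0.7),
                         k_min = 1, k_max = 12, n_restarts = 50,
                         n_perm = 10000, alpha_threshold = 0.70,
                         split_half = TRUE, seed = 1L) {
  if (length(ic_label_thresholds) != 2L || is.null(names(ic_label_thresholds))) {
    ms_abort("ic_label_thresholds must be two named variants", "msvalid_invalid_argument")
  }
  structure(
    list(n_per_condition = as.integer(n_per_condition), conditions = conditions,
         n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
         duration = duration, k_true = as.integer(k_true),
         mean_segment_ms = mean_segment_ms, noise_sigma = noise_sigma,
         envelope_peak = envelope_peak, artifacts = artifacts,
         filter = filter, trim = trim, n_ics = as.integer(n_ics),
         ic_label_thresholds = ic_label_thresholds,
         k_min = as.integer(k_min), k_max = as.integer(k_max),
         n_restarts = as.integer(n_restarts), n_perm = as.integer(n_perm),
         alpha_threshold = alpha_threshold, split_half = isTRUE(split_half),
         seed = as.integer(seed)),
    class = "ms_study_config"
  )
}

## generate one subject's raw (artifacted) recording plus ground truth
simulate_subject <- function(config, truth_templates, subject_seed) {
  gc <- generator_config(
    n_channels = config$n_channels, sampling_rate = config$sampling_rate,
    duration = config$duration, k_true = config$k_true,
    mean_segment_ms = config$mean_segment_ms, noise_sigma = config$noise_sigma,
    envelope_peak = config$envelope_peak, seed = subject_seed
  )
  labels <- generate_label_sequence(gc)
  clean <- synthesize_eeg(truth_templates, labels, gc)
  art <- inject_artifacts(clean$recording, config$artifacts,
                          seed = ms_seed(subject_seed, 5e5))
  list(recording = art$recording, eeg_truth = clean$ground_truth,
       artifact_truth = art$ground_truth, config = gc)
}

preprocess_recording <- function(rec, config) {
  if (!is.null(config$filter)) {
    rec <- bandpass_notch_filter(rec, low = config$filter$low,
                                 high = config$filter$high,
                                 notch = config$filter$notch)
  }
  if (!is.null(config$trim)) {
    rec <- trim_noisy_segments(rec, amp_threshold = config$trim$amp_threshold,
                               fraction = config$trim$fraction)
  }
  average_reference(rec)
}

## denoise one preprocessed recording for every variant
denoise_variants <- function(rec, artifact_truth, config, subject_seed) {
  n_ics <- min(config$n_ics, n_channels(rec))
  dec <- decompose_ica(rec, n_ics = n_ics, seed = ms_seed(subject_seed, 11),
                       on_nonconvergence = "warn")
  out <- list()
  for (v in names(config$ic_label_thresholds)) {
    labs <- label_ics_from_ground_truth(dec, artifact_truth,
                                        threshold = config$ic_label_thresholds[[v]])
    denoised <- remove_ics_and_reproject(dec, flagged_ics(labs))
    out[[v]] <- list(recording = average_reference(denoised), labels = labs)
  }
  list(variants = out, decomposition = dec)
}

## microstate extraction for one group of denoised recordings: per-subject
## model-order selection, modal k, refit at modal k, group templates,
## backfitting and metrics
extract_group_microstates <- function(recs, config, group_seed) {
  n <- length(recs)
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    trace <- compute_gfp(recs[[i]])
    pk <- find_gfp_peaks(trace)
    maps[[i]] <- peak_maps(recs[[i]], pk)
  }
  k_per_subject <- vapply(seq_len(n), function(i) {
    select_k_kl(maps[[i]], k_min = config$k_min, k_max = config$k_max,
                n_restarts = config$n_restarts, seed = ms_seed(group_seed, i),
                keep_fits = FALSE)$k_opt
  }, integer(1))
  tab <- table(k_per_subject)
  k_group <- as.integer(names(tab)[which.max(tab)])  # modal; ties -> smaller
  sets <- lapply(seq_len(n), function(i) {
    modified_kmeans(maps[[i]], k_group, n_restarts = config$n_restarts,
                    seed = ms_seed(group_seed, 1000 + i))$templates
  })
  global <- build_group_templates(sets, k = k_group)
  segs <- lapply(recs, backfit, templates = global)
  list(k_per_subject = k_per_subject, k = k_group, individual_sets = sets,
       global_templates = global, segmentations = segs,
       gev = vapply(seq_len(n), function(i) explained_variance(global, maps[[i]]),
                    numeric(1)),
       metrics = lapply(segs, microstate_metrics))
}

## permute/flip `other` so its templates correspond to `ref`'s labels
align_template_sets <- function(ref, other) {
  al <- align_to_global(template_maps_unit_norm(other),
                        template_maps_unit_norm(ref))
  ord <- order(al$perm)
  ms_template_set(other$maps[ord, , drop = FALSE] * al$signs[ord],
                  labels = ref$labels, level = other$level, gev = other$gev)
}

## assemble cases x items matrices and run the metric-level statistics
metric_comparison <- function(res_a, res_b, config) {
  k <- res_a$k
  labs <- res_a$global_templates$labels
  out <- list()
  grab <- function(res, metric) {
    t(vapply(res$metrics, function(m) m$summary[[metric]], numeric(k)))
  }
  for (metric in c("duration_ms", "occurrence_hz", "coverage_pct")) {
    Xa <- grab(res_a, metric)
    Xb <- grab(res_b, metric)
    for (j in seq_len(k)) {
      out[[length(out) + 1L]] <- metric_stat_row(metric, labs[j], Xa[, j], Xb[, j])
    }
  }
  preds_a <- lapply(res_a$metrics, function(m) m$predominance)
  preds_b <- lapply(res_b$metrics, function(m) m$predominance)
  if (!any(vapply(c(preds_a, preds_b), is.null, logical(1)))) {
    pairs <- preds_a[[1]]$pair
    for (j in seq_along(pairs)) {
      xa <- vapply(preds_a, function(p) p$predominance_pct[j], numeric(1))
      xb <- vapply(preds_b, function(p) p$predominance_pct[j], numeric(1))
      out[[length(out) + 1L]] <- metric_stat_row("predominance_pct", pairs[j], xa, xb)
    }
  }
  do.call(rbind, out)
}

metric_stat_row <- function(metric, unit, xa, xb) {
  row <- data.frame(metric = metric, template = unit, t = NA_real_,
                    p = NA_real_, alpha = NA_real_, note = "")
  ok <- all(is.finite(xa)) && all(is.finite(xb))
  if (!ok) {
    row$note <- "metric undefined for some recordings"
    return(row)
  }
  tt <- tryCatch(paired_ttest(xa, xb), msvalid_error = function(e) conditionMessage(e))
  if (is.list(tt)) {
    row$t <- tt$t
    row$p <- tt$p
  } else {
    row$note <- tt
    if (all(xa == xb)) row$p <- 1  # identical variants: no difference
  }
  al <- tryCatch(cronbach_alpha(cbind(xa, xb)), msvalid_error = function(e) NULL)
  if (!is.null(al)) row$alpha <- al
  row
}

#' Run the full microstate-based validation study
#'
#' Executes the complete design on a synthetic cohort: generate artifacted
#' resting EEG per condition, preprocess, decompose into independent
#' components, denoise under each labeling variant, extract group-level
#' microstate templates per variant x condition, backfit and compute
#' sequence metrics, and statistically compare the variants
#' (component-label McNemar tests, template global dissimilarity with
#' TANOVA, GEV and metric paired t-tests, Cronbach's alpha, optional
#' split-half test--retest of the second variant). Fully reproducible:
#' the report is a deterministic function of the configuration.
#'
#' @param config an [study_config()].
#' @param out_path optional path; when given the report is also written as
#'   JSON.
#' @return a nested list report of class `ms_study_report`.
#' @export
run_study <- function(config, out_path = NULL) {
  stopifnot(inherits(config, "ms_study_config"))
  variants <- names(config$ic_label_thresholds)
  report <- list(parameters = config_echo(config), conditions = list())
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    truth_templates <- generate_template_set(config$n_channels, config$k_true,
                                             seed = ms_seed(config$seed, ci))
    subjects <- lapply(seq_len(config$n_per_condition), function(j) {
      simulate_subject(config, truth_templates,
                       ms_seed(config$seed, 1000 * ci + j))
    })
    pre <- lapply(subjects, function(s) preprocess_recording(s$recording, config))
    den <- lapply(seq_along(subjects), function(j) {
      denoise_variants(pre[[j]], subjects[[j]]$artifact_truth, config,
                       ms_seed(config$seed, 1000 * ci + j))
    })
    groups <- list()
    for (vi in seq_along(variants)) {
      v <- variants[vi]
      recs <- lapply(den, function(d) d$variants[[v]]$recording)
      ## same extraction seed for both variants: the procedure applied to
      ## the two denoised versions must be identical, so coinciding inputs
      ## yield coinciding microstates
      groups[[v]] <- extract_group_microstates(
        recs, config, ms_seed(config$seed, 1e5 * ci))
    }
    va <- variants[1]
    vb <- variants[2]
    ## make variant-b templates label-comparable with variant a's
    if (groups[[vb]]$k == groups[[va]]$k) {
      aligned_b <- align_template_sets(groups[[va]]$global_templates,
                                       groups[[vb]]$global_templates)
      groups[[vb]]$global_templates <- aligned_b
      groups[[vb]]$segmentations <- lapply(
        lapply(den, function(d) d$variants[[vb]]$recording),
        backfit, templates = aligned_b)
      groups[[vb]]$metrics <- lapply(groups[[vb]]$segmentations, microstate_metrics)
    }
    cond_report <- list(
      condition = cond,
      k_selected = lapply(groups, function(g)
        list(per_subject = g$k_per_subject, modal = g$k)),
      gev = lapply(groups, function(g) g$gev),
      mcnemar = mcnemar_block(den, va, vb),
      templates = template_block(groups, va, vb, config,
                                 ms_seed(config$seed, 7e6 + ci)),
      metric_stats = metric_comparison(groups[[va]], groups[[vb]], config),
      gev_ttest = tryCatch(paired_ttest(groups[[va]]$gev, groups[[vb]]$gev),
                           msvalid_error = function(e) list(note = conditionMessage(e)))
    )
    if (config$split_half) {
      cond_report$split_half <- split_half_block(subjects, config, vb,
                                                 ms_seed(config$seed, 8e6 + ci))
    }
    report$conditions[[cond]] <- cond_report
  }
  report <- structure(report, class = c("ms_study_report", "list"))
  if (!is.null(out_path)) {
    jsonlite::write_json(strip_class(report), out_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

config_echo <- function(config) {
  config[c("n_per_condition", "conditions", "n_channels", "sampling_rate",
           "duration", "k_true", "mean_segment_ms", "noise_sigma",
           "envelope_peak", "n_ics", "k_min", "k_max", "n_restarts",
           "n_perm", "alpha_threshold", "split_half", "seed",
           "ic_label_thresholds", "filter", "trim")]
}

mcnemar_block <- function(den, va, vb) {
  out <- list()
  for (cl in c("eye", "myogenic", "cardiac", "artifact")) {
    la <- concat_ic_labels(lapply(den, function(d) d$variants[[va]]$labels), cl)
    lb <- concat_ic_labels(lapply(den, function(d) d$variants[[vb]]$labels), cl)
    res <- tryCatch(mcnemar_compare(la, lb),
                    msvalid_undefined_test = function(e)
                      list(chi2 = NA, p = NA, note = conditionMessage(e)))
    res$n <- length(la)
    out[[cl]] <- res
  }
  out
}

template_block <- function(groups, va, vb, config, seed) {
  ga <- groups[[va]]$global_templates
  gb <- groups[[vb]]$global_templates
  gd <- matrix(NA_real_, ga$k, gb$k, dimnames = list(ga$labels, gb$labels))
  for (i in seq_len(ga$k)) {
    for (j in seq_len(gb$k)) {
      v <- gb$maps[j, ]
      if (spatial_correlation(ga$maps[i, ], v) < 0) v <- -v
      gd[i, j] <- global_dissimilarity(ga$maps[i, ], v)
    }
  }
  tan <- list()
  if (ga$k == gb$k) {
    ## per-subject clustering orders templates arbitrarily: align every
    ## individual set to the reference global labels before comparing
    ## "templates of the same type"
    sets_a <- lapply(groups[[va]]$individual_sets, align_template_sets, ref = ga)
    sets_b <- lapply(groups[[vb]]$individual_sets, align_template_sets, ref = ga)
    for (lab in ga$labels) {
      tz <- tanova_permutation(sets_a, sets_b,
                               template_label = lab, n_perm = config$n_perm,
                               seed = seed)
      tan[[lab]] <- tz[c("observed_gd", "p_value", "n_permutations",
                         "reported_identical")]
      ## a numerically zero observed GD is identity outright; the inverted
      ## permutation convention cannot flag it because any heterogeneity in
      ## the cohort makes every permuted GD strictly positive
      if (tz$observed_gd < 1e-9) tan[[lab]]$reported_identical <- TRUE
    }
  }
  list(gd_matrix = gd, tanova = tan)
}

## split-half test-retest: the full pipeline (decomposition, labeling,
## denoising, microstate extraction, backfitting, metrics) repeated on each
## half of every raw recording; alpha between the halves' metrics
split_half_block <- function(subjects, config, variant, seed) {
  halves <- lapply(subjects, function(s) split_half(s$recording))
  half_cfg <- config
  half_cfg$n_perm <- 0L
  run_half <- function(which_half, off) {
    recs <- lapply(seq_along(subjects), function(j) {
      rec <- preprocess_recording(halves[[j]][[which_half]], config)
      d <- denoise_variants(rec, subjects[[j]]$artifact_truth, config,
                            ms_seed(seed, off + j))
      d$variants[[variant]]$recording
    })
    extract_group_microstates(recs, config, ms_seed(seed, off + 900))
  }
  h1 <- run_half("first", 0)
  h2 <- run_half("second", 5000)
  if (h1$k != h2$k) {
    return(list(note = sprintf("halves selected different k (%d vs %d); alpha skipped",
                               h1$k, h2$k)))
  }
  h2$global_templates <- align_template_sets(h1$global_templates, h2$global_templates)
  h2$metrics <- lapply(
    seq_along(subjects), function(j) {
      rec <- preprocess_recording(halves[[j]]$second, config)
      d <- denoise_variants(rec, subjects[[j]]$artifact_truth, config,
                            ms_seed(seed, 5000 + j))
      microstate_metrics(backfit(d$variants[[variant]]$recording,
                                 h2$global_templates))
    })
  list(k = h1$k, alphas = metric_comparison(h1, h2, config))
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates a small cohort (at `scale = "tiny"`: 4 recordings x 2
#' conditions, 8 s each, 16 channels), writes each recording as delimited
#' text with a JSON sidecar, the true per-sample label sequence, the
#' ground-truth component label vectors from a small decomposition, and a
#' ground-truth metrics table recomputed by a deliberately plain
#' straight-line run-length pass (independent of [compute_metrics()]).
#' Deterministic: the same seed reproduces every byte.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param scale `"tiny"` (test-sized) or `"default"` (a 10-subject,
#'   64-channel, 60-second cohort).
#' @return invisibly, a list with the written paths and a manifest.
#' @export
make_fixtures <- function(dir, seed = 1L, scale = c("tiny", "default")) {
  scale <- match.arg(scale)
  dims <- if (scale == "tiny") {
    list(n = 4L, n_channels = 16L, duration = 8, n_ics = 8L)
  } else {
    list(n = 10L, n_channels = 64L, duration = 60, n_ics = 20L)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conditions <- c("EO", "EC")
  paths <- character(0)
  metrics_rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    tpl <- generate_template_set(dims$n_channels, 4L, seed = ms_seed(seed, ci))
    for (j in seq_len(dims$n)) {
      sseed <- ms_seed(seed, 100 * ci + j)
      gc <- generator_config(n_channels = dims$n_channels, duration = dims$duration,
                             k_true = 4L, seed = sseed)
      labels <- generate_label_sequence(gc)
      synth <- synthesize_eeg(tpl, labels, gc)
      art <- inject_artifacts(synth$recording,
                              list(eyeblink = list(amplitude = 40, rate = 0.25),
                                   cardiac = list(amplitude = 15, rate = 1)),
                              seed = ms_seed(sseed, 7))
      id <- sprintf("%s_%02d", cond, j)
      rec_path <- file.path(dir, paste0("recording_", id, ".tsv"))
      write_recording(art$recording, rec_path,
                      meta = list(id = id, condition = cond, seed = sseed,
                                  k_true = 4L, synthetic = TRUE))
      lab_path <- file.path(dir, paste0("true_labels_", id, ".txt"))
      writeLines(as.character(labels), lab_path)
      dec <- decompose_ica(average_reference(art$recording), n_ics = dims$n_ics,
                           seed = sseed, on_nonconvergence = "warn")
      ic_labs <- label_ics_from_ground_truth(dec, art$ground_truth)
      ic_path <- file.path(dir, paste0("ic_labels_", id, ".tsv"))
      data.table::fwrite(as.data.frame(ic_labs), ic_path, sep = "\t")
      metrics_rows[[id]] <- cbind(recording = id,
                                  reference_metrics(labels, gc$sampling_rate, 4L))
      paths <- c(paths, rec_path, lab_path, ic_path)
    }
  }
  metrics_path <- file.path(dir, "true_metrics.tsv")
  data.table::fwrite(do.call(rbind, metrics_rows), metrics_path, sep = "\t")
  manifest <- list(seed = as.integer(seed), scale = scale,
                   files = basename(c(paths, metrics_path)))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(c(list(dir = dir, manifest = manifest),
              list(paths = c(paths, metrics_path, manifest_path))))
}

## straight-line reference bookkeeping for duration/occurrence/coverage:
## one explicit pass over the sequence, no rle, no vectorized shortcuts
reference_metrics <- function(labels, sampling_rate, k) {
  run_count <- integer(k)
  run_total <- integer(k)
  sample_count <- integer(k)
  current <- labels[1]
  len <- 0L
  for (s in seq_along(labels)) {
    sample_count[labels[s]] <- sample_count[labels[s]] + 1L
    if (labels[s] == current) {
      len <- len + 1L
    } else {
      run_count[current] <- run_count[current] + 1L
      run_total[current] <- run_total[current] + len
      current <- labels[s]
      len <- 1L
    }
  }
  run_count[current] <- run_count[current] + 1L
  run_total[current] <- run_total[current] + len
  data.frame(
    template = make_template_labels(k),
    duration_ms = run_total / run_count * 1000 / sampling_rate,
    occurrence_hz = run_count / (length(labels) / sampling_rate),
    coverage_pct = 100 * sample_count / length(labels)
  )
}
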