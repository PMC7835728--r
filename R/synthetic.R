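#' Configuration for the surrogate resting-EEG generator
#'
#' The generator emulates the structure microstate analysis presumes: a
#' semi-Markov sequence of `k_true` quasi-stable scalp topographies, each
#' segment lasting on the order of 60--120 ms, multiplied by a per-segment
#' GFP envelope and buried in sensor noise. Segment durations follow a gamma
#' law (shape `segment_shape`, mean `mean_segment_ms`) truncated below at
#' `segment_floor_ms`; successor states are drawn from a row-stochastic
#' transition matrix with zero diagonal (uniform off-diagonal by default).
#'
#' @param n_channels number of electrodes (>= 2).
#' @param sampling_rate sampling frequency, Hz.
#' @param duration recording length, seconds.
#' @param k_true number of ground-truth templates.
#' @param mean_segment_ms mean of the (untruncated) segment-duration law, ms.
#' @param segment_shape gamma shape of the segment-duration law.
#' @param segment_floor_ms lower truncation bound for segment durations, ms.
#' @param transition_matrix `k_true` x `k_true` row-stochastic matrix with
#'   zero diagonal; `NULL` means uniform off-diagonal.
#' @param noise_sigma per-channel Gaussian sensor-noise SD, microvolts.
#' @param envelope_peak peak of the per-segment GFP envelope, microvolts.
#' @param envelope_type `"halfsine"` (rectified sinusoid peaking mid-segment)
#'   or `"constant"`.
#' @param seed integer seed; the same config always yields identical output.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_channels = 64, sampling_rate = 250, duration = 600,
                             k_true = 4, mean_segment_ms = 90, segment_shape = 4,
                             segment_floor_ms = 40, transition_matrix = NULL,
                             noise_sigma = 2, envelope_peak = 10,
                             envelope_type = c("halfsine", "constant"),
                             seed = 1L) {
  envelope_type <- match.arg(envelope_type)
  if (!is_count(n_channels, 2L)) ms_abort("n_channels must be >= 2", "msvalid_invalid_argument")
  if (!is_count(k_true, 1L)) ms_abort("k_true must be >= 1", "msvalid_invalid_argument")
  if (!is_number(mean_segment_ms) || mean_segment_ms <= 0) {
    ms_abort("mean_segment_ms must be positive", "msvalid_invalid_argument")
  }
  if (!is_number(segment_shape) || segment_shape <= 0) {
    ms_abort("segment_shape must be positive", "msvalid_invalid_argument")
  }
  if (!is_number(sampling_rate) || sampling_rate <= 0 ||
      !is_number(duration) || duration <= 0) {
    ms_abort("sampling_rate and duration must be positive", "msvalid_invalid_argument")
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) {
    ms_abort("noise_sigma must be non-negative", "msvalid_invalid_argument")
  }
  if (is.null(transition_matrix)) {
    transition_matrix <- uniform_transition_matrix(k_true)
  }
  if (k_true > 1L) {
    transition_matrix <- as.matrix(transition_matrix)
    if (!all(dim(transition_matrix) == c(k_true, k_true))) {
      ms_abort("transition_matrix must be k_true x k_true", "msvalid_invalid_argument")
    }
    if (any(diag(transition_matrix) != 0)) {
      ms_abort("transition_matrix diagonal must be exactly 0", "msvalid_invalid_argument")
    }
    if (any(abs(rowSums(transition_matrix) - 1) > 1e-9) || any(transition_matrix < 0)) {
      ms_abort("transition_matrix rows must sum to 1 (tolerance 1e-9)", "msvalid_invalid_argument")
    }
  }
  structure(
    list(n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
         duration = duration, k_true = as.integer(k_true),
         mean_segment_ms = mean_segment_ms, segment_shape = segment_shape,
         segment_floor_ms = segment_floor_ms,
         transition_matrix = transition_matrix,
         noise_sigma = noise_sigma, envelope_peak = envelope_peak,
         envelope_type = envelope_type, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
uniform_transition_matrix <- function(k_true) {
  if (k_true == 1L) return(matrix(0, 1, 1))
  tm <- matrix(1 / (k_true - 1), k_true, k_true)
  diag(tm) <- 0
  tm
}

#' Noise level for a target per-sample signal-to-noise ratio
#'
#' SNR here is the ratio of the GFP-envelope peak to the per-channel noise
#' SD, so with the default 10 microvolt envelope peak, SNR 5 corresponds to
#' the default 2 microvolt sensor noise.
#'
#' @param snr target ratio (> 0).
#' @param envelope_peak envelope peak, microvolts.
#' @return noise SD in microvolts.
#' @export
snr_noise_sigma <- function(snr, envelope_peak = 10) {
  if (!is_number(snr) || snr <= 0) ms_abort("snr must be positive", "msvalid_invalid_argument")
  envelope_peak / snr
}

#' Generate a set of ground-truth microstate templates
#'
#' Draws `k` random smooth scalp maps, average-references each and scales it
#' to unit GFP, and regenerates any map whose absolute spatial correlation
#' with an already-accepted map exceeds `max_abs_corr`, so the truth set is
#' well separated (mimicking the four canonical resting maps, which differ
#' in field orientation). Deterministic for a fixed seed.
#'
#' @param n_channels number of electrodes (>= 2, >= k).
#' @param k number of templates.
#' @param seed integer seed.
#' @param max_abs_corr pairwise separation constraint (default 0.5).
#' @param max_attempts regeneration budget per map before failing.
#' @return an `ms_template_set` with `level = "truth"`.
#' @export
generate_template_set <- function(n_channels, k, seed = 1L, max_abs_corr = 0.5,
                                  max_attempts = 500L) {
  if (!is_count(n_channels, 2L)) ms_abort("n_channels must be >= 2", "msvalid_invalid_argument")
  if (!is_count(k, 1L) || k > n_channels) {
    ms_abort("k must satisfy 1 <= k <= n_channels", "msvalid_invalid_argument")
  }
  withr::with_seed(seed, {
    maps <- matrix(0, k, n_channels)
    for (j in seq_len(k)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        m <- random_smooth_map(n_channels)
        if (j == 1L) { ok <- TRUE } else {
          cors <- apply(maps[seq_len(j - 1L), , drop = FALSE], 1,
                        spatial_correlation, v = m)
          ok <- all(abs(cors) <= max_abs_corr)
        }
        if (ok) { maps[j, ] <- m; break }
      }
      if (!ok) {
        ms_abort(sprintf("could not draw template %d with pairwise |correlation| <= %g",
                         j, max_abs_corr), "msvalid_generation_failure")
      }
    }
    ms_template_set(maps, level = "truth")
  })
}

## smooth random topography: white noise circularly averaged over ~n/8
## neighbouring channels to mimic the spatial correlation of scalp fields
random_smooth_map <- function(n_channels) {
  z <- rnorm(n_channels)
  w <- max(1L, round(n_channels / 8))
  if (w > 1L) {
    idx <- outer(seq_len(n_channels), seq_len(w) - 1L, "+")
    idx <- (idx - 1L) %% n_channels + 1L
    z <- rowMeans(matrix(z[idx], n_channels, w))
  }
  z <- z - mean(z)
  g <- sqrt(mean(z * z))
  if (g == 0) z[1] <- 1  # vanishing map is virtually impossible; keep total
  z / max(g, .Machine$double.eps)
}

#' Generate a semi-Markov microstate label sequence
#'
#' Segment durations are drawn from the config's truncated gamma law and
#' converted to samples; each new segment's state is drawn from the
#' transition-matrix row of its predecessor (the zero diagonal forbids
#' self-transitions). The sequence is truncated to exactly
#' `duration * sampling_rate` samples.
#'
#' @param config a [generator_config()].
#' @return integer vector of per-sample template indices in `1..k_true`.
#' @export
generate_label_sequence <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  total <- round(config$duration * config$sampling_rate)
  withr::with_seed(config$seed, {
    lens <- integer(0)
    expected_run <- max(1, config$mean_segment_ms * config$sampling_rate / 1000)
    while (sum(lens) < total) {
      need <- ceiling((total - sum(lens)) / expected_run * 1.5) + 10L
      d_ms <- rgamma(need, shape = config$segment_shape,
                     rate = config$segment_shape / config$mean_segment_ms)
      d_ms <- d_ms[d_ms >= config$segment_floor_ms]  # truncation by rejection
      lens <- c(lens, pmax(1L, as.integer(round(d_ms * config$sampling_rate / 1000))))
    }
    k <- config$k_true
    n_runs <- which(cumsum(lens) >= total)[1]
    lens <- lens[seq_len(n_runs)]
    states <- rep.int(1L, n_runs)
    states[1] <- sample.int(k, 1L)
    if (k > 1L && n_runs > 1L) {
      for (r in 2:n_runs) {
        states[r] <- sample.int(k, 1L, prob = config$transition_matrix[states[r - 1L], ])
      }
    }
    labels <- rep.int(states, lens)
    labels[seq_len(total)]
  })
}

#' Synthesize a multichannel EEG recording from templates and labels
#'
#' Every sample equals its template scaled by the GFP envelope plus
#' independent per-channel Gaussian noise. With `envelope_type = "halfsine"`
#' each segment carries a rectified sinusoid peaking mid-segment at
#' `envelope_peak`; with zero noise the recording's GFP trace equals the
#' envelope exactly, because templates have unit GFP.
#'
#' @param templates an `ms_template_set` (unit-GFP maps).
#' @param labels integer label sequence from [generate_label_sequence()].
#' @param config the [generator_config()] (noise, envelope, seed).
#' @return list with elements `recording` (an [eeg_recording()]) and
#'   `ground_truth` (templates, label sequence, envelope, config).
#' @export
synthesize_eeg <- function(templates, labels, config) {
  stopifnot(inherits(templates, "ms_template_set"), inherits(config, "generator_config"))
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > templates$k)) {
    ms_abort("labels must index the template set", "msvalid_invalid_argument")
  }
  total <- length(labels)
  nch <- templates$n_channels
  env <- segment_envelope(labels, config$envelope_peak, config$envelope_type)
  data <- t(templates$maps)[, labels, drop = FALSE] *
    rep(env, each = nch)
  if (config$noise_sigma > 0) {
    noise <- withr::with_seed(ms_seed(config$seed, 1e6), {
      matrix(rnorm(nch * total, sd = config$noise_sigma), nch, total)
    })
    data <- data + noise
  }
  rec <- eeg_recording(data, config$sampling_rate)
  truth <- structure(
    list(templates = templates, label_sequence = labels, envelope = env,
         config = config),
    class = "ms_ground_truth"
  )
  list(recording = rec, ground_truth = truth)
}

segment_envelope <- function(labels, peak, type) {
  if (type == "constant") return(rep(peak, length(labels)))
  r <- rle(labels)
  unlist(lapply(r$lengths, function(L) peak * sin(pi * (seq_len(L) - 0.5) / L)),
         use.names = FALSE)
}

artifact_classes <- c("eyeblink", "eye_movement", "cardiac", "myogenic")

#' Inject rank-1 physiological artifacts into a recording
#'
#' Each requested artifact class adds one rank-1 component: a fixed synthetic
#' spatial pattern times a class-specific time course scaled to unit RMS and
#' multiplied by `amplitude` (microvolts). The spatial patterns are schematic
#' (no forward head model): eyeblink and eye movement are weighted toward the
#' low-index ("frontal") channels, eye movement with a left/right
#' antisymmetric sign, cardiac is a broad gradient, myogenic is weighted to
#' the edge channels. Time courses: eyeblink = smooth positive pulses at
#' `rate` Hz; eye_movement = ramped bipolar steps at `rate` Hz; cardiac =
#' QRS-like spike train at `rate` Hz (default 1) plus a delayed slow
#' pulse-wave component; myogenic = 20--70 Hz band-limited noise. Event
#' counts equal `round(rate * duration)` exactly.
#'
#' @param rec an [eeg_recording()].
#' @param spec named list keyed by class (`eyeblink`, `eye_movement`,
#'   `cardiac`, `myogenic`), each entry a list with `amplitude` and, where
#'   applicable, `rate`.
#' @param seed integer seed.
#' @return list with `recording` (artifacted copy) and `ground_truth`: the
#'   added source time courses (one row per artifact), spatial patterns,
#'   classes, event times, and amplitudes.
#' @export
inject_artifacts <- function(rec, spec, seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(spec) == 0) {
    return(list(recording = rec, ground_truth = empty_artifact_truth(rec)))
  }
  classes <- names(spec)
  bad <- setdiff(classes, artifact_classes)
  if (length(bad)) {
    ms_abort(paste0("unknown artifact class: ", paste(bad, collapse = ", ")),
             "msvalid_invalid_argument")
  }
  nch <- n_channels(rec)
  total <- n_samples(rec)
  fs <- rec$sampling_rate
  duration <- total / fs
  withr::with_seed(seed, {
    sources <- matrix(0, length(classes), total)
    patterns <- matrix(0, length(classes), nch)
    events <- vector("list", length(classes))
    amps <- numeric(length(classes))
    data <- rec$data
    for (i in seq_along(classes)) {
      cl <- classes[i]
      amp <- spec[[i]]$amplitude %||% 0
      rate <- spec[[i]]$rate %||% default_artifact_rate(cl)
      patterns[i, ] <- artifact_pattern(cl, nch)
      tc_ev <- artifact_time_course(cl, total, fs, rate)
      amps[i] <- amp
      events[[i]] <- tc_ev$events
      if (amp > 0) {
        src <- amp * tc_ev$tc
        sources[i, ] <- src
        data <- data + patterns[i, ] %o% src
      }
    }
    out <- update_recording(rec, data)
    truth <- structure(
      list(sources = sources, patterns = patterns, classes = classes,
           event_times = events, amplitudes = amps, seed = as.integer(seed)),
      class = "ms_artifact_truth"
    )
    list(recording = out, ground_truth = truth)
  })
}

empty_artifact_truth <- function(rec) {
  structure(
    list(sources = matrix(0, 0, n_samples(rec)),
         patterns = matrix(0, 0, n_channels(rec)),
         classes = character(0), event_times = list(), amplitudes = numeric(0),
         seed = NA_integer_),
    class = "ms_artifact_truth"
  )
}

default_artifact_rate <- function(class) {
  switch(class, eyeblink = 0.25, eye_movement = 0.2, cardiac = 1, myogenic = NA_real_)
}

## schematic spatial patterns over an index-ordered montage (unit L2 norm,
## average-referenced); "frontal" = low channel indices by convention
artifact_pattern <- function(class, nch) {
  idx <- seq_len(nch)
  p <- switch(
    class,
    eyeblink = exp(-4 * (idx - 1) / nch),
    eye_movement = exp(-4 * (idx - 1) / nch) * ifelse(idx %% 2 == 0, 1, -1),
    cardiac = seq(-1, 1, length.out = nch) + 0.25 * sin(2 * pi * idx / nch),
    myogenic = exp(-6 * pmin(idx - 1, nch - idx) / nch)
  )
  p <- p - mean(p)
  p / sqrt(sum(p * p))
}

## near-regular event times with +-20% spacing jitter; exactly
## round(rate * duration) events
artifact_event_times <- function(rate, duration) {
  n_ev <- round(rate * duration)
  if (n_ev < 1) return(numeric(0))
  spacing <- duration / n_ev
  centers <- (seq_len(n_ev) - 0.5) * spacing
  pmin(pmax(centers + runif(n_ev, -0.2, 0.2) * spacing, 0), duration)
}

artifact_time_course <- function(class, total, fs, rate) {
  t_s <- (seq_len(total) - 1) / fs
  duration <- total / fs
  tc <- numeric(total)
  events <- numeric(0)
  if (class == "eyeblink") {
    events <- artifact_event_times(rate, duration)
    for (e in events) tc <- tc + exp(-((t_s - e)^2) / (2 * 0.06^2))
  } else if (class == "eye_movement") {
    events <- artifact_event_times(rate, duration)
    lvl <- numeric(total)
    state <- sample(c(-1, 1), 1)
    bounds <- c(0, events, duration)
    for (j in seq_len(length(bounds) - 1)) {
      sel <- t_s >= bounds[j] & t_s < bounds[j + 1]
      lvl[sel] <- state
      state <- -state
    }
    lvl[total] <- lvl[max(1, total - 1)]
    w <- max(1L, round(0.1 * fs))  # 100 ms linear ramp at each step
    tc <- as.numeric(stats::filter(lvl, rep(1 / w, w), sides = 2))
    tc[is.na(tc)] <- lvl[is.na(tc)]
  } else if (class == "cardiac") {
    events <- artifact_event_times(rate, duration)
    w <- 0.012  # QRS half-width, s
    for (e in events) {
      u <- (t_s - e) / w
      sel <- abs(u) < 6
      tc[sel] <- tc[sel] + (1 - u[sel]^2) * exp(-u[sel]^2 / 2)
    }
    pw <- numeric(total)  # slow pulse wave, delayed 0.25 s, 0.35 s wide
    for (e in events) {
      u <- (t_s - e - 0.25) / 0.35
      sel <- u >= 0 & u <= 1
      pw[sel] <- pw[sel] + sin(pi * u[sel])
    }
    tc <- tc + 0.3 * max(abs(tc)) * pw
  } else if (class == "myogenic") {
    z <- rnorm(total)
    hi <- min(70, 0.45 * fs)
    bp <- signal::butter(4, c(20, hi) / (fs / 2), type = "pass")
    tc <- signal::filtfilt(bp, z)
  }
  rms <- sqrt(mean(tc^2))
  if (rms > 0) tc <- tc / rms
  list(tc = tc, events = events)
}
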