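test_that("two-channel template is forced to +-(1, -1) and seeds are reproducible", {
  t1 <- generate_template_set(2, 1, seed = 42)
  m <- t1$maps[1, ]
  expect_equal(mean(m), 0, tolerance = 1e-12)
  expect_equal(map_gfp(m), 1, tolerance = 1e-12)
  expect_equal(abs(m), c(1, 1), tolerance = 1e-12)  # zero-mean unit-GFP in 2 channels
  expect_identical(generate_template_set(64, 4, seed = 7),
                   generate_template_set(64, 4, seed = 7))
})

test_that("generated templates satisfy the pairwise separation constraint", {
  tpl <- generate_template_set(64, 4, seed = 7)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_lte(abs(spatial_correlation(tpl$maps[i, ], tpl$maps[j, ])), 0.5)
    }
  }
  expect_error(generate_template_set(4, 5, seed = 1), class = "msvalid_invalid_argument")
})

test_that("label sequences follow the segment law and transition matrix", {
  cfg1 <- generator_config(n_channels = 8, duration = 10, k_true = 1, seed = 3)
  expect_true(all(generate_label_sequence(cfg1) == 1L))

  cfg <- generator_config(n_channels = 8, duration = 600, k_true = 4, seed = 5)
  lab <- generate_label_sequence(cfg)
  expect_length(lab, 600 * 250)
  r <- rle(lab)
  # truncated-gamma mean in ms, closed form: E[X | X >= a] for Gamma(shape, rate)
  shape <- cfg$segment_shape
  rate <- shape / cfg$mean_segment_ms
  a <- cfg$segment_floor_ms
  trunc_mean <- (shape / rate) *
    stats::pgamma(a, shape + 1, rate, lower.tail = FALSE) /
    stats::pgamma(a, shape, rate, lower.tail = FALSE)
  interior <- r$lengths[-length(r$lengths)]  # last run is truncated by design
  emp_ms <- mean(interior) * 1000 / cfg$sampling_rate
  expect_lt(abs(emp_ms - trunc_mean) / trunc_mean, 0.10)

  # a forbidden transition never occurs
  tm <- matrix(c(0, 0.0, 1.0,
                 0.5, 0, 0.5,
                 0.5, 0.5, 0), 3, 3, byrow = TRUE)
  cfg3 <- generator_config(n_channels = 8, duration = 300, k_true = 3,
                           transition_matrix = tm, seed = 9)
  v <- rle(generate_label_sequence(cfg3))$values
  expect_equal(sum(v[-length(v)] == 1 & v[-1] == 2), 0)
})

test_that("empirical transition frequencies match the generator rows", {
  tm <- matrix(c(0, 0.7, 0.3,
                 0.2, 0, 0.8,
                 0.5, 0.5, 0), 3, 3, byrow = TRUE)
  cfg <- generator_config(n_channels = 8, duration = 900, k_true = 3,
                          transition_matrix = tm, seed = 21)
  v <- rle(generate_label_sequence(cfg))$values
  expect_gt(length(v), 1000)
  from <- v[-length(v)]
  to <- v[-1]
  for (i in 1:3) {
    obs <- table(factor(to[from == i], levels = (1:3)[-i]))
    gof <- suppressWarnings(stats::chisq.test(obs, p = tm[i, -i]))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("noiseless synthesis is exact: GFP equals the envelope, samples equal templates", {
  tpl <- generate_template_set(32, 4, seed = 3)
  cfg <- generator_config(n_channels = 32, duration = 10, noise_sigma = 0, seed = 11)
  lab <- generate_label_sequence(cfg)
  syn <- synthesize_eeg(tpl, lab, cfg)
  trace <- compute_gfp(syn$recording)
  expect_equal(trace$gfp, syn$ground_truth$envelope, tolerance = 1e-12)

  cfg_c <- generator_config(n_channels = 32, duration = 10, noise_sigma = 0,
                            envelope_type = "constant", envelope_peak = 1, seed = 11)
  syn_c <- synthesize_eeg(tpl, lab, cfg_c)
  expect_equal(syn_c$recording$data, t(tpl$maps)[, lab], tolerance = 0,
               ignore_attr = TRUE)

  expect_identical(synthesize_eeg(tpl, lab, cfg)$recording$data,
                   syn$recording$data)
})

test_that("artifact injection is exact bookkeeping: zero amplitude, event counts", {
  tpl <- generate_template_set(16, 3, seed = 2)
  cfg <- generator_config(n_channels = 16, duration = 60, k_true = 3, seed = 8)
  syn <- synthesize_eeg(tpl, generate_label_sequence(cfg), cfg)

  z <- inject_artifacts(syn$recording,
                        list(eyeblink = list(amplitude = 0, rate = 0.25)), seed = 1)
  expect_identical(z$recording$data, syn$recording$data)

  expect_error(
    inject_artifacts(syn$recording, list(linenoise = list(amplitude = 1)), seed = 1),
    class = "msvalid_invalid_argument"
  )

  bl <- inject_artifacts(syn$recording,
                         list(eyeblink = list(amplitude = 30, rate = 0.25)), seed = 4)
  expect_equal(count_source_events(bl$ground_truth$sources[1, ]), 15)  # 0.25 Hz x 60 s

  cfg10 <- generator_config(n_channels = 16, duration = 600, k_true = 3, seed = 8)
  syn10 <- synthesize_eeg(tpl, generate_label_sequence(cfg10), cfg10)
  ca <- inject_artifacts(syn10$recording,
                         list(cardiac = list(amplitude = 20, rate = 1)), seed = 4)
  n_beats <- count_source_events(ca$ground_truth$sources[1, ])
  expect_gte(n_beats, 599)
  expect_lte(n_beats, 601)
})

test_that("template recovery from noisy synthesis reaches |r| >= 0.95 at SNR 5", {
  worst <- 1
  for (s in 1:10) {
    tpl <- generate_template_set(32, 4, seed = 60 + s)
    cfg <- generator_config(n_channels = 32, duration = 30, k_true = 4,
                            noise_sigma = snr_noise_sigma(5), seed = 80 + s)
    syn <- synthesize_eeg(tpl, generate_label_sequence(cfg), cfg)
    pk <- find_gfp_peaks(compute_gfp(syn$recording))
    fit <- modified_kmeans(maps_at_peaks(syn$recording, pk), 4,
                           n_restarts = 20, seed = s)
    cr <- abs(fit$templates$maps %*% t(tpl$maps)) / 32  # unit-GFP rows: cos = <u,v>/N
    worst <- min(worst, mean(apply(cr, 2, max)))
  }
  expect_gte(worst, 0.95)
})
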