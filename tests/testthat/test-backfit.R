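test_that("noiseless synthesis backfits to the exact label sequence", {
  tpl <- generate_template_set(24, 4, seed = 3)
  cfg <- generator_config(n_channels = 24, duration = 10, noise_sigma = 0, seed = 11)
  lab <- generate_label_sequence(cfg)
  syn <- synthesize_eeg(tpl, lab, cfg)
  seg <- backfit(syn$recording, tpl, at = "samples")
  expect_identical(seg$labels, lab)

  # flat-GFP constant envelope: per-sample assignment still exact
  cfg_c <- generator_config(n_channels = 24, duration = 10, noise_sigma = 0,
                            envelope_type = "constant", seed = 11)
  syn_c <- synthesize_eeg(tpl, lab, cfg_c)
  seg_c <- backfit(syn_c$recording, tpl, at = "samples")
  expect_identical(seg_c$labels, lab)

  # peak-mode backfitting recovers the sequence to within boundary samples
  # (nearest-peak interpolation misplaces only segment-edge samples)
  seg_p <- backfit(syn$recording, tpl)
  expect_gte(mean(seg_p$labels == lab), 0.85)
})

test_that("backfitting ignores polarity", {
  tpl <- generate_template_set(12, 4, seed = 5)
  env <- c(1, 3, 1)  # single interior GFP peak
  data <- t(tpl$maps[c(1, 3, 1), ]) * rep(env, each = 12) * -1
  seg <- backfit(eeg_recording(data, 250), tpl)
  expect_identical(seg$peak_labels, 3L)  # template C despite the sign flip
  expect_true(all(seg$labels == 3L))
})

test_that("nearest-peak interpolation splits ties toward the earlier peak", {
  # peaks at 0-based samples {10, 20}: 0-based 0..15 -> first, 16.. -> second
  lab <- msvalid:::fill_nearest_peak(c(11L, 21L), c(1L, 2L), 30L)
  expect_identical(lab, rep(c(1L, 2L), c(16L, 14L)))
})

test_that("duration, occurrence and coverage follow run-length bookkeeping", {
  seg <- segmentation_from_labels(rep(c(1L, 2L, 1L), c(20, 30, 20)), 250, 2)
  met <- compute_metrics(seg)
  expect_equal(met$duration_ms, c(80, 120))
  expect_equal(met$occurrence_hz, c(2 / 0.28, 1 / 0.28))
  expect_equal(met$coverage_pct, c(4000 / 70, 3000 / 70))
  expect_equal(sum(met$coverage_pct), 100, tolerance = 1e-9)

  one <- segmentation_from_labels(rep(1L, 500), 250, 1)
  m1 <- compute_metrics(one)
  expect_equal(m1$coverage_pct, 100)
  expect_equal(m1$occurrence_hz, 1 / 2)
  expect_equal(m1$duration_ms, 2000)
  expect_error(transition_percentages(one), class = "msvalid_undefined_transitions")
})

test_that("transition percentages and directional predominance", {
  seg <- segmentation_from_labels(rep(c(1L, 2L, 1L, 2L), each = 5), 250, 2)
  tp <- transition_percentages(seg)
  expect_equal(tp["A", "B"], 200 / 3)
  expect_equal(tp["B", "A"], 100 / 3)
  expect_equal(sum(tp), 100)
  pred <- directional_predominance(tp)
  expect_equal(nrow(pred), 1)
  expect_equal(pred$predominance_pct, 100 / 3, tolerance = 1e-9)

  # k = 4: 12 ordered transition cells, 6 unordered pairs
  seg4 <- segmentation_from_labels(rep(c(1L, 2L, 3L, 4L, 2L, 1L, 3L), each = 4), 250, 4)
  tp4 <- transition_percentages(seg4)
  expect_equal(dim(tp4), c(4, 4))
  expect_equal(sum(tp4 == 0 & row(tp4) == col(tp4)), 4)  # zero diagonal
  expect_equal(nrow(directional_predominance(tp4)), 6)
  # antisymmetry
  p4 <- directional_predominance(tp4)
  expect_equal(p4$predominance_pct,
               tp4[cbind(match(p4$from, rownames(tp4)), match(p4$to, colnames(tp4)))] -
                 tp4[cbind(match(p4$to, rownames(tp4)), match(p4$from, colnames(tp4)))])

  # balanced alternation: equal counts each way, zero predominance
  segs <- segmentation_from_labels(rep(c(1L, 2L, 1L), c(5, 5, 5)), 250, 2)
  tps <- transition_percentages(segs)
  expect_equal(unname(tps["A", "B"]), 50)
  expect_equal(directional_predominance(tps)$predominance_pct, 0)
})

test_that("relabeling templates permutes the metric vectors identically", {
  set.seed(8)
  lab <- sample(1:3, 400, TRUE)
  seg <- segmentation_from_labels(lab, 250, 3)
  perm <- c(3L, 1L, 2L)  # new index of old template j is perm[j]
  seg_p <- segmentation_from_labels(perm[lab], 250, 3)
  m <- compute_metrics(seg)
  mp <- compute_metrics(seg_p)
  expect_equal(mp$duration_ms[perm], m$duration_ms)
  expect_equal(mp$occurrence_hz[perm], m$occurrence_hz)
  expect_equal(mp$coverage_pct[perm], m$coverage_pct)
  tp <- transition_percentages(seg)
  tpp <- transition_percentages(seg_p)
  expect_equal(tpp[perm, perm], tp, ignore_attr = TRUE)
})

test_that("occurrence x duration equals coverage x 10 for every template", {
  set.seed(9)
  seg <- segmentation_from_labels(rep(sample(1:4, 200, TRUE), times = sample(1:40, 200, TRUE)),
                                  250, 4)
  met <- compute_metrics(seg)
  expect_equal(met$occurrence_hz * met$duration_ms, met$coverage_pct * 10,
               tolerance = 1e-9)
})

test_that("backfitted metrics recover the generator dynamics at SNR 5", {
  for (s in 1:3) {
    tpl <- generate_template_set(32, 4, seed = 700 + s)
    cfg <- generator_config(n_channels = 32, duration = 120, k_true = 4,
                            noise_sigma = snr_noise_sigma(5), seed = 720 + s)
    lab <- generate_label_sequence(cfg)
    syn <- synthesize_eeg(tpl, lab, cfg)
    seg <- backfit(syn$recording, tpl)
    met <- compute_metrics(seg)
    r <- rle(lab)
    true_dur <- vapply(1:4, function(x) mean(r$lengths[r$values == x]) * 1000 / 250,
                       numeric(1))
    expect_lt(max(abs(met$duration_ms - true_dur) / true_dur), 0.15)
  }
})
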