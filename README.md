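# msvalid

Microstate-based validation of EEG artifact removal.

## The problem

ICA-based EEG denoising discards independent components labeled as
artifactual (eyeblinks, eye movements, cardiac and myogenic interference)
and reprojects the rest. The open question for any automated labeling
method is whether the reconstructed EEG still carries the *global brain
dynamics* of the original recording, not just less artifact. `msvalid`
answers that question with microstate analysis: resting EEG is modeled as a
sequence of a few quasi-stable scalp topographies ("microstates",
canonically labeled A--D, each lasting ~60--120 ms). If two denoising
variants yield microstate templates that are topographically
indistinguishable and sequence metrics that are statistically consistent,
the denoising preserved the dynamics.

The package is aimed at EEG methods researchers: it provides every stage as
a tested, seeded, composable function, plus `run_study()` to execute the
full two-variant comparison end to end on ground-truthed synthetic cohorts.

## What is computed

* **GFP and peaks.** Global field power
  `GFP(t) = sqrt(mean_i (v_i(t) - vbar(t))^2)`; its local maxima mark
  moments of maximal topographic stability whose maps feed clustering.
* **Modified k-means.** Polarity-invariant clustering of peak maps:
  assignment by squared spatial correlation, template update as the first
  principal axis of the assigned maps; best of 50 restarts by GEV
  (global explained variance, `sum((gfp_p * r_p)^2) / sum(gfp_p^2)`).
* **Krzanowski--Lai model order.** With dispersion
  `W(k) = sum (1 - r^2) * gfp^2`,
  `DIFF(k) = (k-1)^(2/N) W(k-1) - k^(2/N) W(k)` and
  `KL(k) = |DIFF(k)|/|DIFF(k+1)|`; the optimal k maximizes KL over the
  interior of 1..12.
* **Backfitting and metrics.** Per-template mean duration (ms), occurrence
  (Hz), coverage (%), transition percentages (12 ordered types at k = 4)
  and directional predominance `P(X->Y) - P(Y->X)` (6 pairs at k = 4).
* **Statistics.** Global dissimilarity
  `GD(u, v) = sqrt(mean_i (u_i/GFP_u - v_i/GFP_v)^2)` (0 identical, 2
  polarity-reversed) with a 10,000-permutation TANOVA; Cronbach's alpha;
  paired t-tests; McNemar tests (continuity-corrected) on component label
  vectors; split-half test--retest reliability.
* **Synthetic cohorts.** A semi-Markov surrogate generator (truncated-gamma
  segment durations, per-segment GFP envelopes, Gaussian sensor noise) with
  injectable rank-1 eyeblink / eye-movement / cardiac / myogenic artifacts
  and full ground truth, so every stage is testable without any download.

## Worked example

Generate a one-minute, 64-channel surrogate at SNR 5, recover the model
order, backfit, and compute metrics:

```r
library(msvalid)

templates <- generate_template_set(n_channels = 64, k = 4, seed = 7)
cfg <- generator_config(n_channels = 64, duration = 60, k_true = 4,
                        noise_sigma = snr_noise_sigma(5), seed = 7)
synth <- synthesize_eeg(templates, generate_label_sequence(cfg), cfg)
rec <- average_reference(synth$recording)

peaks <- find_gfp_peaks(compute_gfp(rec))
maps  <- maps_at_peaks(rec, peaks)
sel <- select_k_kl(maps, k_min = 1, k_max = 12, n_restarts = 50, seed = 7)
sel$k_opt
#> [1] 4
fit <- sel$fits[[as.character(sel$k_opt)]]
round(100 * fit$gev, 1)
#> [1] 95.7

seg <- backfit(rec, fit$templates)
compute_metrics(seg)
#>   template duration_ms occurrence_hz coverage_pct
#> 1        A        98.2          2.62         25.7
#> 2        B        99.8          2.43         24.3
#> 3        C        94.1          2.68         25.3
#> 4        D       101.8          2.43         24.8
```

The KL criterion recovers the true four-template structure; the fitted
templates explain 95.7% of the peak-map variance; and the backfitted mean
durations sit near the generator's 90-ms segment mean (the truncated-gamma
law's corrected mean is ~97 ms). The recovered templates match the
ground-truth maps at |spatial correlation| 1.000, and the dissimilarity
anchors hold exactly:

```r
u <- fit$templates$maps[1, ]
global_dissimilarity(u, u)   # identical topographies
#> [1] 0
global_dissimilarity(u, -u)  # polarity-reversed
#> [1] 2
```

For the full two-variant study (preprocess, ICA, per-variant denoising,
group templates, metrics, TANOVA/alpha/t-test/McNemar comparison,
split-half reliability), see `?run_study` and the methods vignette in
`vignettes/microstate-validation.Rmd`.

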