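---
title: "Validating EEG denoising with microstate analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating EEG denoising with microstate analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(msvalid)
```

## The question the package answers

Removing artifacts from EEG (eyeblinks, eye movements, myogenic bursts,
cardiac interference) by discarding independent components always risks
discarding brain signal with them. A denoising method should therefore be
judged not only by how much artifact it removes but by whether it leaves the
*global dynamics* of brain activity intact. Microstate analysis offers a
compact description of that dynamics: resting EEG spends most of its time in
a handful of quasi-stable scalp topographies (canonically A, B, C, D) of
roughly 60--120 ms each, and the temporal statistics of their sequence —
duration, occurrence, coverage, transition percentages, directional
predominance — summarize the dynamics without choosing channels, epochs, or
frequency bands in advance. If two denoising variants (say, expert and
automated component labeling) yield microstate templates that are
topographically indistinguishable and metric profiles that are statistically
consistent, the automated variant preserved what matters.

`msvalid` implements that entire validation design: a ground-truthed
surrogate-EEG generator, the signal-conditioning chain, PCA-whitened
extended Infomax ICA with component removal, polarity-invariant microstate
clustering with Krzanowski--Lai (KL) model-order selection, template
backfitting and sequence metrics, and the statistical comparison layer.
`run_study()` strings the stages together into a reproducible two-variant
study.

## The signal model behind the generator

The generator treats resting EEG as a semi-Markov process over `k_true`
scalp maps:

* **Templates.** `generate_template_set()` draws smooth random
  average-referenced, unit-GFP maps and enforces pairwise absolute spatial
  correlation at or below 0.5, regenerating offenders. Real canonical maps
  differ in field orientation; the separation constraint is the generator's
  stand-in for that. Maps are spatially smoothed white noise — there is no
  forward head model, no volume conduction, and channel indices have only a
  schematic geometry. This is a deliberate non-goal: the pipeline consumes
  topographies as vectors, so their anatomical plausibility is irrelevant to
  what the tests establish.
* **Segment durations.** Gamma with shape 4 and configurable mean (default
  90 ms), truncated below at 40 ms by rejection. The gamma is smooth and
  positive and, at the default mean, concentrates runs in the 60--120 ms
  band reported for resting microstates; the floor removes implausibly short
  segments. Successor states are drawn from a row-stochastic transition
  matrix with zero diagonal (uniform off-diagonal by default).
* **Amplitude.** Each segment carries a rectified-sinusoid GFP envelope
  peaking mid-segment at `envelope_peak` (default 10 µV), because template
  stability is empirically strongest around GFP maxima. Sensor noise is
  i.i.d. Gaussian per channel (default 2 µV). We define the per-sample SNR
  as envelope peak over noise SD, so the defaults sit at SNR 5
  (`snr_noise_sigma(5)` returns 2).
* **Artifacts.** `inject_artifacts()` adds one rank-1 component per class —
  a fixed synthetic spatial pattern times a class-specific time course
  (smooth positive pulses for blinks, ramped bipolar steps for eye
  movements, a QRS-like spike train plus delayed pulse wave for cardiac,
  20--70 Hz band-limited noise for myogenic). Rank-1 sources map one-to-one
  onto independent components, which makes component-label validation
  well-posed: the ground-truth labeler flags a component artifactual when
  its source time course correlates with an injected source at |r| > 0.8.

What passing tests on this surrogate do *not* show: robustness to
non-stationary artifact topographies (real blinks are not exactly rank-1),
to correlated sensor noise, or to deviations from the semi-Markov segment
model. They do show that every algorithmic stage does exactly what its
contract says when the data satisfy the model it assumes.

## Preprocessing choices

The band-pass is a 4th-order Butterworth (0.3--70 Hz) plus a second-order
notch biquad (50 Hz, quality factor 30), both applied forward--backward.
Zero-phase filtering matters here: a causal filter would delay GFP peaks and
shift every microstate boundary. "Excessive noise" is operationalized in two
explicit, seedable rules that replace visual inspection: a channel is
dropped when the robust z-score (median/MAD across channels) of its MAD
amplitude exceeds 5 or its variance is zero, and a 1-s window is trimmed
when the proportion of channels whose peak amplitude exceeds 100 µV is
strictly greater than one half. Explicit masks are always accepted as the
faithful path for recordings that were screened by hand. All maps are
common-average referenced before GFP, correlation, and dissimilarity
computations; the dissimilarity formula presumes zero-mean maps, and GFP is
reference-free, so this choice is conservative. The reference montage used
before decomposition in comparable hardware setups varies; common average is
this package's single documented choice, not a claim about any particular
laboratory's practice.

## Decomposition and denoising

`decompose_ica()` centers the data, prewhitens by PCA to `n_ics`
dimensions, and runs extended Infomax: full-batch natural-gradient ascent
with the per-component super-/sub-Gaussian switch estimated from the sample
kurtosis each iteration. Full-batch updates with a fixed learning rate
(0.05, halved only on divergence) make the fit deterministic — important
because the whole study must be a pure function of its configuration.
Convergence is declared when the Frobenius norm of the natural gradient per
component falls below `tol` (default 1e-5); at the Infomax fixed point this
gradient vanishes identically. Whatever the rotation does, the
reconstruction contract holds by construction:
`mixing %*% sources + center` equals the rank-`n_ics` PCA projection of the
input, and `remove_ics_and_reproject()` is linear in the retained set.

The fixed 50-component decomposition is the conventional choice for
montages of 64 channels and above, keeping component counts comparable
across recordings whose retained channel counts differ; `n_ics` larger than
the retained channel count is refused rather than silently truncated.
Classifier internals (feature-based artifact classification) are out of
scope: the pipeline consumes component label vectors from any source, with
ground-truth correlation labeling standing in for automated classifiers on
surrogate data and user-supplied files standing in for expert labels.

## Microstate core: numerical choices

* **GFP** uses the population (1/N) form, and **peaks** are strict interior
  local maxima with exact-tie plateaus counted once at their first sample.
  Peaks are never detected across trim boundaries because trimming
  concatenates segments before peak detection; with 1-s windows removed the
  junctions are rare relative to peak counts.
* **Modified k-means** assigns by squared spatial correlation (polarity is
  ignored — spontaneous-EEG practice, even though descriptions of the
  canonical maps sometimes speak of fixed polarities; the package follows
  the polarity-blind convention throughout and documents rather than
  resolves the discrepancy) and updates each template as the first
  principal axis of its assigned maps, the sign-invariant analogue of a
  mean. Both steps are monotone in GEV, so iteration converges; stopping is
  at an assignment fixpoint or relative GEV change below 1e-7 (cap 500).
  The best of `n_restarts` (default 50) random initializations by GEV is
  kept; ties keep the earliest restart, and tied correlations assign to the
  lowest template index, so results are reproducible bit for bit. Empty
  clusters are reseeded from the worst-fitted map and counted.
* **Dispersion and KL.** The dispersion is
  `W(k) = sum over maps of (1 - r^2) * GFP^2`, which equals total squared
  GFP times (1 - GEV) — weighting by squared GFP makes it reference- and
  scale-consistent. `DIFF(k) = (k-1)^(2/N) W(k-1) - k^(2/N) W(k)` and
  `KL(k) = |DIFF(k)| / |DIFF(k+1)|`; the optimum maximizes KL over the
  interior of the search range (KL is undefined at both ends), ties toward
  the smaller k, and a zero denominator with positive numerator counts as
  infinite (the noiseless case, where W collapses to zero at the true k).
  Each k is additionally warm-started from the previous optimum plus its
  worst-fitted map, which guarantees the dispersion curve is monotone
  non-increasing — without the warm start, restart luck could violate it.
* **Group templates** are built by an explicit alignment-average fixpoint:
  repeatedly find, per individual set, the label permutation and signs
  maximizing total absolute correlation to the current global set
  (exhaustive over permutations up to k = 6, greedy above — at k = 12 the
  exhaustive search would be 479 million permutations per set per
  iteration), then recompute each global template as the principal axis of
  its aligned members. The aggregation rule cited in the literature is
  described only by reference; this fixpoint is the package's explicit
  choice. Output templates are ordered by total squared member correlation
  and labeled A, B, C, ...

## Backfitting and metrics

Backfitting assigns template labels at GFP peaks and fills the remaining
samples from the temporally nearest peak, ties toward the earlier peak —
the assignment is defined at peaks only, and nearest-peak filling is the
package's interpolation choice (an alternative per-sample mode,
`at = "samples"`, exists for sensitivity analyses and for flat-GFP edge
cases such as constant-envelope surrogates, where peak detection is
undefined). No temporal smoothing or minimum-duration rejection is applied
by default: metrics are computed on the literal label sequence, and
boundary (truncated) runs are included in duration and occurrence.
Transitions are counted between consecutive distinct runs — per-sample
counting would be dominated by the self-transitions that the k(k-1)
transition enumeration excludes by construction. Duration, occurrence and
coverage are tied by the exact identity
`occurrence x duration = coverage x 10` (ms·Hz against %), which the test
suite asserts.

## Statistical layer

Global dissimilarity `GD = sqrt(mean((u/GFP_u - v/GFP_v)^2))` is 0 for
identical and 2 for polarity-reversed topographies. The TANOVA permutation
test aggregates each group's same-label individual templates by the
sign-invariant principal axis, sign-aligns the two aggregates, and compares
the observed GD against re-aggregations under `n_perm` random reassignments
of individuals to pseudo-groups of the original sizes (both groups' sets
are label-aligned to the reference global set first, because per-subject
clustering orders templates arbitrarily). The p-value counts permuted
values *strictly* greater than the observed one, exactly as worded in the
convention it implements; an inclusive variant is available
(`strictly_greater = FALSE`). Two peculiarities are deliberate and flagged
in the output rather than silently corrected. First, the convention is an
inverted null — p below 0.01 is *reported as* "statistically identical" —
and the report text says so. Second, when the observed GD is numerically
zero the permutation machinery cannot flag identity (any cohort
heterogeneity makes every permuted GD strictly positive), so the study
report short-circuits: zero dissimilarity is identity by definition.
Whether permutations should shuffle whole template sets or single-label
templates is underdetermined in the convention's usual description;
single-label shuffling with re-aggregation is implemented, matching the
wording "shuffling individual microstate templates between groups". What
is recomputed per permutation is the group-level aggregate GD (standard
TANOVA), not pairwise individual GDs. Ties at the observed value are made
reproducible by sorting each drawn subset, so permuted splits that merely
relabel the same partition reproduce the same aggregate bit for bit. No
multiple-comparison correction is applied across the GD matrix; a note to
that effect accompanies the output.

Cronbach's alpha uses the standard variance decomposition with sample
variances; the paired t-test delegates to `stats::t.test` behind an
explicit zero-variance guard, because a degenerate comparison should be a
typed error, not a NaN. Split-half reliability re-runs the *entire*
pipeline (decomposition, labeling, denoising, extraction, backfitting,
metrics) independently on the first and second halves of each recording
before computing alphas between halves.

## Problem sizes and defaults used in the shipped checks

The packaged tests and the acceptance script choose sizes that exercise
every claim at full fidelity while remaining desk-scale: model-order
recovery runs ten 60-s, 64-channel, 250-Hz surrogates at SNR 5 with the
full k = 1..12 scan and 50 restarts; temporal-parameter recovery uses ten
10-minute surrogates, the cohort duration the generator defaults to;
clustering optimality is checked against exhaustive partition enumeration
on instances of at most 12 maps; the permutation-null calibration uses 200
replicate tests of 500 permutations on 12-member cohorts; and the
end-to-end study tests run a 3-subject, 16-channel, 8-s miniature of the
full design. The full-scale defaults of `study_config()` (10 subjects per
condition, 10-minute recordings, 50 components, 10,000 permutations) are
the intended scientific operating point.

## Known limitations

* Surrogate topographies are schematic; nothing here validates spatial
  plausibility against real electrode geometry.
* The ICA contract is judged by reconstruction and source independence on
  data that satisfy the linear mixing model; real EEG violates it in ways
  the surrogate does not emulate.
* KL model-order selection inherits the elbow heuristic's known fragility
  when clusters are weakly separated; the shipped recovery checks quantify
  it only under the generator's conditions.
* The inverted-null identity convention is reported literally; users who
  want a conventional equivalence test should treat the GD magnitudes and
  their permutation quantiles, both present in the output, as the primary
  evidence.
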