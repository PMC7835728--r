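Package: msvalid
Title: Microstate-Based Validation of EEG Artifact Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing whether an EEG denoising step preserves
    global brain dynamics. Generates ground-truthed surrogate resting EEG
    with quasi-stable microstate structure and injectable physiological
    artifacts (eyeblink, eye movement, cardiac, myogenic); preprocesses
    recordings (zero-phase Butterworth band-pass, power-line notch,
    bad-channel masking, noisy-segment trimming, common average reference);
    decomposes signals with PCA-whitened extended Infomax independent
    component analysis and reconstructs denoised EEG after removal of
    labeled artifactual components; extracts microstate templates with a
    polarity-invariant modified k-means and Krzanowski-Lai model-order
    selection; backfits templates to obtain duration, occurrence, coverage,
    transition-percentage and directional-predominance metrics; and
    statistically compares denoising variants via global dissimilarity with
    permutation (TANOVA) testing, Cronbach's alpha, paired t-tests, McNemar
    tests on component labels, and split-half test-retest reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
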