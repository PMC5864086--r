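Package: speechMI
Title: Stimulus-Specific Speech Tracking and Cross-Frequency Coupling via
    Gaussian-Copula Mutual Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for perceptually relevant speech tracking in
    source-level neural recordings. Derives stimulus-specific frequency
    bands (phrase, word, syllable, phoneme timescales) from corpus timing
    annotations, extracts wideband cochlear-filterbank speech envelopes,
    and quantifies speech-to-brain tracking as lag-summed Gaussian-copula
    mutual information between band-limited envelope and neural analytic
    signals. Includes trial-shuffling and time-reversal surrogate nulls,
    equalised correct-versus-incorrect condition contrasts, delta-phase to
    beta-power phase-amplitude coupling with control band pairs,
    cluster-based permutation statistics with FDR-corrected post-hoc tests,
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
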