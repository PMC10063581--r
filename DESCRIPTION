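Package: bwsportrait
Title: Best-Worst-Scaling Annotation, Tournament Scoring and Acoustic
    Portraits of Sound Concepts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A simulation and analysis pipeline for studying how listeners
    map metaphorical sound concepts (brightness, warmth, roundness,
    roughness) onto acoustic attributes. Generates a loudness-equalized
    synthetic instrument-like sound corpus, builds randomized Best-Worst
    Scaling trial designs under a pair-uniqueness constraint, simulates
    rater populations with latent utility functions, scores stimuli with a
    Rescorla-Wagner tournament algorithm, computes inter- and
    intra-participant consistency statistics, extracts timbre descriptors
    (spectral summaries, F0, harmonic-to-noise ratio, attack features,
    modulation-power-spectrum roughness), and fits cross-validated
    gradient-boosted regressions with Shapley-value attributions to produce
    per-concept "acoustic portraits".
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    xgboost,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
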