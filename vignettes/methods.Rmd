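---
title: "Methods: simulated Best-Worst-Scaling annotation and acoustic portraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated Best-Worst-Scaling annotation and acoustic portraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bwsportrait)
```

This vignette documents the models, parameter choices and numerical
decisions behind the package. Everything here describes what the code
does and why; all empirical statements are the ones the test suite and
`scripts/acceptance.R` themselves compute.

## The annotation model

Best-Worst Scaling presents k-tuples of sounds (k = 4 throughout) and
asks for the best and worst exemplar of a concept. Treating each trial
as a mini-tournament, a choice of best b and worst w on a tuple T
determines the relations b > x for every other member and y > w for
every non-worst member: 2k − 3 duels, and nothing about the middle
pair(s). `deduce_duels()` implements exactly this determined set; the
test suite cross-checks it for k = 2..6 against a brute-force oracle
that enumerates all total orders consistent with the choice.

### Trial designs

`build_design()` partitions the corpus into ⌈N/k⌉ trials per rater so
that every stimulus is judged exactly once per plan, and — within the
configurable uniqueness scope, by default the group × concept pool on
which scores are computed — no unordered pair of stimuli co-occurs
twice across non-retest trials. Pair uniqueness maximizes the distinct
relations the tournament can propagate. Retest trials repeat a source
trial's stimuli in fresh order; they are exempt from the constraint
(a repeat necessarily reuses pairs) and are placed uniformly at random
in the second half of the sequence, always after their source, so test
and retest are separated in time.

The constraint solver is a randomized greedy constructor with
depth-first backtracking: trials are grown from a random anchor with
randomized compatible-partner sets, a dead-end budget (1000) triggers a
plan restart with a fresh derived sub-seed, and repeated failure
restarts the whole construction (up to 50 times) before failing with
the remaining pair budget. This is complete enough to find maximally
dense solutions at desk scale — at N = 16, k = 4 and five raters the
only solution is a resolvable 2-(16,4,1) design (the affine plane of
order 4), which the solver finds in milliseconds — and comfortably
handles the sparse study-scale instances (N = 100 with eight pooled
plans uses 24% of available pairs; N = 520 with one plan uses 0.6%).
Known limitation: for large N *near* the pair-exhaustion bound (e.g.
N = 28 with eight pooled plans, 89% pair usage), bounded randomized
search can fail even though a design may exist; such instances are
reported as infeasible rather than searched exhaustively.

When k does not divide N, the final trial holds the N mod k remainder
(at least 2; a remainder of 1 is rejected since a singleton trial
cannot produce a judgment).

### Simulated raters

Raters follow a Thurstonian choice model: a rater's utility for a
stimulus under a concept is the dot product of a concept-specific
weight vector with the stimulus's z-scored latent attributes, plus
independent Gaussian noise drawn per stimulus per presentation
(`noise_sd`, in utility units). Best is the noisy argmax, worst the
noisy argmin, ties broken toward the lexicographically lowest id. A
logistic (Gumbel) noise alternative was considered; Gaussian was chosen
because it makes "moderate noise" directly interpretable as a fraction
of the utility SD (the latent attributes are z-scored, so a unit weight
vector has utility SD ≈ 1).

The latent attributes are the ground-truth synthesis parameters (log
F0, spectral slope, noise level, AM depth, attack time) plus the
analytically derived spectral centroid of the harmonic stack — not the
extracted features. This separation is deliberate: it lets
parameter-recovery tests compare scores against a known order without
circularity through the feature extractor.

Group presets (`default_group_presets()`) give the three simulated
populations qualitatively distinct weight profiles (e.g. a technical
population ties brightness to spectral centroid; a naive one to pitch
height and absence of noise) and increasing judgment noise (0.5, 1, 2).
They are illustrative defaults for demonstrating the pipeline, not
estimates of any real population.

## Tournament scoring

Scores are learned by a Rescorla-Wagner value-updating rule: for each
duel, the predicted win probability is the logistic of the score
difference, p̂ = σ(s_w − s_l), and both scores move by the learning
rate times the prediction error δ = 1 − p̂ (winner up, loser down).
Defaults: α = 0.05, 50 epochs over the duel list, initial score 0,
duel order reshuffled each epoch from the config seed. The published
description of this scoring family does not pin down the update
constants; these values are this package's own declared choice, exposed
in `rw_config()`, chosen so that single updates are small (bounded by
α) and epoch-level shuffling averages out order effects.

Properties the implementation guarantees and the tests assert:

* **Zero-sum / mean conservation**: the symmetric update keeps the mean
  score at the initial value (within 1e-9).
* **Translation invariance**: only score differences enter the
  logistic, so shifting the initial score shifts all outputs by the
  same constant.
* **Order effects**: sequential (online) updates leave an O(α²)
  asymmetry between stimuli with identical duel patterns processed in
  different positions (~5e-5 at α = 0.05). Exact symmetry holds for
  the average over presentation orders; per-epoch shuffling serves the
  same purpose in practice.
* **Recovery**: on a complete round-robin of consistent duels the
  recovered order is exact. For partial tournaments the data determine
  only the transitive closure of the observed duels; utility-adjacent
  stimuli that never co-occur with one as best or worst are genuinely
  undetermined, and no scorer can order them from the data. The
  acceptance suite therefore checks exact agreement with every
  *determined* pair (computed by an independent transitive-closure
  oracle, scorer run to convergence at 400 epochs), and rank
  correlation ≥ 0.9 against the latent utilities at N = 100 under
  moderate noise with the default configuration.

The classical count-based BWS score, (wins − losses)/(wins + losses),
is implemented as an independent baseline; on balanced noiseless
designs the two scorers agree at Spearman ≥ 0.95.

## Consistency measures

**Compliance** is the proportion of a rater's deduced duels whose
winner has the strictly higher group score. Duels whose two group
scores are exactly equal are dropped from the denominator — a tie
carries no information about agreement, and raw RW scores make exact
ties vanishingly rare. Retest trials are excluded from the duel set by
default (they re-measure the same pairs). The group score table
includes the rater's own judgments, mirroring how a group mean is
usually computed; a leave-one-out variant would shift all values
slightly but is not needed for the package's calibration claims.

The 50% null for a uniformly random responder
(`random_responder_compliance()`) is exact only when the reference
ranking is independent of the responder. Including the responder's own
duels in the scoring pool biases the null upward, because the
iterative scorer partially absorbs the responder's choices into the
reference ranking (the effect is large: roughly +10 percentage points
at 1-in-8 raters with 50 epochs of replay). The calibration therefore
scores the group from the seven informative raters only; self-inclusion
is available behind `include_random_in_scores = TRUE`.

**Retest agreement** compares a trial with its repeat: comparable duels
are the unordered pairs determined in *both* passes, agreement the
fraction with the same winner. The alternative — counting undetermined
pairs as disagreements — would conflate inconsistency with the
structural indeterminacy of middle pairs.

The nonparametric battery (`kruskal_wallis()`, `mann_whitney_u()`,
`friedman_rank_test()`, `wilcoxon_signed_rank()`, `bonferroni_adjust()`)
wraps the base R implementations (tie-corrected statistics; exact p
for small tie-free samples — n ≤ 12 observations for the rank-sum
tests — and normal/χ² approximations with continuity correction
otherwise). The tests validate them against exhaustive enumeration:
all C(8,4) labelings for Mann-Whitney, all 2⁶ sign patterns for
Wilcoxon, all 1680 group assignments for Kruskal-Wallis at 3 × 3, all
6³ within-row permutations for Friedman, plus a 2000-replicate type-I
calibration of Kruskal-Wallis at α = 0.05. Note the χ² approximations
are coarse against the very discrete exact distributions at 3 × 3;
the statistics themselves match exactly.

## The synthetic corpus

Additive synthesis: harmonics at integer multiples of F0 with
amplitudes following a spectral slope (dB/octave), plus white noise at
a prescribed noise-to-harmonic RMS ratio, sinusoidal amplitude
modulation, and an envelope of linear attack followed by a sustained
plateau (blown/bowed families) or an exponential decay to −40 dB
(plucked/struck: harp, guitar, keyboards). Pitches are restricted to Cs
of octaves 1-8 in twelve-tone equal temperament (A4 = 440 Hz).
Family-conditioned parameter priors (brass: shallow slopes, fast
attacks; strings: optionally noisy like sul ponticello; accordion:
strong AM like a bellows shake) are this package's own illustrative
distributions — ground truth for recovery tests, not estimates of any
recorded-sample library.

Loudness equalization implements ITU-R BS.1770 as used by EBU R-128:
two-stage K-weighting (high-shelf + high-pass biquads, coefficients
re-derived for arbitrary sample rates via the bilinear transform),
400 ms blocks with 75% overlap, −70 LUFS absolute and −10 LU relative
gates. The target level is −23 LUFS (the R-128 reference; the level
itself is a free choice since only relative loudness matters here).
The implementation reproduces the published −3.01 LUFS value for a
full-scale 997 Hz sine within 0.1 LU. If per-stimulus gains would clip,
the whole corpus is scaled down uniformly (preserving relative
loudness) with a warning. Digital silence returns −∞ and is a
normalization error listing the offending ids.

What the generator does *not* emulate: inharmonicity, transients and
multiphonics beyond a noise/AM proxy, room acoustics, stereo imaging,
or the spectral envelopes of real instruments. Passing tests
demonstrate that the pipeline recovers structure that is present in the
signal by construction; they say nothing about recorded audio beyond
that.

## Feature extraction

All descriptors operate on mono waveforms at the corpus sample rate:

* **Spectral frames**: Hann-windowed STFT, 25 ms windows, 5 ms hop.
  Frames more than 60 dB below the loudest frame are excluded from
  summaries. Per frame: centroid (magnitude-weighted mean frequency),
  bandwidth (weighted SD), crest (max/mean magnitude), flatness
  (geometric/arithmetic mean of power, ε-guarded so pure tones do not
  hit log 0), and the 85%-energy rolloff. Summaries are median and IQR.
* **F0 and HNR**: frame-wise FFT autocorrelation with the zero-padding
  taper undone (the biased estimate decays as (win − lag)/win, which
  would both depress HNR and drag long-lag peaks down); lags are capped
  at 0.75 × window for stability. Peak picking takes the smallest lag
  among local maxima within 90% of the global maximum — the standard
  guard against octave errors — refined by parabolic interpolation.
  Search range 25-4500 Hz (C1-C8 with margin), window ≥ 2/fmin.
  Frames with peak correlation below 0.5 are unvoiced; F0 is the median
  over voiced frames, NA if none (imputed at the corpus minimum in the
  feature matrix so model inputs stay complete). HNR = 10·log10(r/(1−r))
  with r clamped to [1e-6, 1 − 1e-6] (so ±60 dB bounds), median over
  frames.
* **Attack**: smoothed 10 ms RMS envelope; attack time from the 10% to
  the 90% crossing of the maximum (floored at one frame for sub-frame
  attacks); slope = 0.8·max/(t90 − t10); temporal centroid is the
  energy-weighted mean time. Flat envelopes are flagged rather than an
  error.
* **MPS roughness**: log-magnitude spectrogram (25 ms windows), mean
  removed, 2-D FFT, power averaged over the 30-150 Hz band on both
  signs of the temporal-modulation axis and over all
  spectral-modulation rows. The hop is 2.5 ms so the temporal-modulation
  Nyquist (200 Hz) covers the whole band; a larger hop triggers a
  warning. Silence returns 0 by definition.
* **Meta features**: one-hot columns per family and technique;
  single-level categories are kept but flagged zero-variance.
* **Pruning**: greedy multicollinearity removal — while any acoustic
  pair exceeds |r| > 0.9, drop the member with the larger mean |r| to
  all other acoustic columns; meta columns are exempt; every removal is
  logged with its trigger. The full superset of descriptors is
  extracted and pruning reduces it, rather than hard-coding a final
  feature list.

## Portrait models

`fit_cv_gbt()` fits gradient-boosted regression trees (xgboost,
single-threaded for reproducibility) in a shuffled 5-fold
cross-validation; R² is computed on each held-out fold. Default
hyperparameters — 300 trees, depth 4, learning rate 0.05, subsample
0.8 — are a deliberately modest capacity for a few hundred rows and are
exposed in the call; no per-concept tuning is done. Shapley
attributions use exact tree-path-dependent TreeSHAP
(`predcontrib = TRUE`), computed for each stimulus on the fold where it
was held out, so every stimulus is attributed exactly once by a model
that never saw it. Local accuracy (base value + contributions =
prediction) holds to single precision — xgboost evaluates trees in
float32, so with 300 trees the identity is exact to ~1e-6 on
unit-scale targets. The portrait is the top-k (default 5) features by
mean |contribution|, each with the sign of the Pearson correlation
between feature value and contribution as a scalar direction summary.

## Dependent correlations

`steiger_compare()` implements both dependent-correlation variants via
Fisher z with Steiger's pooled covariance: the overlapping case (two
correlations sharing a variable; requires the one cross-correlation)
and the non-overlapping case (four distinct variables; requires four
cross-correlations, Pearson-Filon covariance). With all
cross-correlations zero the non-overlapping statistic reduces exactly
to the classical two-sample Fisher z at equal n, which the tests
assert, alongside a 2000-replicate type-I calibration under the null.
Which variant applies depends on the comparison: correlations of two
concept pairs sharing a concept within one group are overlapping;
comparisons across groups (different score variables on the same
sounds) are non-overlapping. The caller chooses; no silent default.
Results print with n − 1 in the df position, the usual reporting style,
while the SE uses n internally.

## Problem sizes and reproducibility

The default `study_config()` describes the package's desk-scale
reference study: 100 stimuli (family counts scaled proportionally from
the 520-sound reference composition), 3 groups × 8 raters × 4 concepts,
3 retest trials per 25-trial plan, 22.05 kHz audio of 0.5-2 s. These
sizes keep a full `run_study()` around half a minute while leaving every
stage statistically meaningful; the corpus generator accepts the
full-scale composition (520 sounds, durations to 15 s, 44.1 kHz)
unchanged. All randomness flows from one master seed through
`derive_seed(master, stage, ...)` (a 31-bit string hash), so any stage
can be re-run in isolation and two runs of one config are identical —
the acceptance suite asserts byte-identical summaries and score tables.

## Known limitations

* The synthetic corpus is a controlled idealization; portraits learned
  on it reflect the generator's parameter priors, not real orchestral
  timbre.
* The design solver is randomized and bounded; pair-uniqueness
  instances near the exhaustion bound at large N may be reported
  infeasible (see above).
* Partial tournaments leave some stimulus pairs undetermined; score
  differences between such pairs are extrapolation by the scorer, not
  measurement.
* Exact p-values for the rank tests are only used for small tie-free
  samples; elsewhere the usual approximations apply.
* The Rescorla-Wagner constants are declared package defaults, not a
  reconstruction of any particular published scorer's internals.
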