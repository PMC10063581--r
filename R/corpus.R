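#' Sound concepts and instrument families
#'
#' The four metaphorical sound concepts under study and the seven
#' instrument families of the emulated orchestral corpus.
#'
#' @export
bws_concepts <- c("brightness", "warmth", "roundness", "roughness")

#' @rdname bws_concepts
#' @export
bws_families <- c("strings", "woodwinds", "brass", "keyboards",
                  "harp", "guitar", "accordion")

#' Family counts of the emulated orchestral corpus
#'
#' Default per-family stimulus counts matching the composition of the
#' 520-sound orchestral corpus the package emulates.
#'
#' @export
bws_family_counts <- c(strings = 140, woodwinds = 172, brass = 102,
                       keyboards = 67, harp = 16, guitar = 9, accordion = 14)

# Families whose envelope decays after the attack (plucked/struck) versus
# families that sustain a plateau (blown/bowed).
.decaying_families <- c("harp", "guitar", "keyboards")

#' Scale the reference family composition to a target corpus size
#'
#' Proportionally rescales [bws_family_counts] so the counts sum exactly
#' to `n_stimuli`, keeping every family represented.
#'
#' @param n_stimuli target corpus size (>= number of families).
#' @return named integer vector of per-family counts summing to
#'   `n_stimuli`.
#' @export
scaled_family_counts <- function(n_stimuli) {
  if (n_stimuli < length(bws_family_counts)) {
    stop_bws("n_stimuli must be at least %d (one per family)",
             length(bws_family_counts), class = "bws_manifest_error")
  }
  counts <- round(bws_family_counts / sum(bws_family_counts) * n_stimuli)
  counts[counts == 0] <- 1
  # absorb the rounding residue in the largest family
  counts[which.max(counts)] <- counts[which.max(counts)] +
    (n_stimuli - sum(counts))
  counts
}

#' Convert a pitch name to frequency
#'
#' Twelve-tone equal-temperament conversion with a configurable reference
#' pitch. Octaves follow scientific pitch notation, so the corpus pitch grid
#' runs from C1 (32.70 Hz) to C8 (4186.01 Hz) at A4 = 440 Hz.
#'
#' @param note pitch name: letter A-G, optional `#` or `b`, octave digit,
#'   e.g. `"C4"`, `"F#3"`, `"Bb2"`.
#' @param a4_hz reference frequency of A4 in Hz (default 440).
#' @return frequency in Hz.
#' @export
#' @examples
#' note_to_freq("C1")  # 32.70 Hz
#' note_to_freq("A4")  # 440 Hz
note_to_freq <- function(note, a4_hz = 440) {
  if (length(note) != 1L || !is.character(note)) {
    stop_bws("'note' must be a single pitch name string", class = "bws_parse_error")
  }
  if (!is.numeric(a4_hz) || a4_hz <= 0) {
    stop_bws("'a4_hz' must be positive", class = "bws_parse_error")
  }
  m <- regmatches(note, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", note))[[1]]
  if (length(m) == 0L) {
    stop_bws("cannot parse pitch name '%s'", note, class = "bws_parse_error")
  }
  base <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)[toupper(m[2])]
  accidental <- switch(m[3], "#" = 1, "b" = -1, 0)
  octave <- as.integer(m[4])
  # semitones relative to A4 (= C4 + 9)
  semis <- (octave - 4) * 12 + base + accidental - 9
  unname(a4_hz * 2^(semis / 12))
}

#' Describe one synthetic stimulus
#'
#' A `StimulusSpec` holds everything needed to synthesize one
#' instrument-like sound: pitch, harmonic structure, noise, amplitude
#' modulation and envelope timing. These parameters double as the
#' ground-truth latent attributes used by the rater simulator, which is the
#' point of replacing recorded samples by additive synthesis.
#'
#' @param stimulus_id unique id string.
#' @param family one of [bws_families].
#' @param technique free-text playing-technique label.
#' @param note pitch name; corpus convention restricts notes to Cs of
#'   octaves 1-8.
#' @param dynamics one of `"pp"`, `"mf"`, `"ff"`.
#' @param duration_s duration in seconds, within `[0.5, 15]`.
#' @param n_harmonics number of harmonic partials (>= 1).
#' @param spectral_slope_db_per_oct spectral envelope slope in dB/octave
#'   (typically <= 0; steeper = darker).
#' @param noise_level ratio in `[0, 1]` of noise RMS to harmonic RMS.
#' @param am_rate_hz amplitude-modulation rate in Hz (>= 0).
#' @param am_depth amplitude-modulation depth in `[0, 1]`; 0 disables AM.
#' @param attack_s linear attack time in seconds (> 0).
#' @param envelope `"sustain"` (plateau after attack) or `"decay"`
#'   (exponential decay, for plucked/struck families).
#' @param seed integer seed making the noise realization reproducible.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(stimulus_id, family = "strings", technique = "ordinario",
                          note = "C4", dynamics = "mf", duration_s = 2,
                          n_harmonics = 10, spectral_slope_db_per_oct = -6,
                          noise_level = 0.05, am_rate_hz = 0, am_depth = 0,
                          attack_s = 0.05,
                          envelope = c("sustain", "decay"), seed = 1L) {
  envelope <- match.arg(envelope)
  family <- match.arg(family, bws_families)
  dynamics <- match.arg(dynamics, c("pp", "mf", "ff"))
  if (duration_s < 0.5 || duration_s > 15) {
    stop_bws("duration_s must lie in [0.5, 15], got %g", duration_s,
             class = "bws_spec_error")
  }
  if (noise_level < 0 || noise_level > 1) {
    stop_bws("noise_level must lie in [0, 1]", class = "bws_spec_error")
  }
  if (am_depth < 0 || am_depth > 1) {
    stop_bws("am_depth must lie in [0, 1]", class = "bws_spec_error")
  }
  if (am_depth > 0 && am_rate_hz <= 0) {
    stop_bws("am_rate_hz must be > 0 when am_depth > 0", class = "bws_spec_error")
  }
  if (attack_s <= 0) stop_bws("attack_s must be > 0", class = "bws_spec_error")
  if (n_harmonics < 1) stop_bws("n_harmonics must be >= 1", class = "bws_spec_error")
  note_to_freq(note)  # validates the pitch name
  structure(list(
    stimulus_id = as.character(stimulus_id), family = family,
    technique = technique, note = note, dynamics = dynamics,
    duration_s = duration_s, n_harmonics = as.integer(n_harmonics),
    spectral_slope_db_per_oct = spectral_slope_db_per_oct,
    noise_level = noise_level, am_rate_hz = am_rate_hz, am_depth = am_depth,
    attack_s = attack_s, envelope = envelope, seed = as.integer(seed)
  ), class = "stimulus_spec")
}

#' Synthesize one stimulus from its spec
#'
#' Additive synthesis: harmonics at integer multiples of F0 with amplitudes
#' following the spectral slope, plus white Gaussian noise scaled to the
#' requested noise-to-harmonic RMS ratio, amplitude-modulated, then shaped
#' by a linear attack ramp followed by either a sustained plateau or an
#' exponential decay. Harmonics at or above Nyquist are dropped. The result
#' is deterministic given the spec's seed.
#'
#' @param spec a [stimulus_spec()].
#' @param sample_rate_hz sample rate in Hz (default 44100).
#' @return an object of class `sound_stimulus`: list with `stimulus_id`,
#'   `sample_rate_hz`, `samples` (numeric vector in `[-1, 1]`) and `spec`.
#' @export
synthesize_stimulus <- function(spec, sample_rate_hz = 44100) {
  f0 <- note_to_freq(spec$note)
  nyquist <- sample_rate_hz / 2
  if (f0 >= nyquist) {
    stop_bws("fundamental %g Hz is at or above Nyquist (%g Hz)", f0, nyquist,
             class = "bws_synthesis_error")
  }
  n <- round(spec$duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz

  k <- seq_len(spec$n_harmonics)
  k <- k[k * f0 < nyquist]
  # amplitude of harmonic k follows the spectral slope in dB per octave
  amps <- 10^(spec$spectral_slope_db_per_oct * log2(k) / 20)

  harm <- rep(0, n)
  with_seed(spec$seed, {
    phases <- runif(length(k), 0, 2 * pi)
    for (i in seq_along(k)) {
      harm <- harm + amps[i] * sin(2 * pi * k[i] * f0 * t + phases[i])
    }
    x <- harm
    if (spec$noise_level > 0) {
      harm_rms <- sqrt(mean(harm^2))
      noise <- rnorm(n)
      noise <- noise / sqrt(mean(noise^2)) * spec$noise_level * harm_rms
      x <- x + noise
    }
    x
  }) -> x

  if (spec$am_depth > 0) {
    x <- x * (1 + spec$am_depth * sin(2 * pi * spec$am_rate_hz * t)) /
      (1 + spec$am_depth)
  }

  env <- pmin(t / spec$attack_s, 1)
  if (spec$envelope == "decay") {
    # decay to about -40 dB over the post-attack span
    tau <- (spec$duration_s - spec$attack_s) / log(100)
    post <- t > spec$attack_s
    env[post] <- exp(-(t[post] - spec$attack_s) / tau)
  }
  x <- x * env

  peak <- max(abs(x))
  if (peak > 0) x <- x * (0.9 / peak)

  structure(list(stimulus_id = spec$stimulus_id,
                 sample_rate_hz = sample_rate_hz,
                 samples = x, spec = spec),
            class = "sound_stimulus")
}

#' @export
print.sound_stimulus <- function(x, ...) {
  cat(sprintf("<sound_stimulus %s: %s %s %s, %.2f s @ %d Hz>\n",
              x$stimulus_id, x$spec$family, x$spec$technique, x$spec$note,
              x$spec$duration_s, as.integer(x$sample_rate_hz)))
  invisible(x)
}

# Family-conditioned priors over synthesis parameters. These are the
# package's own illustrative distributions (brass = shallow slope + fast
# attack, strings may be noisy like sul ponticello, plucked families decay);
# they are not estimates of any recorded-sample library.
.family_priors <- list(
  strings   = list(slope = c(-12, -4), noise = c(0.01, 0.40), attack = c(0.02, 0.40),
                   nharm = c(8, 24), am = c(0.0, 0.3), env = "sustain",
                   techniques = c("ordinario", "sul_ponticello", "tremolo")),
  woodwinds = list(slope = c(-14, -6), noise = c(0.01, 0.25), attack = c(0.02, 0.20),
                   nharm = c(6, 18), am = c(0.0, 0.5), env = "sustain",
                   techniques = c("ordinario", "flatterzunge", "multiphonic")),
  brass     = list(slope = c(-8, -2), noise = c(0.01, 0.15), attack = c(0.01, 0.10),
                   nharm = c(12, 30), am = c(0.0, 0.4), env = "sustain",
                   techniques = c("ordinario", "cuivre", "sordino")),
  keyboards = list(slope = c(-12, -5), noise = c(0.01, 0.10), attack = c(0.005, 0.03),
                   nharm = c(8, 20), am = c(0.0, 0.1), env = "decay",
                   techniques = c("ordinario", "staccato")),
  harp      = list(slope = c(-14, -8), noise = c(0.01, 0.08), attack = c(0.005, 0.02),
                   nharm = c(6, 14), am = c(0.0, 0.05), env = "decay",
                   techniques = c("ordinario", "pres_de_la_table")),
  guitar    = list(slope = c(-13, -7), noise = c(0.01, 0.10), attack = c(0.005, 0.02),
                   nharm = c(6, 14), am = c(0.0, 0.05), env = "decay",
                   techniques = c("ordinario", "harmonics")),
  accordion = list(slope = c(-10, -4), noise = c(0.01, 0.12), attack = c(0.03, 0.20),
                   nharm = c(10, 24), am = c(0.1, 0.6), env = "sustain",
                   techniques = c("ordinario", "bellows_shake"))
)

#' Build a corpus manifest
#'
#' Lays out the metadata skeleton of a synthetic corpus: one entry per
#' stimulus with id, family, technique, pitch (Cs of octaves 1-8),
#' dynamics and duration. Family-specific synthesis parameters are sampled
#' later by [generate_corpus()] so that two seeds share metadata but differ
#' in waveform realizations.
#'
#' @param family_counts named integer vector mapping family to stimulus
#'   count; defaults to [bws_family_counts].
#' @param duration_range duration range in seconds (within `[0.5, 15]`).
#' @param octave_range integer range of C octaves to draw pitches from.
#' @param target_loudness_lufs loudness-equalization target in LUFS
#'   (default -23, the EBU R-128 reference level).
#' @param seed integer seed for the metadata draws.
#' @return an object of class `corpus_manifest`: list with `entries`
#'   (data.frame of metadata), `family_counts`, `target_loudness_lufs`.
#' @export
corpus_manifest <- function(family_counts = bws_family_counts,
                            duration_range = c(0.5, 2),
                            octave_range = c(1, 8),
                            target_loudness_lufs = -23,
                            seed = 1L) {
  unknown <- setdiff(names(family_counts), bws_families)
  if (length(unknown)) {
    stop_bws("unknown families: %s", paste(unknown, collapse = ", "),
             class = "bws_manifest_error")
  }
  if (any(family_counts < 0) || sum(family_counts) < 1) {
    stop_bws("family_counts must be nonnegative with positive total",
             class = "bws_manifest_error")
  }
  family_counts <- family_counts[family_counts > 0]
  n <- sum(family_counts)
  fams <- rep(names(family_counts), family_counts)
  entries <- with_seed(seed, {
    octaves <- sample(seq(octave_range[1], octave_range[2]), n, replace = TRUE)
    data.frame(
      stimulus_id = sprintf("S%04d", seq_len(n)),
      family = fams,
      technique = vapply(fams, function(f) {
        sample(.family_priors[[f]]$techniques, 1)
      }, character(1)),
      note = paste0("C", octaves),
      dynamics = sample(c("pp", "mf", "ff"), n, replace = TRUE),
      duration_s = round(runif(n, duration_range[1], duration_range[2]), 3),
      stringsAsFactors = FALSE
    )
  })
  structure(list(entries = entries,
                 family_counts = family_counts,
                 target_loudness_lufs = target_loudness_lufs,
                 seed = as.integer(seed)),
            class = "corpus_manifest")
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf("<corpus_manifest: %d stimuli, target %.1f LUFS>\n",
              nrow(x$entries), x$target_loudness_lufs))
  print(x$family_counts)
  invisible(x)
}

#' Generate a synthetic corpus from a manifest
#'
#' Samples family-conditioned synthesis parameters (spectral slope, noise
#' level, AM, attack, harmonic count) deterministically from `seed`, then
#' synthesizes one [sound_stimulus][synthesize_stimulus()] per manifest
#' entry. The metadata (ids, families, notes, durations) comes from the
#' manifest, so two seeds give the same metadata but different parameter
#' and noise realizations.
#'
#' @param manifest a [corpus_manifest()].
#' @param seed integer seed for parameter sampling and noise.
#' @param sample_rate_hz sample rate in Hz.
#' @param normalize if `TRUE` (default), loudness-normalize to the
#'   manifest's target via [normalize_loudness()].
#' @param synthesize if `FALSE`, skip waveform synthesis and return
#'   spec-only stimuli (enough for [latent_attributes()] and rater
#'   simulation, where only the ground-truth parameters matter).
#' @return an object of class `sound_corpus`: list of stimuli with the
#'   manifest and specs attached.
#' @export
generate_corpus <- function(manifest, seed = 1L, sample_rate_hz = 44100,
                            normalize = TRUE, synthesize = TRUE) {
  entries <- manifest$entries
  if (anyDuplicated(entries$stimulus_id)) {
    stop_bws("duplicate stimulus ids in manifest", class = "bws_manifest_error")
  }
  n <- nrow(entries)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    e <- entries[i, ]
    pr <- .family_priors[[e$family]]
    sub_seed <- derive_seed(seed, "synth", e$stimulus_id)
    pars <- with_seed(sub_seed, {
      am_depth <- runif(1, pr$am[1], pr$am[2])
      list(slope = runif(1, pr$slope[1], pr$slope[2]),
           noise = runif(1, pr$noise[1], pr$noise[2]),
           attack = runif(1, pr$attack[1], pr$attack[2]),
           nharm = sample(seq(pr$nharm[1], pr$nharm[2]), 1),
           am_depth = if (am_depth < 0.05) 0 else am_depth,
           am_rate = runif(1, 4, 120))
    })
    # dynamics shade the spectral slope: louder playing is brighter
    dyn_shift <- c(pp = -3, mf = 0, ff = 3)[[e$dynamics]]
    specs[[i]] <- stimulus_spec(
      stimulus_id = e$stimulus_id, family = e$family, technique = e$technique,
      note = e$note, dynamics = e$dynamics, duration_s = e$duration_s,
      n_harmonics = pars$nharm,
      spectral_slope_db_per_oct = pars$slope + dyn_shift,
      noise_level = pars$noise,
      am_rate_hz = if (pars$am_depth > 0) pars$am_rate else 0,
      am_depth = pars$am_depth,
      attack_s = pars$attack, envelope = pr$env,
      seed = derive_seed(seed, "noise", e$stimulus_id)
    )
  }
  stimuli <- if (synthesize) {
    lapply(specs, synthesize_stimulus, sample_rate_hz = sample_rate_hz)
  } else {
    lapply(specs, function(sp) {
      structure(list(stimulus_id = sp$stimulus_id,
                     sample_rate_hz = sample_rate_hz,
                     samples = NULL, spec = sp),
                class = "sound_stimulus")
    })
  }
  names(stimuli) <- entries$stimulus_id
  corpus <- structure(list(stimuli = stimuli, manifest = manifest,
                           sample_rate_hz = sample_rate_hz),
                      class = "sound_corpus")
  if (normalize && synthesize) {
    corpus <- normalize_loudness(corpus, manifest$target_loudness_lufs)
  }
  corpus
}

#' @export
print.sound_corpus <- function(x, ...) {
  cat(sprintf("<sound_corpus: %d stimuli @ %d Hz>\n",
              length(x$stimuli), as.integer(x$sample_rate_hz)))
  print(table(vapply(x$stimuli, function(s) s$spec$family, character(1))))
  invisible(x)
}

#' Corpus metadata as a data.frame
#'
#' @param corpus a `sound_corpus`.
#' @return data.frame with one row per stimulus: id, family, technique,
#'   note, dynamics, duration.
#' @export
corpus_metadata <- function(corpus) {
  do.call(rbind, lapply(corpus$stimuli, function(s) {
    data.frame(stimulus_id = s$stimulus_id, family = s$spec$family,
               technique = s$spec$technique, note = s$spec$note,
               dynamics = s$spec$dynamics, duration_s = s$spec$duration_s,
               stringsAsFactors = FALSE)
  }))
}

#' Ground-truth latent attributes of a synthetic corpus
#'
#' Returns the z-scored synthesis parameters (log F0, spectral slope, noise
#' level, AM depth, attack time) plus the analytically derived spectral
#' centroid of the harmonic stack. These are the latent attributes rater
#' utility functions operate on, enabling clean parameter-recovery tests.
#'
#' @param corpus a `sound_corpus`.
#' @param zscore standardize columns (default `TRUE`).
#' @return numeric matrix, rows = stimuli, columns = attributes.
#' @export
latent_attributes <- function(corpus, zscore = TRUE) {
  rows <- lapply(corpus$stimuli, function(s) {
    sp <- s$spec
    f0 <- note_to_freq(sp$note)
    k <- seq_len(sp$n_harmonics)
    k <- k[k * f0 < s$sample_rate_hz / 2]
    a <- 10^(sp$spectral_slope_db_per_oct * log2(k) / 20)
    centroid <- sum(k * f0 * a^2) / sum(a^2)
    c(log_f0 = log2(f0), spectral_centroid = centroid,
      spectral_slope = sp$spectral_slope_db_per_oct,
      noise_level = sp$noise_level, am_depth = sp$am_depth,
      attack_s = sp$attack_s, duration_s = sp$duration_s)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(corpus$stimuli)
  if (zscore) {
    m <- scale(m)
    m[, attr(m, "scaled:scale") == 0] <- 0  # constant columns -> 0
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}

#' Write a corpus to disk
#'
#' Emits one WAV file per stimulus (filename = stimulus id), the metadata
#' CSV, and the manifest as JSON.
#'
#' @param corpus a `sound_corpus`.
#' @param dir output directory, created if missing.
#' @param bit_depth WAV bit depth passed to [write_wav()].
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(corpus, dir, bit_depth = 16) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wavs <- vapply(corpus$stimuli, function(s) {
    p <- file.path(dir, paste0(s$stimulus_id, ".wav"))
    write_wav(s$samples, s$sample_rate_hz, p, bit_depth = bit_depth)
    p
  }, character(1))
  meta_path <- file.path(dir, "corpus_metadata.csv")
  write.csv(corpus_metadata(corpus), meta_path, row.names = FALSE)
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    family_counts = as.list(corpus$manifest$family_counts),
    target_loudness_lufs = corpus$manifest$target_loudness_lufs,
    seed = corpus$manifest$seed,
    entries = corpus$manifest$entries
  ), man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(wavs, meta_path, man_path))
}
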