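#' Frame configuration for spectral analysis
#'
#' @param win_s analysis window length in seconds (Hann window).
#' @param hop_s hop between frames in seconds.
#' @param silence_gate_db frames whose energy is this many dB below the
#'   loudest frame are excluded from the median/IQR summaries.
#' @return list of class `frame_config`.
#' @export
frame_config <- function(win_s = 0.025, hop_s = 0.005, silence_gate_db = 60) {
  structure(list(win_s = win_s, hop_s = hop_s,
                 silence_gate_db = silence_gate_db),
            class = "frame_config")
}

#' Short-time Fourier transform magnitudes
#'
#' Hann-windowed STFT; returns the one-sided magnitude spectrogram.
#'
#' @param x numeric samples.
#' @param fs sample rate in Hz.
#' @param cfg a [frame_config()].
#' @return list (`frame_spectra`): `frame_times` (s), `frequencies` (Hz),
#'   `magnitudes` (frames x bins matrix), `win`, `hop` (samples).
#' @export
stft_frames <- function(x, fs, cfg = frame_config()) {
  win <- max(4L, round(cfg$win_s * fs))
  hop <- max(1L, round(cfg$hop_s * fs))
  if (length(x) < win) {
    stop_bws("signal shorter than one analysis window", class = "bws_feature_error")
  }
  nfft <- 2^ceiling(log2(win))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))  # Hann
  starts <- seq(1, length(x) - win + 1, by = hop)
  nbins <- nfft %/% 2 + 1
  mags <- matrix(0, length(starts), nbins)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1)] * w
    sp <- fft(c(seg, rep(0, nfft - win)))
    mags[i, ] <- Mod(sp[seq_len(nbins)])
  }
  structure(list(frame_times = (starts - 1 + win / 2) / fs,
                 frequencies = (seq_len(nbins) - 1) * fs / nfft,
                 magnitudes = mags, win = win, hop = hop),
            class = "frame_spectra")
}

# frames loud enough to summarize: energy within gate of the loudest frame
gated_frames <- function(mags, gate_db) {
  energy <- rowSums(mags^2)
  if (max(energy) <= 0) return(integer(0))
  keep <- 10 * log10(energy / max(energy)) > -gate_db
  which(keep)
}

med_iqr <- function(v) {
  c(med = median(v), iqr = unname(diff(quantile(v, c(0.25, 0.75)))))
}

#' Frame-wise spectral descriptors with median/IQR summaries
#'
#' Per frame: centroid (magnitude-weighted mean frequency), bandwidth
#' (weighted SD about the centroid), crest (max/mean magnitude), flatness
#' (geometric over arithmetic mean) and 85%-energy rolloff. Summaries
#' (median and interquartile range) are taken over frames above the
#' silence gate.
#'
#' @param stim a `sound_stimulus` (or list with `samples`,
#'   `sample_rate_hz`).
#' @param cfg a [frame_config()].
#' @return list with `frames` (per-frame data.frame) and `summary`
#'   (named vector `<name>_med` / `<name>_iqr`).
#' @export
spectral_descriptors <- function(stim, cfg = frame_config()) {
  fr <- stft_frames(stim$samples, stim$sample_rate_hz, cfg)
  keep <- gated_frames(fr$magnitudes, cfg$silence_gate_db)
  if (!length(keep)) stop_bws("all frames silent", class = "bws_feature_error")
  f <- fr$frequencies
  per_frame <- t(apply(fr$magnitudes[keep, , drop = FALSE], 1, function(m) {
    msum <- sum(m)
    centroid <- sum(f * m) / msum
    bandwidth <- sqrt(sum((f - centroid)^2 * m) / msum)
    crest <- max(m) / mean(m)
    # flatness on the power spectrum, epsilon-guarded for pure tones
    p <- m^2 + 1e-20
    flatness <- exp(mean(log(p))) / mean(p)
    cum <- cumsum(m^2)
    rolloff <- f[which(cum >= 0.85 * cum[length(cum)])[1]]
    c(centroid = centroid, bandwidth = bandwidth, crest = crest,
      flatness = flatness, rolloff = rolloff)
  }))
  frames <- data.frame(time = fr$frame_times[keep], per_frame)
  summ <- unlist(lapply(colnames(per_frame), function(nm) {
    v <- med_iqr(per_frame[, nm])
    setNames(v, paste0("spectral_", nm, "_", names(v)))
  }))
  list(frames = frames, summary = summ)
}

#' Median fundamental frequency by autocorrelation
#'
#' Frame-wise normalized autocorrelation; the F0 candidate is the highest
#' peak at lags within `[fs/fmax, fs/fmin]`, refined by parabolic
#' interpolation. Frames whose peak autocorrelation falls below the
#' voicing threshold are treated as unvoiced; the median is over voiced
#' frames, `NA` if none (the unvoiced sentinel).
#'
#' @param stim a `sound_stimulus`.
#' @param fmin,fmax F0 search range in Hz (default 25-4500, covering
#'   C1-C8 with margin).
#' @param voicing_threshold minimum normalized autocorrelation peak.
#' @return `f0_med` in Hz, or `NA` if no voiced frames.
#' @export
estimate_f0 <- function(stim, fmin = 25, fmax = 4500, voicing_threshold = 0.5) {
  fs <- stim$sample_rate_hz
  if (fmin >= fmax || fmax > fs / 2) {
    stop_bws("need fmin < fmax <= Nyquist", class = "bws_feature_error")
  }
  f0s <- frame_acf_f0(stim$samples, fs, fmin, fmax)
  voiced <- f0s$r >= voicing_threshold & is.finite(f0s$f0)
  if (!any(voiced)) return(NA_real_)
  median(f0s$f0[voiced])
}

# shared frame-wise autocorrelation machinery for F0 and HNR: windows of
# >= 2/fmin seconds, hop 10 ms, FFT-based autocorrelation with the
# zero-padding taper undone (unbiased estimate). Peak picking prefers the
# smallest lag among near-maximal local peaks to avoid octave errors.
frame_acf_f0 <- function(x, fs, fmin, fmax) {
  win <- round(max(2 / fmin, 0.04) * fs)
  win <- min(win, length(x))
  hop <- max(1L, round(0.01 * fs))
  starts <- seq(1, max(1, length(x) - win + 1), by = hop)
  lag_min <- max(2L, floor(fs / fmax))
  # keep lags well inside the window so the unbiased correction stays stable
  lag_max <- min(floor(0.75 * win), ceiling(fs / fmin))
  nfft <- 2^ceiling(log2(2 * win))
  f0 <- r <- rep(NA_real_, length(starts))
  if (lag_max <= lag_min + 1) return(list(f0 = f0, r = r))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win - 1)]
    seg <- seg - mean(seg)
    if (sum(seg^2) <= 0) next
    sp <- fft(c(seg, rep(0, nfft - win)))
    ac <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(lag_max + 1)]
    ac <- ac / ac[1]
    # zero-padded linear autocorrelation tapers as (win - lag)/win: undo it
    ac <- ac * win / (win - (0:lag_max))
    idx <- (lag_min:lag_max) + 1L            # 1-based positions in ac
    inner <- idx[idx > 2 & idx < length(ac)]
    is_peak <- ac[inner] >= ac[inner - 1] & ac[inner] >= ac[inner + 1]
    cand <- inner[is_peak]
    if (!length(cand)) next
    rmax <- max(ac[cand])
    pk <- cand[ac[cand] >= 0.9 * rmax][1]    # smallest near-maximal lag
    y1 <- ac[pk - 1]; y2 <- ac[pk]; y3 <- ac[pk + 1]
    denom <- y1 - 2 * y2 + y3
    shift <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    shift <- max(-0.5, min(0.5, shift))
    f0[i] <- fs / ((pk - 1) + shift)
    r[i] <- min(y2 - 0.25 * (y1 - y3) * shift, 1)
  }
  list(f0 = f0, r = r)
}

#' Harmonic-to-noise ratio in dB
#'
#' Harmonicity from the normalized autocorrelation peak r in the F0 lag
#' range: `HNR = 10 log10(r / (1 - r))`, median over frames above the
#' silence gate. A pure tone approaches the 60 dB clamp; white noise goes
#' negative.
#'
#' @param stim a `sound_stimulus`.
#' @param fmin,fmax lag search range in Hz.
#' @return HNR in dB (median over frames).
#' @export
hnr <- function(stim, fmin = 25, fmax = 4500) {
  if (all(stim$samples == 0)) stop_bws("silent stimulus", class = "bws_feature_error")
  fr <- frame_acf_f0(stim$samples, stim$sample_rate_hz, fmin, fmax)
  r <- fr$r[is.finite(fr$r)]
  if (!length(r)) stop_bws("no analyzable frames", class = "bws_feature_error")
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  median(10 * log10(r / (1 - r)))
}

#' Attack and temporal-envelope features
#'
#' The energy envelope is a smoothed frame RMS. Attack time runs from the
#' 10% to the 90% crossing of the envelope maximum; `attack_slope` is
#' `0.8 * max / (t90 - t10)` (1/s), `log_attack_time` is `log10(t90 - t10)`
#' and `temporal_centroid` the energy-weighted mean time.
#'
#' @param stim a `sound_stimulus`.
#' @param frame_s RMS frame length in seconds.
#' @return named vector: attack_slope, log_attack_time, temporal_centroid;
#'   attribute `"flat_envelope"` flags degenerate envelopes.
#' @export
attack_features <- function(stim, frame_s = 0.01) {
  x <- stim$samples
  fs <- stim$sample_rate_hz
  wl <- max(2L, round(frame_s * fs))
  n <- floor(length(x) / wl)
  if (n < 3) stop_bws("signal too short for envelope", class = "bws_feature_error")
  env <- sqrt(colMeans(matrix(x[seq_len(n * wl)]^2, nrow = wl)))
  env <- as.numeric(stats::filter(env, rep(1 / 3, 3), sides = 2))
  env[is.na(env)] <- 0
  tt <- (seq_len(n) - 0.5) * wl / fs
  m <- max(env)
  flat <- m <= 0 || (diff(range(env)) < 1e-12)
  if (flat) {
    out <- c(attack_slope = 0, log_attack_time = NA_real_,
             temporal_centroid = median(tt))
    attr(out, "flat_envelope") <- TRUE
    return(out)
  }
  i_peak <- which.max(env)
  t10 <- tt[which(env >= 0.1 * m)[1]]
  t90 <- tt[which(env >= 0.9 * m)[1]]
  if (t90 <= t10) t90 <- t10 + wl / fs  # sub-frame attack: floor at one frame
  out <- c(attack_slope = 0.8 * m / (t90 - t10),
           log_attack_time = log10(t90 - t10),
           temporal_centroid = sum(tt * env^2) / sum(env^2))
  attr(out, "flat_envelope") <- FALSE
  out
}

#' Modulation-power-spectrum roughness
#'
#' Mean power of the modulation power spectrum in a temporal-modulation
#' band (default 30-150 Hz): log-magnitude spectrogram, mean-removed, 2-D
#' Fourier transform, power averaged over both signs of the temporal
#' modulation axis within the band and over all spectral-modulation rows.
#' The default hop (2.5 ms) keeps the temporal-modulation Nyquist at
#' 200 Hz so the whole 30-150 Hz band is observable.
#'
#' @param stim a `sound_stimulus`.
#' @param band temporal-modulation band in Hz.
#' @param win_s,hop_s spectrogram window and hop in seconds.
#' @return mean band power (>= 0); 0 for digital silence.
#' @export
mps_roughness <- function(stim, band = c(30, 150), win_s = 0.025,
                          hop_s = 0.0025) {
  x <- stim$samples
  if (all(x == 0)) return(0)
  fs <- stim$sample_rate_hz
  fr <- stft_frames(x, fs, frame_config(win_s = win_s, hop_s = hop_s))
  nt <- nrow(fr$magnitudes)
  if (nt < 8) stop_bws("too few frames for modulation analysis",
                       class = "bws_feature_error")
  frame_rate <- fs / fr$hop
  if (frame_rate / 2 < band[2]) {
    warning(sprintf("hop too large: modulation Nyquist %.0f Hz < band top %.0f Hz",
                    frame_rate / 2, band[2]))
  }
  S <- log(fr$magnitudes + 1e-10)
  S <- S - mean(S)
  M <- Mod(stats::mvfft(t(stats::mvfft(S))))^2  # 2-D FFT power
  # temporal-modulation frequencies along the frame axis (rows of S)
  ft <- (seq_len(nt) - 1) * frame_rate / nt
  ft[ft > frame_rate / 2] <- ft[ft > frame_rate / 2] - frame_rate
  sel <- abs(ft) >= band[1] & abs(ft) <= band[2]
  if (!any(sel)) stop_bws("band empty at this frame rate", class = "bws_feature_error")
  mean(t(M)[sel, ]) / length(x)
}

#' One-hot encode corpus metadata
#'
#' Indicator column per instrument family and per playing technique;
#' exactly one 1 per stimulus within each category. Zero-variance columns
#' (single-level corpora) are kept but flagged.
#'
#' @param meta data.frame with `stimulus_id`, `family`, `technique`.
#' @return numeric matrix (rows named by stimulus id) with attribute
#'   `"zero_variance"` listing constant columns.
#' @export
one_hot_meta <- function(meta) {
  stopifnot(all(c("stimulus_id", "family", "technique") %in% names(meta)))
  unknown <- setdiff(unique(meta$family), bws_families)
  if (length(unknown)) {
    stop_bws("unknown family labels: %s", paste(unknown, collapse = ", "),
             class = "bws_feature_error")
  }
  enc <- function(values, prefix) {
    lev <- sort(unique(values))
    m <- outer(values, lev, `==`) * 1
    colnames(m) <- paste0(prefix, lev)
    m
  }
  m <- cbind(enc(meta$family, "family_"), enc(meta$technique, "technique_"))
  rownames(m) <- meta$stimulus_id
  attr(m, "zero_variance") <- colnames(m)[apply(m, 2, function(c) length(unique(c)) == 1)]
  m
}

#' Extract the full feature matrix of a corpus
#'
#' One row per stimulus: spectral descriptor medians and IQRs, median F0,
#' HNR, attack features, MPS roughness, plus one-hot family/technique meta
#' columns.
#'
#' @param corpus a `sound_corpus`.
#' @param cfg a [frame_config()] for the spectral descriptors.
#' @return object of class `bws_feature_matrix`: data.frame with rownames
#'   = stimulus ids; attributes `column_meta` (name, kind) and
#'   `pruning_log` (empty until [prune_multicollinear()]).
#' @export
extract_features <- function(corpus, cfg = frame_config()) {
  rows <- lapply(corpus$stimuli, function(s) {
    sd_ <- spectral_descriptors(s, cfg)$summary
    af <- attack_features(s)
    c(sd_,
      f0_med = estimate_f0(s),
      hnr = hnr(s),
      af,
      mps_roughness = mps_roughness(s))
  })
  acoustic <- do.call(rbind, rows)
  rownames(acoustic) <- names(corpus$stimuli)
  # unvoiced F0 sentinel: impute at the corpus minimum so columns are complete
  if (anyNA(acoustic[, "f0_med"])) {
    acoustic[is.na(acoustic[, "f0_med"]), "f0_med"] <-
      min(acoustic[, "f0_med"], na.rm = TRUE)
  }
  if (anyNA(acoustic[, "log_attack_time"])) {
    acoustic[is.na(acoustic[, "log_attack_time"]), "log_attack_time"] <-
      min(acoustic[, "log_attack_time"], na.rm = TRUE)
  }
  meta <- one_hot_meta(corpus_metadata(corpus))
  stopifnot(identical(rownames(acoustic), rownames(meta)))
  df <- as.data.frame(cbind(acoustic, meta))
  structure(df,
            column_meta = data.frame(
              name = c(colnames(acoustic), colnames(meta)),
              kind = c(rep("acoustic", ncol(acoustic)),
                       rep("meta", ncol(meta))),
              stringsAsFactors = FALSE),
            pruning_log = data.frame(removed = character(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE),
            class = c("bws_feature_matrix", "data.frame"))
}

#' Acoustic / meta column names of a feature matrix
#' @param fm a `bws_feature_matrix`.
#' @param kind `"acoustic"` or `"meta"`.
#' @return character vector of column names.
#' @export
feature_columns <- function(fm, kind = c("acoustic", "meta")) {
  kind <- match.arg(kind)
  cm <- attr(fm, "column_meta")
  cm$name[cm$kind == kind]
}

#' Greedy multicollinearity pruning
#'
#' While any pair of acoustic columns has |Pearson r| above the threshold,
#' the member with the larger mean absolute correlation to all other
#' acoustic columns is removed. Meta columns are exempt. Every removal is
#' appended to the matrix's pruning log.
#'
#' @param fm a `bws_feature_matrix`.
#' @param r_threshold absolute correlation threshold (default 0.9).
#' @return the pruned `bws_feature_matrix`.
#' @export
prune_multicollinear <- function(fm, r_threshold = 0.9) {
  ac <- feature_columns(fm, "acoustic")
  if (length(ac) < 2) return(fm)
  log_rows <- attr(fm, "pruning_log")
  repeat {
    X <- as.matrix(fm[, ac, drop = FALSE])
    keep_var <- apply(X, 2, sd) > 0
    C <- matrix(0, length(ac), length(ac), dimnames = list(ac, ac))
    if (sum(keep_var) >= 2) {
      C[keep_var, keep_var] <- abs(cor(X[, keep_var, drop = FALSE]))
    }
    diag(C) <- 0
    worst <- max(C)
    if (worst <= r_threshold) break
    idx <- which(C == worst, arr.ind = TRUE)[1, ]
    pair <- ac[idx]
    mean_r <- colMeans(C[, pair, drop = FALSE])
    drop_col <- pair[which.max(mean_r)]
    log_rows <- rbind(log_rows, data.frame(
      removed = drop_col,
      reason = sprintf("|r| = %.3f with %s", worst,
                       setdiff(pair, drop_col)),
      stringsAsFactors = FALSE))
    ac <- setdiff(ac, drop_col)
  }
  keep <- c(ac, feature_columns(fm, "meta"))
  cm <- attr(fm, "column_meta")
  out <- fm[, keep, drop = FALSE]
  attr(out, "column_meta") <- cm[cm$name %in% keep, ]
  attr(out, "pruning_log") <- log_rows
  class(out) <- class(fm)
  out
}

#' Write a feature matrix to CSV with a JSON sidecar
#'
#' @param fm a `bws_feature_matrix`.
#' @param path CSV path; `<path>.json` records column kinds and the
#'   pruning log.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(stimulus_id = rownames(fm), fm, check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(column_meta = attr(fm, "column_meta"),
                            pruning_log = attr(fm, "pruning_log")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
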