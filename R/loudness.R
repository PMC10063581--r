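#' Integrated loudness per ITU-R BS.1770 (EBU R-128)
#'
#' Computes K-weighted, gated integrated loudness in LUFS: a two-stage
#' K-weighting prefilter (high-frequency shelf + high-pass), 400 ms gating
#' blocks with 75% overlap, a -70 LUFS absolute gate and a -10 LU relative
#' gate. Mono signals only (the corpus is diotic, so one channel carries
#' all the information).
#'
#' @param stim a `sound_stimulus`, or a numeric vector of samples (then
#'   `sample_rate_hz` is required).
#' @param sample_rate_hz sample rate, ignored when `stim` is a stimulus.
#' @return integrated loudness in LUFS; `-Inf` for silence.
#' @export
integrated_loudness <- function(stim, sample_rate_hz = NULL) {
  if (inherits(stim, "sound_stimulus")) {
    x <- stim$samples
    fs <- stim$sample_rate_hz
  } else {
    x <- as.numeric(stim)
    fs <- sample_rate_hz
    if (is.null(fs)) stop_bws("sample_rate_hz required", class = "bws_loudness_error")
  }
  if (length(x) < 0.4 * fs) {
    stop_bws("signal shorter than one 400 ms gating block", class = "bws_loudness_error")
  }
  if (all(x == 0)) return(-Inf)

  y <- k_weight(x, fs)

  block <- round(0.4 * fs)
  hop <- round(0.1 * fs)
  starts <- seq(1, length(y) - block + 1, by = hop)
  z <- vapply(starts, function(s) mean(y[s:(s + block - 1)]^2), numeric(1))
  lj <- -0.691 + 10 * log10(z)

  keep <- which(lj > -70)
  if (!length(keep)) return(-Inf)
  gamma_r <- -0.691 + 10 * log10(mean(z[keep])) - 10
  keep2 <- keep[lj[keep] > gamma_r]
  if (!length(keep2)) keep2 <- keep
  -0.691 + 10 * log10(mean(z[keep2]))
}

# K-weighting prefilter: shelving + high-pass biquads with coefficients
# re-derived for arbitrary sample rates via the bilinear transform
# (the BS.1770 tables give them only at 48 kHz).
k_weight <- function(x, fs) {
  # stage 1: high-frequency shelf (+4 dB above ~1.68 kHz)
  f0 <- 1681.974450955533; G <- 3.999843853973347; Q <- 0.7071752369554196
  K <- tan(pi * f0 / fs)
  Vh <- 10^(G / 20); Vb <- Vh^0.4996667741545416
  a0_ <- 1 + K / Q + K * K
  b1c <- c((Vh + Vb * K / Q + K * K) / a0_,
           2 * (K * K - Vh) / a0_,
           (Vh - Vb * K / Q + K * K) / a0_)
  a1c <- c(2 * (K * K - 1) / a0_, (1 - K / Q + K * K) / a0_)
  y <- biquad(x, b1c, a1c)
  # stage 2: high-pass (RLB weighting, ~38 Hz)
  f0 <- 38.13547087602444; Q <- 0.5003270373238773
  K <- tan(pi * f0 / fs)
  a0_ <- 1 + K / Q + K * K
  b2c <- c(1, -2, 1)
  a2c <- c(2 * (K * K - 1) / a0_, (1 - K / Q + K * K) / a0_)
  biquad(y, b2c, a2c)
}

# direct-form I biquad via two stats::filter passes:
# MA part (convolution with zero-padded history) then AR recursion
biquad <- function(x, b, a) {
  v <- stats::filter(c(0, 0, x), b, method = "convolution", sides = 1)
  v <- as.numeric(v[-(1:2)])
  y <- stats::filter(v, c(-a[1], -a[2]), method = "recursive")
  as.numeric(y)
}

#' Loudness-normalize a corpus
#'
#' Applies a per-stimulus scalar gain so every stimulus's integrated
#' loudness lands on the target. If any gained waveform would clip, the
#' whole corpus is scaled down uniformly (preserving relative loudness)
#' and a warning is issued.
#'
#' @param corpus a `sound_corpus` or plain list of `sound_stimulus`.
#' @param target_lufs target integrated loudness in LUFS (default -23).
#' @return the corpus with gains applied; attribute `"gains"` holds the
#'   per-stimulus linear gains and `"headroom_scaled"` whether the uniform
#'   anti-clipping reduction was applied.
#' @export
normalize_loudness <- function(corpus, target_lufs = -23) {
  is_corpus <- inherits(corpus, "sound_corpus")
  stimuli <- if (is_corpus) corpus$stimuli else corpus
  L <- vapply(stimuli, integrated_loudness, numeric(1))
  silent <- names(stimuli)[!is.finite(L)]
  if (length(silent)) {
    stop_bws("silent stimuli cannot be normalized: %s",
             paste(silent, collapse = ", "), class = "bws_loudness_error")
  }
  gains <- 10^((target_lufs - L) / 20)
  peaks <- mapply(function(s, g) max(abs(s$samples)) * g, stimuli, gains)
  headroom <- FALSE
  if (max(peaks) > 1) {
    shrink <- 0.999 / max(peaks)
    gains <- gains * shrink
    headroom <- TRUE
    warning(sprintf(
      "normalization would clip; whole corpus scaled down by %.2f dB",
      -20 * log10(shrink)))
  }
  stimuli <- mapply(function(s, g) {
    s$samples <- s$samples * g
    s
  }, stimuli, gains, SIMPLIFY = FALSE)
  out <- if (is_corpus) {
    corpus$stimuli <- stimuli
    corpus
  } else {
    stimuli
  }
  attr(out, "gains") <- setNames(gains, names(stimuli))
  attr(out, "headroom_scaled") <- headroom
  out
}
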