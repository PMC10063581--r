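test_that("spectral centroid hits known closed-form cases", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  sine <- list(samples = sin(2 * pi * 1000 * t), sample_rate_hz = fs)
  s1 <- spectral_descriptors(sine)$summary
  bin <- fs / 2^ceiling(log2(round(0.025 * fs)))
  expect_lt(abs(s1[["spectral_centroid_med"]] - 1000), 1.5 * bin)
  # equal-amplitude sines at 500 and 1500 Hz -> centroid at the midpoint
  two <- list(samples = sin(2 * pi * 500 * t) + sin(2 * pi * 1500 * t),
              sample_rate_hz = fs)
  s2 <- spectral_descriptors(two)$summary
  expect_lt(abs(s2[["spectral_centroid_med"]] - 1000), 2 * bin)
  # flatness: white noise near 1, pure tone near 0
  noise <- list(samples = with_seed(4, rnorm(fs)), sample_rate_hz = fs)
  sn <- spectral_descriptors(noise)$summary
  expect_gt(sn[["spectral_flatness_med"]], 0.3)
  expect_lt(s1[["spectral_flatness_med"]], 0.01)
  expect_error(spectral_descriptors(list(samples = numeric(4000),
                                         sample_rate_hz = fs)),
               class = "bws_feature_error")
})

test_that("F0 estimates track the generator's pitch grid", {
  c4 <- make_tone(note = "C4", n_harmonics = 6)
  f <- estimate_f0(c4)
  expect_lt(abs(f - note_to_freq("C4")) / note_to_freq("C4"), 0.01)
  # octave tones give monotone increasing estimates (C1..C6 at 16 kHz)
  f0s <- vapply(1:6, function(o) {
    estimate_f0(make_tone(note = paste0("C", o), n_harmonics = 3))
  }, numeric(1))
  expect_true(all(diff(f0s) > 0))
  # pure noise is unvoiced
  noise <- list(samples = with_seed(5, rnorm(16000)), sample_rate_hz = 16000)
  expect_true(is.na(estimate_f0(noise)))
})

test_that("HNR separates tones from noise and tracks the noise level", {
  expect_gt(hnr(make_tone(noise_level = 0)), 40)
  noise <- list(samples = with_seed(6, rnorm(16000)), sample_rate_hz = 16000)
  expect_lte(hnr(noise), 0)
  h <- vapply(c(0, 0.1, 0.5), function(nl) {
    hnr(make_tone(noise_level = nl, seed = 3))
  }, numeric(1))
  expect_true(all(diff(h) < 0))
  # a pure-noise "stimulus" scores below any harmonic spec
  expect_lt(hnr(noise), min(h))
  expect_error(hnr(list(samples = numeric(8000), sample_rate_hz = 16000)),
               class = "bws_feature_error")
})

test_that("attack features follow the generator envelope", {
  fast <- attack_features(make_tone(attack_s = 0.01))
  slow <- attack_features(make_tone(attack_s = 0.5))
  expect_gt(fast[["attack_slope"]], slow[["attack_slope"]])
  expect_lt(fast[["log_attack_time"]], slow[["log_attack_time"]])
  # measured 10-90% duration of a 0.125 s linear ramp is 0.1 s -> log10 = -1
  lat <- attack_features(make_tone(attack_s = 0.125))[["log_attack_time"]]
  expect_lt(abs(lat - (-1)), 0.15)
  # symmetric triangular envelope centers the temporal centroid
  fs <- 16000
  tri <- c(seq(0, 1, length.out = fs / 2), seq(1, 0, length.out = fs / 2))
  stim <- list(samples = tri * sin(2 * pi * 220 * (0:(fs - 1)) / fs),
               sample_rate_hz = fs)
  tc <- attack_features(stim)[["temporal_centroid"]]
  expect_lt(abs(tc - 0.5), 0.05)
})

test_that("MPS roughness selects the 30-150 Hz modulation band", {
  plain <- make_tone(note = "C4", duration_s = 1)
  am70 <- make_tone(note = "C4", duration_s = 1, am_rate = 70, am_depth = 1)
  am8 <- make_tone(note = "C4", duration_s = 1, am_rate = 8, am_depth = 1)
  r_plain <- mps_roughness(plain)
  r_am70 <- mps_roughness(am70)
  r_am8 <- mps_roughness(am8)
  expect_gt(r_am70, r_plain)
  expect_gt(r_am70, r_am8)
  silence <- list(samples = numeric(16000), sample_rate_hz = 16000)
  expect_equal(mps_roughness(silence), 0)
})

test_that("scale-invariant features ignore a constant gain", {
  s <- make_tone(noise_level = 0.1, seed = 9)
  s3 <- s
  s3$samples <- 0.3 * s$samples
  a <- spectral_descriptors(s)$summary
  b <- spectral_descriptors(s3)$summary
  expect_equal(a[["spectral_centroid_med"]], b[["spectral_centroid_med"]],
               tolerance = 1e-6)
  expect_equal(a[["spectral_flatness_med"]], b[["spectral_flatness_med"]],
               tolerance = 1e-4)
  expect_equal(estimate_f0(s), estimate_f0(s3), tolerance = 1e-6)
  expect_equal(hnr(s), hnr(s3), tolerance = 1e-4)
})

test_that("one-hot meta encoding is exact and reversible", {
  meta <- data.frame(stimulus_id = c("a", "b", "c"),
                     family = c("strings", "brass", "strings"),
                     technique = c("ordinario", "cuivre", "tremolo"),
                     stringsAsFactors = FALSE)
  m <- one_hot_meta(meta)
  fam_cols <- grep("^family_", colnames(m))
  tec_cols <- grep("^technique_", colnames(m))
  expect_true(all(rowSums(m[, fam_cols]) == 1))
  expect_true(all(rowSums(m[, tec_cols]) == 1))
  # round-trip decode
  decoded <- colnames(m)[fam_cols][apply(m[, fam_cols], 1, which.max)]
  expect_identical(sub("family_", "", decoded), meta$family)
  expect_error(one_hot_meta(transform(meta, family = "theremin")),
               class = "bws_feature_error")
  single <- one_hot_meta(data.frame(stimulus_id = c("a", "b"),
                                    family = "harp", technique = "ordinario"))
  expect_true(all(c("family_harp", "technique_ordinario") %in%
                    attr(single, "zero_variance")))
})

test_that("a full corpus yields a complete feature matrix", {
  fm <- extract_features(tiny_corpus())
  expect_s3_class(fm, "bws_feature_matrix")
  expect_equal(nrow(fm), 10)
  expect_false(anyNA(fm))
  expect_true(all(c("spectral_centroid_med", "spectral_centroid_iqr",
                    "f0_med", "hnr", "attack_slope", "log_attack_time",
                    "temporal_centroid", "mps_roughness") %in% colnames(fm)))
  expect_true(all(fm$spectral_centroid_med >= 0 &
                    fm$spectral_centroid_med <= 8000))
  p <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, p)
  expect_true(file.exists(paste0(p, ".json")))
  unlink(c(p, paste0(p, ".json")))
})

test_that("multicollinearity pruning removes the right columns", {
  base <- extract_features(tiny_corpus())
  # duplicate column: exactly one copy of the pair is removed
  dup <- base
  dup$centroid_copy <- dup$spectral_centroid_med
  cm <- attr(base, "column_meta")
  attr(dup, "column_meta") <- rbind(cm, data.frame(name = "centroid_copy",
                                                   kind = "acoustic"))
  pruned <- prune_multicollinear(dup, r_threshold = 0.95)
  expect_equal(sum(c("spectral_centroid_med", "centroid_copy") %in%
                     colnames(pruned)), 1)
  expect_gt(nrow(attr(pruned, "pruning_log")), 0)
  # threshold above every |r|: nothing removed
  lax <- prune_multicollinear(base, r_threshold = 1)
  expect_identical(colnames(lax), colnames(base))
  # constructed case: A ~ B strongly, C independent
  X <- with_seed(12, {
    a <- rnorm(60)
    data.frame(A = a, B = a + rnorm(60, sd = 0.05), C = rnorm(60))
  })
  fmx <- structure(X, column_meta = data.frame(name = c("A", "B", "C"),
                                               kind = "acoustic"),
                   pruning_log = data.frame(removed = character(0),
                                            reason = character(0)),
                   class = c("bws_feature_matrix", "data.frame"))
  px <- prune_multicollinear(fmx, r_threshold = 0.9)
  expect_true("C" %in% colnames(px))
  expect_equal(sum(c("A", "B") %in% colnames(px)), 1)
})

test_that("ground-truth parameters are recovered across a controlled sweep", {
  # HNR vs noise level
  noise_levels <- seq(0, 0.8, length.out = 6)
  hnrs <- vapply(noise_levels, function(nl)
    hnr(make_tone(noise_level = nl, seed = 11)), numeric(1))
  expect_lte(cor(noise_levels, hnrs, method = "spearman"), -0.9)
  # centroid vs spectral slope
  slopes <- seq(-14, -2, length.out = 6)
  cents <- vapply(slopes, function(sl)
    spectral_descriptors(make_tone(note = "C3", n_harmonics = 20,
                                   slope = sl))$summary[["spectral_centroid_med"]],
    numeric(1))
  expect_gte(cor(slopes, cents, method = "spearman"), 0.9)
  # MPS roughness vs AM depth at 70 Hz
  depths <- seq(0, 1, length.out = 6)
  rough <- vapply(depths, function(d)
    mps_roughness(make_tone(am_rate = if (d > 0) 70 else 0, am_depth = d)),
    numeric(1))
  expect_gte(cor(depths, rough, method = "spearman"), 0.9)
})
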