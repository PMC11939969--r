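test_that("preprocess applies pre-emphasis, trimming, and framing", {
  # constant signal: y[t] = c - 0.97c = 0.03c everywhere (first sample
  # included by the boundary convention)
  sig <- audio_signal(rep(0.5, 22050), 22050)
  fr <- preprocess(sig, extract_config(trim_db = NULL))
  expect_equal(unique(round(as.numeric(fr$frames_emph), 12)), 0.03 * 0.5)

  # 1 s at 22.05 kHz, window 512 / hop 256 -> 1 + floor((22050-512)/256)
  expect_equal(ncol(fr$frames_raw), 85)
  expect_equal(nrow(fr$frames_raw), 512)

  # all-zero signal: nothing survives the trim
  expect_error(preprocess(audio_signal(rep(0, 22050), 22050)), "silent")
  # shorter than one window
  expect_error(preprocess(audio_signal(rnorm(100), 22050),
                          extract_config(trim_db = NULL)), "window")
})

test_that("voicing detection separates vowels, noise, and silence", {
  cfg <- extract_config()
  set.seed(5)
  noise <- audio_signal(rnorm(22050) * 0.1, 22050)
  frn <- preprocess(noise, cfg)
  expect_lte(mean(detect_voiced(frn, cfg)), 0.1)

  vowel <- synthesize_vowel(voice_params(duration_s = 2), seed = 6)
  frv <- preprocess(vowel, cfg)
  expect_gte(mean(detect_voiced(frv, cfg)), 0.9)

  silence <- audio_signal(rep(0, 22050), 22050)
  frs <- preprocess(silence, extract_config(trim_db = NULL))
  expect_false(any(detect_voiced(frs, cfg)))
})

test_that("F0 estimation finds known tones and flags out-of-band input", {
  sr <- 22050
  tone <- audio_signal(0.5 * sin(2 * pi * 180 * (0:(2 * sr - 1)) / sr), sr)
  fr <- preprocess(tone)
  mask <- detect_voiced(fr)
  trk <- estimate_f0(fr, mask)
  expect_lt(abs(trk$f0_mean - 180), 1)

  # search band excluding the tone -> missing F0
  cfg <- extract_config(f0_min = 300, f0_max = 600)
  trk2 <- estimate_f0(fr, mask, cfg)
  expect_true(is.na(trk2$f0_mean))
})

test_that("compute_jitter equals the Praat local-jitter formula", {
  expect_equal(compute_jitter(rep(0.005, 50)), 0)

  # hand evaluation: periods 10,11,10,11 ms
  p <- c(10, 11, 10, 11) / 1000
  expect_equal(compute_jitter(p, scale = "ratio"), 1 / 10.5,
               tolerance = 1e-12)
  expect_equal(compute_jitter(p, scale = "percent"), 100 / 10.5,
               tolerance = 1e-12)

  # exact match with an independent one-line oracle on random sequences
  oracle <- function(t) (sum(abs(diff(t))) / (length(t) - 1)) / mean(t)
  set.seed(8)
  for (i in 1:20) {
    t <- abs(rnorm(sample(2:200, 1), 5e-3, 1e-4))
    expect_equal(compute_jitter(t, scale = "ratio"), oracle(t),
                 tolerance = 1e-14)
  }

  expect_true(is.na(compute_jitter(numeric(0))))
  expect_true(is.na(compute_jitter(0.005)))
})

test_that("formant estimation recovers planted resonances", {
  v1 <- synthesize_vowel(voice_params(formants = list(c(500, 80),
                                                      c(2000, 120),
                                                      c(2900, 200))),
                         seed = 21)
  fr <- preprocess(v1)
  fm <- estimate_formants(fr, detect_voiced(fr))
  expect_lt(abs(fm$f1f2 - 0.25) / 0.25, 0.05)

  v2 <- synthesize_vowel(voice_params(formants = list(c(700, 90),
                                                      c(1200, 110),
                                                      c(2900, 200))),
                         seed = 22)
  fr2 <- preprocess(v2)
  fm2 <- estimate_formants(fr2, detect_voiced(fr2))
  expect_lt(abs(fm2$f1 - 700) / 700, 0.05)
  expect_lt(abs(fm2$f2 - 1200) / 1200, 0.05)

  # white noise: mostly unvoiced, low-confidence formants
  set.seed(23)
  fn <- preprocess(audio_signal(rnorm(22050) * 0.1, 22050))
  res <- estimate_formants(fn, detect_voiced(fn))
  expect_true(res$low_confidence)
})

test_that("intensity follows the dB laws", {
  sr <- 22050
  square <- audio_signal(rep(c(1, -1), each = 64, length.out = sr), sr)
  fr <- preprocess(square, extract_config(trim_db = NULL))
  expect_equal(compute_intensity(fr, offset_db = 0), 0, tolerance = 1e-9)

  half <- audio_signal(square$samples / 2, sr)
  frh <- preprocess(half, extract_config(trim_db = NULL))
  expect_equal(compute_intensity(fr, offset_db = 0) -
                 compute_intensity(frh, offset_db = 0),
               20 * log10(2), tolerance = 1e-9)

  # gain equivariance on a vowel, and jitter / F1-F2 gain invariance
  v <- synthesize_vowel(voice_params(duration_s = 2), seed = 31)
  g <- 2.5
  vg <- audio_signal(v$samples * g, v$sample_rate)
  cfg <- extract_config(trim_db = NULL)
  f1 <- preprocess(v, cfg); f2 <- preprocess(vg, cfg)
  expect_equal(compute_intensity(f2, cfg) - compute_intensity(f1, cfg),
               20 * log10(g), tolerance = 1e-6)
  m1 <- detect_voiced(f1, cfg); m2 <- detect_voiced(f2, cfg)
  expect_equal(compute_jitter(estimate_f0(f1, m1, cfg)),
               compute_jitter(estimate_f0(f2, m2, cfg)), tolerance = 1e-6)
  expect_equal(estimate_formants(f1, m1, config = cfg)$f1f2,
               estimate_formants(f2, m2, config = cfg)$f1f2,
               tolerance = 1e-6)
})

test_that("speech rate follows the vowel-group heuristic and annotations", {
  expect_equal(count_syllables("hello world"), 3)
  expect_equal(compute_speech_rate("hello world", 3), 1.0)
  expect_warning(r0 <- compute_speech_rate("", 3), "empty")
  expect_equal(r0, 0)
  expect_equal(compute_speech_rate(list(n_syllables = 12), 9.5), 12 / 9.5)
})

test_that("extract_features composes all extractors with flagged missing", {
  v <- synthesize_vowel(voice_params(syllable_rate = 1.26, duration_s = 5),
                        seed = 41)
  row <- extract_features(v)
  expect_true(all(is.finite(as.numeric(row[1, ]))))
  expect_length(attr(row, "flags"), 0)

  # silence with trimming disabled: voiced features flagged missing and
  # intensity pinned to the configured floor
  silence <- audio_signal(rep(0, 22050), 22050)
  cfg <- extract_config(trim_db = NULL)
  row2 <- suppressWarnings(extract_features(silence, cfg))
  expect_true(is.na(row2$f0))
  expect_true(is.na(row2$jitter))
  expect_true(all(c("f0", "jitter", "speech_rate") %in% attr(row2, "flags")))
  expect_equal(row2$intensity, cfg$intensity_floor_db)
})

test_that("planted and recovered jitter agree in rank across a sweep", {
  planted <- seq(0, 2, length.out = 20)
  est <- numeric(20)
  for (i in seq_along(planted)) {
    s <- synthesize_vowel(voice_params(jitter_pct = planted[i],
                                       duration_s = 2), seed = 200 + i)
    fr <- preprocess(s)
    est[i] <- compute_jitter(estimate_f0(fr, detect_voiced(fr)))
  }
  expect_gte(cor(planted, est, method = "spearman"), 0.9)
})
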