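test_that("build_precision plants exact partial correlations", {
  # empty graph -> identity
  K <- build_precision(list(), p = 5)
  expect_equal(K$matrix, diag(5))

  # single edge, verified by hand 2x2 inversion:
  # K = [[1, -r], [-r, 1]] => pcor = -K12/sqrt(K11 K22) = r
  K2 <- build_precision(list(list(1, 2, 0.5)), p = 2)
  W <- precision_to_pcor(K2)
  expect_equal(W[1, 2], 0.5, tolerance = 1e-10)

  # the published high-anxiety edge set round-trips within 1e-6
  Kh <- build_precision(study_edges("high"), labels = speech_vars)
  Wh <- precision_to_pcor(Kh)
  expect_equal(Wh["speech_rate", "intensity"], 0.28, tolerance = 1e-6)
  expect_equal(Wh["intensity", "f1f2"], 0.33, tolerance = 1e-6)
  expect_equal(Wh["f1f2", "f0"], 0.20, tolerance = 1e-6)
  expect_equal(Wh["jitter", "f0"], -0.39, tolerance = 1e-6)
  ev <- eigen(Kh$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  # unrealizable edge sets fail loudly: three pairwise partials of +0.95
  # admit no PD concentration matrix
  expect_error(build_precision(list(list(1, 2, 0.95), list(2, 3, 0.95),
                                    list(1, 3, 0.95)), p = 3),
               "positive-definite")
  expect_error(build_precision(list(list(1, 1, 0.5)), p = 3), "invalid edge")
  expect_error(build_precision(list(list(1, 2, 1.2)), p = 3), "< 1")
})

test_that("generate_feature_table matches marginals and is reproducible", {
  sp <- study_group_specs()$high
  tab <- generate_feature_table(sp, seed = 11)
  expect_equal(nrow(tab), 197)
  # sample means within 3 SE of Table-1 targets
  for (v in speech_vars) {
    se <- sp$marginal_sds[[v]] / sqrt(197)
    expect_lt(abs(mean(tab[[v]]) - sp$marginal_means[[v]]), 3 * se)
  }
  expect_true(all(tab$anxiety %in% 2:3))

  # same seed identical, different seed different
  expect_identical(tab, generate_feature_table(sp, seed = 11))
  expect_false(identical(tab, generate_feature_table(sp, seed = 12)))
})

test_that("independent columns show only null-level Spearman correlation", {
  tab <- generate_feature_table(null_spec(400), seed = 3)
  S <- spearman_matrix(tab, speech_vars)
  off <- S$matrix[upper.tri(S$matrix)]
  # null sampling band ~ 3.3/sqrt(n) for each of the 10 pairs
  expect_lt(max(abs(off)), 3.3 / sqrt(400))
})

test_that("planted partial correlations are recovered at large n", {
  sp <- study_group_specs()$high
  sp$n <- 5000L
  tab <- generate_feature_table(sp, seed = 7)
  S <- spearman_matrix(tab, speech_vars)
  # Gaussian copula: Pearson rho = 2 sin(pi/6 * rho_S); partials from the
  # inverse of that matrix should approach the planted values
  P <- precision_to_pcor(solve(2 * sin(pi / 6 * S$matrix)))
  tgt <- precision_to_pcor(build_precision(study_edges("high"),
                                           labels = speech_vars))
  expect_lt(max(abs(P - tgt)), 0.05)
})

test_that("synthesized vowels carry self-consistent ground truth", {
  # unperturbed, undrifting train -> realized jitter exactly zero
  vp0 <- voice_params(jitter_pct = 0, f0_drift = 0, noise_db = -Inf,
                      aspiration_db = -Inf, duration_s = 2)
  s0 <- synthesize_vowel(vp0, seed = 1)
  expect_equal(attr(s0, "ground_truth")$jitter_pct, 0)

  # mean realized period within 0.5% of 1/f0
  vp <- voice_params(f0_hz = 180, duration_s = 3)
  s <- synthesize_vowel(vp, seed = 2)
  gt <- attr(s, "ground_truth")
  expect_lt(abs(mean(gt$periods_s) - 1 / 180) / (1 / 180), 0.005)

  # syllable events at the study's printed speech rate
  vs <- voice_params(syllable_rate = 1.26, duration_s = 10)
  ss <- synthesize_vowel(vs, seed = 3)
  expect_true(attr(ss, "ground_truth")$n_syllables %in% c(12, 13))

  # RMS of voiced samples within 0.5 dB of the target
  got <- 20 * log10(sqrt(mean(s$samples^2))) + vp$ref_offset_db
  expect_lt(abs(got - vp$rms_db), 0.5)

  # formant centers above Nyquist refuse before synthesis
  expect_error(voice_params(formants = list(c(500, 80), c(12000, 100)),
                            sample_rate = 22050), "Nyquist")

  # same seed -> identical samples
  expect_identical(synthesize_vowel(vp, seed = 9)$samples,
                   synthesize_vowel(vp, seed = 9)$samples)
})

test_that("each vocal-tract resonator peaks at its requested center", {
  sr <- 22050
  fms <- list(c(500, 80), c(2000, 120), c(2900, 200))
  nfft <- 8192
  f <- (0:(nfft / 2 - 1)) * sr / nfft
  z <- exp(-2i * pi * f / sr)
  bin <- sr / nfft
  for (fm in fms) {
    r <- exp(-pi * fm[2] / sr)
    th <- 2 * pi * fm[1] / sr
    mag <- Mod(1 / (1 - 2 * r * cos(th) * z + r^2 * z^2))
    pk <- f[which.max(mag)]
    expect_lt(abs(pk - fm[1]), bin + 1e-9)
  }
})
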