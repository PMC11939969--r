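#' Voice synthesis parameters
#'
#' Bundle of ground-truth parameters for [synthesize_vowel()]. The defaults
#' describe a vowel-like signal matching the scale of the study population
#' this package models: F0 near 180 Hz, local jitter 0.5%, F1/F2 = 0.25,
#' intensity about 67.5 dB (re the default calibration), and 1.26 syllables/s.
#'
#' @param f0_hz fundamental frequency in Hz (> 0).
#' @param jitter_pct target cycle-to-cycle period perturbation, in percent of
#'   the mean period (>= 0). The period noise is i.i.d. Gaussian with
#'   `sd = jitter_pct/100 * sqrt(pi)/2`, so that the expected Praat-style
#'   local jitter equals `jitter_pct`.
#' @param formants list of `c(center_hz, bandwidth_hz)` resonances, at least
#'   two, centers strictly increasing and below Nyquist.
#' @param rms_db target intensity in dB re the calibration reference (see
#'   `ref_offset_db`); measured over the voiced (envelope-on) samples.
#' @param syllable_rate amplitude-modulation events per second; 0 disables
#'   modulation (continuous voicing).
#' @param f0_drift fractional peak-to-peak F0 declination across the
#'   utterance (linear, centered on `f0_hz`); natural speech drifts
#'   downward over a breath group, and the drift also sweeps harmonics
#'   across the formant peaks instead of sampling them at fixed points.
#' @param noise_db white measurement-noise floor added after the vocal-tract
#'   filter, relative to the signal RMS in dB; `-Inf` for a noiseless signal.
#' @param aspiration_db aspiration (turbulence) noise level relative to the
#'   unit glottal-pulse amplitude in dB, mixed in before the vocal-tract
#'   filter; `-Inf` disables it. Aspiration fills the spectrum between
#'   harmonics the way breathy excitation does in real voices.
#' @param duration_s signal length in seconds (> 0).
#' @param sample_rate sampling rate in Hz.
#' @param ref_offset_db calibration offset such that
#'   `rms_db = 20*log10(rms) + ref_offset_db`; the default 94 puts a
#'   full-scale sine near 91 dB.
#' @return an object of class `voice_params`.
#' @export
voice_params <- function(f0_hz = 180, jitter_pct = 0.5,
                         formants = list(c(500, 80), c(2000, 120), c(2900, 200)),
                         rms_db = 67.5, syllable_rate = 0, f0_drift = 0.08,
                         noise_db = -50, aspiration_db = -46,
                         duration_s = 3, sample_rate = 22050,
                         ref_offset_db = 94) {
  stopifnot(f0_hz > 0, jitter_pct >= 0, duration_s > 0, sample_rate > 0,
            length(formants) >= 2)
  centers <- vapply(formants, `[`, numeric(1), 1L)
  if (any(diff(centers) <= 0))
    stop("formant centers must be strictly increasing")
  if (any(centers >= sample_rate / 2))
    stop("formant center at or above Nyquist (", sample_rate / 2, " Hz): ",
         paste(centers[centers >= sample_rate / 2], collapse = ", "))
  structure(list(f0_hz = f0_hz, jitter_pct = jitter_pct, formants = formants,
                 rms_db = rms_db, syllable_rate = syllable_rate,
                 f0_drift = f0_drift,
                 noise_db = noise_db, aspiration_db = aspiration_db,
                 duration_s = duration_s,
                 sample_rate = sample_rate, ref_offset_db = ref_offset_db),
            class = "voice_params")
}

#' Synthesize a vowel-like signal with known ground truth
#'
#' Source-filter synthesis: a glottal impulse train with period
#' `T_i = (1/f0) * (1 + eps_i)` (`eps_i` i.i.d. Gaussian, calibrated so the
#' expected local jitter equals `jitter_pct`), filtered through cascaded
#' two-pole resonators at the requested formants, amplitude-modulated at
#' `syllable_rate` with silent gaps, scaled to `rms_db` over the voiced
#' samples, with white noise added at `noise_db`. Impulses are placed with
#' sub-sample (linearly interpolated) timing so the realized period sequence
#' is not quantized to the sample grid.
#'
#' @param params a [voice_params()] object.
#' @param seed integer seed; the same seed reproduces the signal exactly.
#' @return an `audio_signal` (see [audio_signal()]) with attribute
#'   `ground_truth`: a list with `periods_s` (realized period sequence),
#'   `jitter_pct` (realized local jitter of that sequence, percent),
#'   `syllable_onsets_s`, `n_syllables`, and the input `params`.
#' @export
synthesize_vowel <- function(params, seed = 1L) {
  stopifnot(inherits(params, "voice_params"))
  set.seed(as.integer(seed))
  sr <- params$sample_rate
  n <- round(params$duration_s * sr)
  t0 <- 1 / params$f0_hz
  sig_eps <- params$jitter_pct / 100 * sqrt(pi) / 2

  # realized (continuous-time) period sequence: linear F0 declination
  # (+drift/2 at onset to -drift/2 at the end) with i.i.d. Gaussian
  # cycle-to-cycle perturbation calibrated to the target local jitter
  n_per <- ceiling(params$duration_s / t0 * (1 + params$f0_drift)) + 8L
  eps <- rnorm(n_per, 0, sig_eps)
  dur <- params$duration_s
  epochs <- numeric(n_per + 1L)
  periods <- numeric(n_per)
  tcur <- 0.25 * t0
  epochs[1] <- tcur
  np <- 0L
  for (i in seq_len(n_per)) {
    f0t <- params$f0_hz *
      (1 + params$f0_drift * (0.5 - min(1, tcur / dur)))
    Ti <- max(0.2 * t0, (1 / f0t) * (1 + eps[i]))
    if (tcur + Ti >= dur - 1 / sr) break
    np <- i
    periods[i] <- Ti
    tcur <- tcur + Ti
    epochs[i + 1L] <- tcur
  }
  periods <- periods[seq_len(np)]
  epochs <- epochs[seq_len(np + 1L)]

  # fractional-position impulse train
  x <- numeric(n)
  pos <- epochs * sr + 1
  i0 <- floor(pos)
  frac <- pos - i0
  ok <- i0 >= 1 & i0 < n
  x[i0[ok]] <- x[i0[ok]] + (1 - frac[ok])
  x[i0[ok] + 1] <- x[i0[ok] + 1] + frac[ok]

  # aspiration noise feeds the vocal tract together with the pulses
  # (level relative to the unit glottal-pulse amplitude); glottal
  # turbulence sits above the pitch range, so the noise is high-passed
  # near 400 Hz to leave the fundamental region clean
  if (is.finite(params$aspiration_db)) {
    asp <- rnorm(n)
    k <- max(2L, round(sr / 400))
    asp <- asp - as.numeric(stats::filter(asp, rep(1 / k, k),
                                          method = "convolution",
                                          sides = 2, circular = TRUE))
    asp <- asp / sd(asp)
    x <- x + 10^(params$aspiration_db / 20) * asp
  }

  # glottal spectral shaping: one real pole at 0.97 tilts the source
  # spectrum downward the way voiced excitation rolls off (and is exactly
  # undone by the 0.97 pre-emphasis of the analysis chain)
  x <- as.numeric(stats::filter(x, 0.97, method = "recursive"))

  # cascaded two-pole resonators
  for (fm in params$formants) {
    r <- exp(-pi * fm[2] / sr)
    th <- 2 * pi * fm[1] / sr
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r * r),
                                  method = "recursive"))
  }

  # syllable envelope: trapezoid with raised-cosine ramps, 65% duty cycle
  onsets <- numeric(0)
  n_syl <- 0L
  env <- rep(1, n)
  if (params$syllable_rate > 0) {
    t_syl <- 1 / params$syllable_rate
    on_s <- 0.65 * t_syl
    ramp <- round(0.1 * on_s * sr)
    on_n <- round(on_s * sr)
    env <- rep(0, n)
    k <- 0L
    repeat {
      start <- round(k * t_syl * sr) + 1
      if (start > n) break
      idx <- start:min(n, start + on_n - 1)
      w <- rep(1, length(idx))
      if (ramp > 1) {
        up <- seq_len(min(ramp, length(idx)))
        w[up] <- 0.5 * (1 - cos(pi * (up - 1) / ramp))
        dn <- seq.int(length(idx), by = -1, length.out = min(ramp, length(idx)))
        w[dn] <- pmin(w[dn], 0.5 * (1 - cos(pi * (seq_along(dn) - 1) / ramp)))
      }
      env[idx] <- w
      onsets <- c(onsets, (start - 1) / sr)
      n_syl <- n_syl + 1L
      k <- k + 1L
    }
  }
  x <- x * env

  # scale the voiced region to the target RMS
  active <- env > 0.5
  if (!any(active)) active <- rep(TRUE, n)
  target <- 10^((params$rms_db - params$ref_offset_db) / 20)
  cur <- sqrt(mean(x[active]^2))
  if (cur > 0) x <- x * target / cur

  if (is.finite(params$noise_db)) {
    x <- x + rnorm(n, 0, target * 10^(params$noise_db / 20))
  }
  if (max(abs(x)) > 1)
    warning("synthesized signal exceeds full scale; 16-bit export will clip")

  jit <- if (length(periods) >= 2) {
    100 * mean(abs(diff(periods))) / mean(periods)
  } else NA_real_
  out <- audio_signal(x, sr)
  attr(out, "ground_truth") <- list(
    periods_s = periods, jitter_pct = jit,
    syllable_onsets_s = onsets, n_syllables = n_syl,
    params = params, seed = as.integer(seed))
  out
}

#' Construct a precision matrix with planted partial correlations
#'
#' Builds the standardized concentration matrix `K = I - P`, where `P` holds
#' the requested partial correlations on the listed node pairs. A symmetric
#' positive-definite `K` with exactly those partial correlations exists if
#' and only if this standardized form is positive definite, since any valid
#' concentration matrix factors as `D^{1/2} K D^{1/2}` with positive `D`
#' (which leaves the partial correlations unchanged).
#'
#' @param edges list of `list(i, j, pcor)` (or a 3-column data.frame); node
#'   indices 1-based, or node names matching `labels`; `|pcor| < 1`.
#' @param p number of nodes (ignored when `labels` given).
#' @param labels optional node names.
#' @return a `precision_matrix`: list with `matrix` and `labels`.
#' @export
build_precision <- function(edges, p = NULL, labels = NULL) {
  if (is.null(labels)) {
    stopifnot(!is.null(p))
    labels <- paste0("V", seq_len(p))
  }
  p <- length(labels)
  K <- diag(p)
  if (is.data.frame(edges)) {
    edges <- lapply(seq_len(nrow(edges)), function(r) as.list(edges[r, ]))
  }
  for (e in edges) {
    i <- e[[1]]; j <- e[[2]]; w <- as.numeric(e[[3]])
    if (is.character(i)) i <- match(i, labels)
    if (is.character(j)) j <- match(j, labels)
    if (is.na(i) || is.na(j) || i == j)
      stop("invalid edge: ", paste(unlist(e), collapse = " "))
    if (abs(w) >= 1) stop("|partial correlation| must be < 1 for edge ",
                          labels[i], "-", labels[j])
    K[i, j] <- K[j, i] <- -w
  }
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    stop("no positive-definite concentration matrix realizes the requested ",
         "partial correlations (min eigenvalue ", signif(min(ev), 3),
         "); offending edge set: ",
         paste(vapply(edges, function(e) paste0(e[[1]], "-", e[[2]], "=",
                                                e[[3]]), ""), collapse = ", "))
  }
  structure(list(matrix = K, labels = labels), class = "precision_matrix")
}

#' Two-group sampling specification for the feature-table generator
#'
#' @param label group name (e.g. "low", "high").
#' @param n sample size (>= 1).
#' @param marginal_means,marginal_sds named per-variable mean and SD for the
#'   continuous features (names from `jitter, f0, f1f2, intensity,
#'   speech_rate`); SDs must be positive.
#' @param edges planted partial-correlation edges, as for [build_precision()],
#'   using variable names (the name `anxiety` refers to the latent node that
#'   is discretized into the ordinal rating).
#' @param rating_probs probability vector over the ordinal anxiety ratings
#'   0..3; must sum to 1.
#' @return a `group_spec` object.
#' @export
group_spec <- function(label, n, marginal_means, marginal_sds, edges,
                       rating_probs) {
  stopifnot(n >= 1, all(marginal_sds > 0),
            length(rating_probs) == 4, all(rating_probs >= 0))
  if (abs(sum(rating_probs) - 1) > 1e-8)
    stop("rating_probs must sum to 1")
  if (sum(rating_probs > 0) == 1)
    warning("degenerate rating_probs: all mass on a single rating category")
  stopifnot(setequal(names(marginal_means), names(marginal_sds)))
  structure(list(label = label, n = as.integer(n),
                 marginal_means = marginal_means,
                 marginal_sds = marginal_sds,
                 edges = edges, rating_probs = rating_probs),
            class = "group_spec")
}

#' Generate a feature table from a planted Gaussian graphical model
#'
#' Draws the continuous features from the multivariate normal implied by
#' [build_precision()] on the group specification's edges, rescales each
#' column to the
#' requested marginal mean/SD (an affine map, which leaves rank correlations
#' untouched), and produces the ordinal anxiety rating by quantile-cutting
#' the latent `anxiety` node (the node coupled to jitter when such an edge is
#' planted; an independent latent otherwise) at the cumulative
#' `rating_probs`.
#'
#' @param spec a [group_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return a data.frame with columns `jitter, f0, f1f2, intensity,
#'   speech_rate, anxiety, group`.
#' @export
generate_feature_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(as.integer(seed))
  feats <- .vocanet_speech_vars
  stopifnot(all(feats %in% names(spec$marginal_means)))
  uses_anx <- any(vapply(spec$edges, function(e)
    any(c(e[[1]], e[[2]]) == "anxiety"), logical(1)))
  labels <- if (uses_anx) c("anxiety", feats) else feats
  K <- build_precision(spec$edges, labels = labels)
  Sigma <- solve(K$matrix)
  R <- stats::cov2cor(Sigma)
  Z <- matrix(rnorm(spec$n * length(labels)), spec$n) %*% chol(R)
  colnames(Z) <- labels
  out <- data.frame(row.names = seq_len(spec$n))
  for (v in feats) {
    out[[v]] <- spec$marginal_means[[v]] + spec$marginal_sds[[v]] * Z[, v]
  }
  z_anx <- if (uses_anx) Z[, "anxiety"] else rnorm(spec$n)
  cuts <- qnorm(pmin(1, pmax(0, cumsum(spec$rating_probs)))[1:3])
  out$anxiety <- findInterval(z_anx, cuts)
  out$group <- spec$label
  out
}

#' Reference descriptive statistics of the modeled study
#'
#' Per-group means and SDs of the anxiety rating and the five acoustic
#' parameters for the study population this package emulates (low-anxiety
#' n = 119, high-anxiety n = 197), together with the published pooled-SD
#' Cohen's d values. These are the marginals the synthetic generator
#' reproduces.
#'
#' @return a data.frame with one row per variable.
#' @export
table1_reference <- function() {
  data.frame(
    variable = c("anxiety", "jitter", "f0", "f1f2", "intensity",
                 "speech_rate"),
    mean_total = c(1.83, 0.50, 181.88, 0.25, 67.54, 1.26),
    sd_total = c(1.01, 0.07, 18.53, 0.05, 5.64, 0.57),
    mean_low = c(0.70, 0.51, 179.20, 0.25, 67.78, 1.26),
    sd_low = c(0.46, 0.06, 18.70, 0.06, 5.41, 0.61),
    mean_high = c(2.51, 0.49, 183.49, 0.25, 67.40, 1.26),
    sd_high = c(0.50, 0.08, 18.29, 0.05, 5.78, 0.55),
    n_low = 119L, n_high = 197L,
    d_published = c(-3.731, 0.229, -0.232, 0.145, 0.068, 0.000),
    stringsAsFactors = FALSE)
}

#' Planted edge sets of the study networks
#'
#' The total network couples the anxiety rating to jitter (-0.17) with four
#' speech-speech edges; the high-anxiety network includes the
#' intensity-F1/F2 coupling (0.33) that the low-anxiety network lacks. The
#' low-anxiety F1/F2-F0 weight (0.30) is implied by the published global
#' expected influence (sum of edge weights 0.19) together with the F1/F2
#' expected-influence maximum (0.30).
#'
#' @param which one of "total", "high", "low".
#' @return list of `list(i, j, pcor)` edges on named nodes.
#' @export
study_edges <- function(which = c("total", "high", "low")) {
  switch(match.arg(which),
    total = list(list("anxiety", "jitter", -0.17),
                 list("jitter", "f0", -0.39),
                 list("speech_rate", "intensity", 0.28),
                 list("intensity", "f1f2", 0.26),
                 list("f1f2", "f0", 0.24)),
    high = list(list("speech_rate", "intensity", 0.28),
                list("intensity", "f1f2", 0.33),
                list("f1f2", "f0", 0.20),
                list("jitter", "f0", -0.39)),
    low = list(list("speech_rate", "intensity", 0.28),
               list("f1f2", "f0", 0.30),
               list("jitter", "f0", -0.39)))
}

#' Group specifications mirroring the modeled study
#'
#' Low-anxiety (n = 119, ratings 0-1) and high-anxiety (n = 197, ratings
#' 2-3) groups with the reference marginals of [table1_reference()] and the
#' planted topologies of [study_edges()]. The rating probabilities follow
#' from the printed rating means/SDs: 0.70 +/- 0.46 is a 30/70 split over
#' {0,1} and 2.51 +/- 0.50 a 49/51 split over {2,3}.
#'
#' @return named list with `low` and `high` [group_spec()]s.
#' @export
study_group_specs <- function() {
  t1 <- table1_reference()
  feats <- .vocanet_speech_vars
  gm <- function(col) stats::setNames(t1[[col]][match(feats, t1$variable)], feats)
  list(
    low = group_spec("low", 119, gm("mean_low"), gm("sd_low"),
                     study_edges("low"), c(0.30, 0.70, 0, 0)),
    high = group_spec("high", 197, gm("mean_high"), gm("sd_high"),
                      study_edges("high"), c(0, 0, 0.49, 0.51)))
}
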