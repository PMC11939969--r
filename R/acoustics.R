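#' Extraction configuration
#'
#' Settings for the acoustic feature extractors. The framing defaults
#' (Hamming window of 512 samples, 50% overlap, 0.97 pre-emphasis) match a
#' 22.05 kHz analysis rate, where 512 samples span about 23 ms.
#'
#' @param window_len analysis window length in samples.
#' @param hop hop size in samples (default `window_len / 2`).
#' @param pre_emphasis first-order pre-emphasis coefficient.
#' @param trim_db leading/trailing silence-trim threshold in dB relative to
#'   the loudest short-term frame; `NULL` disables trimming.
#' @param f0_min,f0_max F0 search band in Hz.
#' @param energy_quantile voicing energy gate: quantile of frame RMS.
#' @param energy_rel_floor relative energy floor (fraction of the maximum
#'   frame RMS) that caps the energy gate, so that uniformly voiced signals
#'   are not thinned by the quantile rule.
#' @param periodicity_min minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @param lpc_order LPC model order for formant estimation.
#' @param formant_min_hz,formant_max_bw candidate formant filter: minimum
#'   center frequency and maximum bandwidth in Hz.
#' @param jitter_scale `"percent"` or `"ratio"` reporting scale for local
#'   jitter.
#' @param intensity_offset_db calibration offset added to dB re full scale;
#'   the default 94 puts a full-scale sine near 91 dB and conversational
#'   speech near 67 dB.
#' @param intensity_rel_floor_db frames whose RMS falls below this many dB
#'   of the 95th-percentile frame RMS are excluded from the intensity
#'   average (this drops pauses and syllable-boundary part-frames).
#' @param intensity_floor_db returned intensity when every frame is silent.
#' @param rate_denominator `"full"` (whole recording) or `"speech"`
#'   (trimmed duration) as the speech-rate denominator.
#' @return an `extract_config` list.
#' @export
extract_config <- function(window_len = 512, hop = window_len / 2,
                           pre_emphasis = 0.97, trim_db = -40,
                           f0_min = 75, f0_max = 400,
                           energy_quantile = 0.3, energy_rel_floor = 0.1,
                           periodicity_min = 0.45,
                           lpc_order = 12, formant_min_hz = 90,
                           formant_max_bw = 400,
                           jitter_scale = c("percent", "ratio"),
                           intensity_offset_db = 94,
                           intensity_rel_floor_db = -10,
                           intensity_floor_db = -120,
                           rate_denominator = c("full", "speech")) {
  structure(list(window_len = as.integer(window_len), hop = as.integer(hop),
                 pre_emphasis = pre_emphasis, trim_db = trim_db,
                 f0_min = f0_min, f0_max = f0_max,
                 energy_quantile = energy_quantile,
                 energy_rel_floor = energy_rel_floor,
                 periodicity_min = periodicity_min,
                 lpc_order = as.integer(lpc_order),
                 formant_min_hz = formant_min_hz,
                 formant_max_bw = formant_max_bw,
                 jitter_scale = match.arg(jitter_scale),
                 intensity_offset_db = intensity_offset_db,
                 intensity_rel_floor_db = intensity_rel_floor_db,
                 intensity_floor_db = intensity_floor_db,
                 rate_denominator = match.arg(rate_denominator)),
            class = "extract_config")
}

.frame_matrix <- function(x, win, hop) {
  n_frames <- 1L + (length(x) - win) %/% hop
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], nrow = win)
}

#' Pre-emphasize, trim, and frame a signal
#'
#' Applies first-order pre-emphasis `y[t] = x[t] - a*x[t-1]`, trims leading
#' and trailing silence by a short-term energy gate, and cuts the signal
#' into Hamming frames. Both the raw (trimmed, un-emphasized) and
#' pre-emphasized frames are kept: intensity and periodicity work on the raw
#' waveform, spectral-envelope (LPC) analysis on the emphasized one.
#'
#' @param signal an [audio_signal()].
#' @param config an [extract_config()].
#' @return a `frame_set` list: raw/emphasized frame matrices (window
#'   length x n_frames), the window taper, framing metadata, trimmed
#'   signals, and both full and trimmed durations.
#' @export
preprocess <- function(signal, config = extract_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  sr <- signal$sample_rate
  duration_full <- length(x) / sr
  if (!is.null(config$trim_db)) {
    w <- max(16L, round(0.010 * sr))
    h <- max(8L, w %/% 2L)
    if (length(x) >= w) {
      fr <- .frame_matrix(x, w, h)
      rms <- sqrt(colMeans(fr^2))
      thr <- max(rms) * 10^(config$trim_db / 20)
      keep <- which(rms > thr)
      if (length(keep) == 0) stop("signal is silent after energy trimming")
      a <- (keep[1] - 1L) * h + 1L
      b <- min(length(x), (keep[length(keep)] - 1L) * h + w)
      x <- x[a:b]
    }
  }
  if (length(x) < config$window_len)
    stop("signal shorter than one analysis window (", config$window_len,
         " samples) after trimming")
  a <- config$pre_emphasis
  y <- c(x[1] * (1 - a), x[-1] - a * x[-length(x)])
  win <- config$window_len
  taper <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  structure(list(frames_raw = .frame_matrix(x, win, config$hop),
                 frames_emph = .frame_matrix(y, win, config$hop),
                 window = taper, window_len = win, hop = config$hop,
                 pre_emphasis = a, sample_rate = sr,
                 signal_raw = x, signal_emph = y,
                 duration_full_s = duration_full,
                 duration_trimmed_s = length(x) / sr),
            class = "frame_set")
}

# moving-average low-pass (first null near 400 Hz) applied before
# periodicity analysis, the usual guard against high-frequency noise and
# formant ringing in F0 tracking
.lp_for_f0 <- function(x, sr) {
  k <- max(1L, round(sr / 400))
  if (k == 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), method = "convolution",
                           sides = 2, circular = TRUE))
}

# normalized autocorrelation over a lag band, via FFT; returns the full
# normalized autocorrelation vector (lag 0..nmax)
.autocorr <- function(frame, lmax) {
  x <- frame - mean(frame)
  n <- length(x)
  m <- stats::nextn(n + lmax + 1, 2)
  X <- stats::fft(c(x, numeric(m - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(lmax + 1)]
  if (r[1] <= 0) return(rep(NA_real_, lmax + 1))
  r / r[1]
}

# peak of r within [lmin, lmax] with parabolic interpolation
.ac_peak <- function(r, lmin, lmax) {
  lags <- (lmin:lmax) + 1L
  seg <- r[lags]
  if (all(is.na(seg))) return(list(lag = NA_real_, value = NA_real_))
  k <- which.max(seg)
  lag <- lmin + k - 1L
  val <- seg[k]
  if (lag > 1 && (lag + 2L) <= length(r)) {
    y1 <- r[lag]; y2 <- r[lag + 1L]; y3 <- r[lag + 2L]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > 1e-12) {
      d <- 0.5 * (y1 - y3) / den
      if (abs(d) <= 1) {
        lag <- lag + d
        val <- y2 - 0.25 * (y1 - y3) * d
      }
    }
  }
  list(lag = lag, value = val)
}

#' Voicing detection
#'
#' A frame is voiced when its RMS clears the energy gate (the
#' `energy_quantile` quantile of frame RMS, capped at `energy_rel_floor`
#' times the maximum frame RMS) and its normalized autocorrelation peak in
#' the F0 search band reaches `periodicity_min`.
#'
#' @param frames a [preprocess()] frame set.
#' @param config an [extract_config()].
#' @return logical voicing mask, one element per frame.
#' @export
detect_voiced <- function(frames, config = extract_config()) {
  stopifnot(inherits(frames, "frame_set"))
  sr <- frames$sample_rate
  rms <- sqrt(colMeans(frames$frames_raw^2))
  thr <- min(quantile(rms, config$energy_quantile),
             config$energy_rel_floor * max(rms))
  lmin <- max(2L, floor(sr / config$f0_max))
  lmax <- min(frames$window_len - 1L, ceiling(sr / config$f0_min))
  peak <- apply(frames$frames_raw, 2, function(f) {
    r <- .autocorr(.lp_for_f0(f, sr), lmax)
    .ac_peak(r, lmin, lmax)$value
  })
  as.logical(rms >= thr & !is.na(peak) & peak >= config$periodicity_min)
}

#' Frame-level F0 and cycle-level period estimation
#'
#' Per voiced frame, F0 is the sample rate over the interpolated argmax of
#' the normalized autocorrelation inside `[f0_min, f0_max]`. The
#' cycle-to-cycle period sequence (for jitter) is then refined from glottal
#' epochs: the pre-emphasized signal is inverse-filtered with an LPC model
#' to sharpen excitation impulses, residual peaks are picked at least 0.65
#' mean periods apart, and peak positions are parabolically interpolated to
#' sub-sample precision.
#'
#' @param frames a [preprocess()] frame set.
#' @param mask logical voicing mask from [detect_voiced()].
#' @param config an [extract_config()].
#' @return an `f0_track`: list with `f0_frame` (per-frame Hz, `NA` where
#'   unvoiced or no peak), `mask`, `f0_mean`, and `periods_s`.
#' @export
estimate_f0 <- function(frames, mask, config = extract_config()) {
  stopifnot(inherits(frames, "frame_set"), length(mask) == ncol(frames$frames_raw))
  sr <- frames$sample_rate
  stopifnot(config$f0_min < config$f0_max, config$f0_max < sr / 2)
  lmin <- max(2L, floor(sr / config$f0_max))
  lmax <- min(frames$window_len - 1L, ceiling(sr / config$f0_min))
  f0 <- rep(NA_real_, length(mask))
  for (i in which(mask)) {
    r <- .autocorr(.lp_for_f0(frames$frames_raw[, i], sr), lmax)
    pk <- .ac_peak(r, lmin, lmax)
    if (!is.na(pk$value) && pk$value >= config$periodicity_min)
      f0[i] <- sr / pk$lag
  }
  f0_mean <- if (any(!is.na(f0))) mean(f0, na.rm = TRUE) else NA_real_
  periods <- numeric(0)
  if (is.finite(f0_mean)) {
    periods <- .epoch_periods(frames, mask, f0_mean, config)
  }
  structure(list(f0_frame = f0, mask = mask, f0_mean = f0_mean,
                 periods_s = periods), class = "f0_track")
}

# cycle marker picking on the low-passed waveform: near the fundamental
# the signal is a jittered sinusoid with high SNR, so one positive peak
# marks each glottal cycle
.epoch_periods <- function(frames, mask, f0_mean, config) {
  sr <- frames$sample_rate
  if (!any(mask)) return(numeric(0))
  # double moving average with null near 1.5 * f0: suppresses every
  # harmonic above the fundamental, so exactly one peak marks each cycle
  k <- max(2L, round(sr / (1.5 * f0_mean)))
  ma <- function(v) as.numeric(stats::filter(v, rep(1 / k, k),
                                             method = "convolution",
                                             sides = 2, circular = TRUE))
  e <- ma(ma(frames$signal_raw - mean(frames$signal_raw)))
  ae <- e
  L <- sr / f0_mean
  thr <- 0.3 * quantile(e, 0.95)
  n <- length(ae)
  cand <- which(ae > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[ae[cand] >= ae[cand - 1] & ae[cand] >= ae[cand + 1]]
  if (length(cand) < 3) return(numeric(0))
  # enforce minimum separation, preferring the larger peak
  keep <- integer(0)
  for (p in cand) {
    if (length(keep) == 0 || p - keep[length(keep)] >= 0.65 * L) {
      keep <- c(keep, p)
    } else if (ae[p] > ae[keep[length(keep)]]) {
      keep[length(keep)] <- p
    }
  }
  if (length(keep) < 3) return(numeric(0))
  # sub-sample period refinement: the lag maximizing the normalized local
  # cross-correlation between consecutive cycles of the full-band waveform
  # (whose sharp formant-ringing structure carries the timing), with
  # parabolic interpolation of the correlation peak
  xr <- frames$signal_raw - mean(frames$signal_raw)
  nr <- length(xr)
  per <- rep(NA_real_, length(keep) - 1L)
  for (k in seq_len(length(keep) - 1L)) {
    d0 <- keep[k + 1L] - keep[k]
    if (d0 < 0.7 * L || d0 > 1.3 * L) next
    h <- floor(0.6 * min(d0, L))
    lo <- keep[k] - h
    hi <- keep[k] + d0 + h + 5L
    if (h < 4 || lo < 1 || hi > nr) next
    s1 <- xr[(keep[k] - h):(keep[k] + h)]
    e1 <- sqrt(sum(s1^2))
    if (e1 == 0) next
    dl <- (d0 - 4L):(d0 + 4L)
    cc <- vapply(dl, function(d) {
      s2 <- xr[(keep[k] + d - h):(keep[k] + d + h)]
      e2 <- sqrt(sum(s2^2))
      if (e2 == 0) return(-Inf)
      sum(s1 * s2) / (e1 * e2)
    }, numeric(1))
    m <- which.max(cc)
    if (!is.finite(cc[m]) || cc[m] < 0.5 || m == 1 || m == length(cc)) next
    y1 <- cc[m - 1]; y2 <- cc[m]; y3 <- cc[m + 1]
    den <- y1 - 2 * y2 + y3
    adj <- if (abs(den) > 1e-12) max(-0.5, min(0.5, 0.5 * (y1 - y3) / den))
      else 0
    per[k] <- (dl[m] + adj) / sr
  }
  per <- per[!is.na(per)]
  # retain only plausible single-cycle intervals (gaps across pauses and
  # halving/doubling errors are excluded)
  per[per >= 1 / config$f0_max & per <= 1 / config$f0_min]
}

#' Local jitter
#'
#' Praat-style local jitter: the mean absolute difference of consecutive
#' periods divided by the mean period,
#' `[(1/(N-1)) * sum |T_i - T_{i-1}|] / [(1/N) * sum T_i]`.
#'
#' @param periods numeric period sequence in seconds (or an `f0_track`).
#' @param scale `"percent"` (x100) or `"ratio"`.
#' @return local jitter, or `NA` (flagged missing) with fewer than 2 periods.
#' @export
compute_jitter <- function(periods, scale = c("percent", "ratio")) {
  scale <- match.arg(scale)
  if (inherits(periods, "f0_track")) periods <- periods$periods_s
  if (length(periods) < 2) return(NA_real_)
  j <- mean(abs(diff(periods))) / mean(periods)
  if (scale == "percent") 100 * j else j
}

# Burg recursion: LPC coefficients a[1..p] of A(z) = 1 + sum a_k z^-k
# minimizing forward+backward prediction error (less spectral bias than the
# autocorrelation method on short frames; the method Praat uses for formants)
.burg <- function(f, p) {
  n <- length(f)
  if (n <= p + 1) stop("frame too short for LPC order ", p)
  fwd <- f[-1]
  bwd <- f[-n]
  a <- numeric(0)
  for (m in seq_len(p)) {
    den <- sum(fwd^2) + sum(bwd^2)
    if (den <= 0) break
    k <- -2 * sum(fwd * bwd) / den
    a <- c(a + k * rev(a), k)
    tmp <- fwd + k * bwd
    bwd <- (bwd + k * fwd)[seq_len(length(bwd) - 1L)]
    fwd <- tmp[-1]
  }
  a
}

# Levinson-Durbin recursion: autocorrelation r[0..p] -> LPC coefficients
# a[1..p] of A(z) = 1 + sum a_k z^-k
.levinson <- function(r) {
  p <- length(r) - 1L
  if (r[1] <= 0) stop("non-positive zero-lag autocorrelation")
  a <- numeric(p)
  err <- r[1]
  for (i in seq_len(p)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc + sum(a[1:(i - 1)] * r[i:2])
    k <- -acc / err
    new_a <- a
    new_a[i] <- k
    if (i > 1) new_a[1:(i - 1)] <- a[1:(i - 1)] + k * a[(i - 1):1]
    a <- new_a
    err <- err * (1 - k^2)
    if (err <= 0) break
  }
  a
}

#' LPC formant estimation
#'
#' Per voiced frame, a 12th-order (by default) LPC model is fit to the
#' pre-emphasized Hamming-windowed frame by Burg's method (the estimator
#' Praat uses for formant tracking; it carries less short-frame spectral
#' bias than the autocorrelation method). Candidate formants are the
#' complex roots of the LPC
#' polynomial with positive imaginary part, mapped to frequency
#' `angle * sr / (2*pi)` and bandwidth `-(sr/pi) * log |root|`; candidates
#' outside `[formant_min_hz, sr/2 - 50]` or wider than `formant_max_bw` are
#' rejected, and the two lowest surviving frequencies are F1 and F2.
#' Frame-wise values are averaged over voiced frames (frames with fewer
#' than two candidates are ignored).
#'
#' @param frames a [preprocess()] frame set.
#' @param mask logical voicing mask.
#' @param order LPC order.
#' @param config an [extract_config()].
#' @return list with `f1`, `f2`, `f1f2`, `n_frames_used`, and
#'   `low_confidence` (TRUE when under half the voiced frames yielded two
#'   candidates).
#' @export
estimate_formants <- function(frames, mask, order = NULL,
                              config = extract_config()) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(order)) order <- config$lpc_order
  stopifnot(order < frames$window_len)
  sr <- frames$sample_rate
  voiced <- which(mask)
  if (length(voiced) == 0)
    return(list(f1 = NA_real_, f2 = NA_real_, f1f2 = NA_real_,
                n_frames_used = 0L, low_confidence = TRUE))
  f1s <- f2s <- rep(NA_real_, length(voiced))
  for (k in seq_along(voiced)) {
    f <- frames$frames_emph[, voiced[k]] * frames$window
    a <- tryCatch(.burg(f, order), error = function(e) NULL)
    if (is.null(a) || length(a) < 2) next
    rts <- polyroot(c(rev(a), 1))
    rts <- rts[Im(rts) > 1e-8]
    fr <- Arg(rts) * sr / (2 * pi)
    bw <- -(sr / pi) * log(Mod(rts))
    ok <- fr >= config$formant_min_hz & fr <= sr / 2 - 50 &
      bw <= config$formant_max_bw & bw > 0
    fr <- sort(fr[ok])
    if (length(fr) >= 2) {
      f1s[k] <- fr[1]
      f2s[k] <- fr[2]
    }
  }
  used <- sum(!is.na(f1s))
  if (used == 0)
    return(list(f1 = NA_real_, f2 = NA_real_, f1f2 = NA_real_,
                n_frames_used = 0L, low_confidence = TRUE))
  f1 <- mean(f1s, na.rm = TRUE)
  f2 <- mean(f2s, na.rm = TRUE)
  list(f1 = f1, f2 = f2, f1f2 = f1 / f2, n_frames_used = used,
       low_confidence = used < 0.5 * length(voiced))
}

#' Frame-averaged intensity in dB
#'
#' The RMS of each raw (un-windowed, un-emphasized) frame is averaged over
#' frames above a relative floor (`intensity_rel_floor_db` of the
#' 95th-percentile frame RMS, so pauses and part-filled boundary frames do
#' not dilute the average), then converted to dB re full scale plus the
#' calibration offset.
#'
#' @param frames a [preprocess()] frame set.
#' @param config an [extract_config()].
#' @param offset_db overrides `config$intensity_offset_db` when given.
#' @return intensity in dB.
#' @export
compute_intensity <- function(frames, config = extract_config(),
                              offset_db = NULL) {
  stopifnot(inherits(frames, "frame_set"))
  if (is.null(offset_db)) offset_db <- config$intensity_offset_db
  rms <- sqrt(colMeans(frames$frames_raw^2))
  ref <- quantile(rms, 0.95)
  if (ref <= 0) return(config$intensity_floor_db)
  keep <- rms >= ref * 10^(config$intensity_rel_floor_db / 20)
  m <- mean(rms[keep])
  if (m <= 0) return(config$intensity_floor_db)
  20 * log10(m) + offset_db
}

#' Syllable count of a transcript
#'
#' Orthographic vowel-group heuristic: each maximal run of vowels
#' (`a e i o u y`) in a word counts one syllable, with a minimum of one
#' syllable per word.
#'
#' @param transcript character string.
#' @return integer syllable count.
#' @export
count_syllables <- function(transcript) {
  words <- unlist(strsplit(tolower(transcript), "[^a-z']+"))
  words <- words[nzchar(words)]
  if (length(words) == 0) return(0L)
  sum(vapply(words, function(w) {
    g <- gregexpr("[aeiouy]+", w)[[1]]
    max(1L, sum(g > 0))
  }, integer(1)))
}

#' Speech rate from a transcript or synthesis annotation
#'
#' @param annotation either a character transcript (syllables counted with
#'   [count_syllables()]) or a list with an `n_syllables` element (e.g. the
#'   `ground_truth` attribute of [synthesize_vowel()] output).
#' @param duration_s task duration in seconds (> 0).
#' @return syllables per second.
#' @export
compute_speech_rate <- function(annotation, duration_s) {
  stopifnot(duration_s > 0)
  n <- if (is.character(annotation)) {
    count_syllables(annotation)
  } else if (is.list(annotation) && !is.null(annotation$n_syllables)) {
    annotation$n_syllables
  } else {
    stop("annotation must be a transcript string or a list with n_syllables")
  }
  if (n == 0) warning("empty annotation: speech rate 0")
  n / duration_s
}

#' Extract the five acoustic parameters from a signal
#'
#' Composes [preprocess()], [detect_voiced()], [estimate_f0()],
#' [compute_jitter()], [estimate_formants()], [compute_intensity()] and
#' [compute_speech_rate()]. Sub-features that cannot be computed propagate
#' as `NA` and are listed in the `flags` attribute, never silently zeroed.
#'
#' @param signal an [audio_signal()].
#' @param config an [extract_config()].
#' @param annotation optional transcript string or annotation list for
#'   speech rate; when `NULL` and the signal carries synthesis ground
#'   truth, that annotation is used.
#' @return a one-row data.frame with columns `jitter, f0, f1f2, intensity,
#'   speech_rate` and attribute `flags` naming any missing fields.
#' @export
extract_features <- function(signal, config = extract_config(),
                             annotation = NULL) {
  if (is.null(annotation)) annotation <- attr(signal, "ground_truth")
  flags <- character(0)
  fr <- preprocess(signal, config)
  mask <- detect_voiced(fr, config)
  trk <- estimate_f0(fr, mask, config)
  if (!is.finite(trk$f0_mean)) flags <- c(flags, "f0")
  jit <- compute_jitter(trk, scale = config$jitter_scale)
  if (!is.finite(jit)) flags <- c(flags, "jitter")
  fmt <- estimate_formants(fr, mask, config = config)
  if (!is.finite(fmt$f1f2)) flags <- c(flags, "f1f2")
  if (isTRUE(fmt$low_confidence)) flags <- c(flags, "f1f2_low_confidence")
  intens <- compute_intensity(fr, config)
  rate <- if (is.null(annotation)) {
    flags <- c(flags, "speech_rate")
    NA_real_
  } else {
    dur <- if (config$rate_denominator == "full") fr$duration_full_s else
      fr$duration_trimmed_s
    compute_speech_rate(annotation, dur)
  }
  out <- data.frame(jitter = jit, f0 = trk$f0_mean, f1f2 = fmt$f1f2,
                    intensity = intens, speech_rate = rate)
  attr(out, "flags") <- flags
  out
}
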