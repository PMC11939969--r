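---
title: "Modeling anxiety-speech parameter networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling anxiety-speech parameter networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

State anxiety — the transient anxiety a speaker experiences under a
situational stressor such as an oral exam — leaves traces in the voice.
Rather than testing acoustic features one at a time, the approach this
package implements treats five voice biomarkers (local jitter, mean
fundamental frequency F0, the F1/F2 formant ratio, frame-averaged intensity,
and speech rate) together with a 4-point self-rated anxiety score as nodes
of a Gaussian graphical model. Edges are regularized partial correlations:
the association between two nodes after conditioning on all others. In the
population this package models (316 undergraduate speakers performing a
timed picture-description task in a second language; 119 low-anxiety
raters 0–1, 197 high-anxiety raters 2–3), the published structure has
anxiety connected to the speech system through a single negative edge to
jitter (−0.17), a strong negative jitter–F0 edge (−0.39), a positive chain
speech rate–intensity (0.28), intensity–F1/F2 (0.26), and F1/F2–F0 (0.24),
and a high-/low-anxiety contrast in which only the intensity–F1/F2 coupling
(0.33 vs absent) distinguishes the groups.

The raw recordings behind those numbers are not deposited, so `vocanet`
pairs every analysis stage with a synthetic ground-truth generator: a
source-filter vowel synthesizer whose acoustic parameters are known
exactly, and a feature-table generator that draws samples from graphical
models with planted edges. All tests are recovery experiments against that
ground truth.

## Estimation pipeline

1. **Spearman correlations** (`spearman_matrix`): rank correlations with
   average ties on listwise-complete rows. The ordinal anxiety rating
   enters through ranks, not a polychoric model. A non-PD matrix is
   repaired by eigenvalue clipping at `1e-6` and flagged.
2. **Graphical lasso** (`glasso_fit`, compiled): maximizes
   `log det K − tr(SK) − λ Σ_{i≠j} |K_ij|` with the diagonal unpenalized,
   by blockwise coordinate descent with warm starts along the penalty path.
   Leaving the diagonal unpenalized matches the psychometric-network
   convention and gives the p = 2 closed form (the implied partial
   correlation is the soft-threshold of the input correlation) used as an
   exact oracle in the tests.
3. **EBIC selection** (`ebic_select`): 100 penalties log-spaced from
   `λ_max` (the largest absolute off-diagonal, which yields an empty graph)
   down to `0.01 λ_max`;
   `EBIC_γ = −2ℓ + E log n + 4 E γ log p` with
   `ℓ = (n/2)(log det K − tr(SK))` and `E` the number of edges; `γ = 0.5`
   (edge-conservative). The `−(np/2) log 2π` constant is constant along the
   path and omitted; an oracle comparing objectives must omit it too.
4. **Centrality**: one-step expected influence, the signed sum of a node's
   edge weights — appropriate when negative edges exist.
5. **Stability** (`bootstrap_edges`, `cs_coefficient`): nonparametric
   bootstrap percentile CIs (matching the default behavior of the standard
   bootnet workflow) and the case-dropping CS coefficient — the largest
   drop proportion at which the 5th percentile of the correlation between
   subsample and full-sample expected influence stays ≥ 0.7. CS > 0.5 is
   conventionally stable, < 0.25 unstable; the report flags, never errors.
   Undefined subsample correlations count as failures (conservative).
6. **Comparison** (`nct`): permutation test with group sizes preserved and
   full re-estimation per permutation. The global statistic is the absolute
   difference of summed unique edge weights ("global expected influence":
   the node-EI sum is exactly twice it); per-edge and per-node statistics
   are absolute differences. Add-one p-values `(1 + #{perm ≥ obs})/(1 + P)`
   avoid p = 0. No multiplicity correction anywhere, by design.

### Group networks and the anxiety node

Group-level networks compare the five speech indicators only; the rating
that defines the groups is nearly constant within each group, so including
it would add a degenerate node. `nct(include_anxiety = TRUE)` restores it
for sensitivity analyses. The total-sample network always includes the
rating as a 4-level ordinal node.

## The synthetic-data generator

### Feature tables

`build_precision` constructs the concentration matrix in closed form:
on the standardized scale `K = I − P`, where `P` carries the requested
partial correlations. Any concentration matrix with those partials factors
as `D^{1/2} K D^{1/2}`, so a positive-definite `K` of this form exists if
and only if the request is realizable; an infeasible edge set fails with
the edges named rather than being silently shrunk. `generate_feature_table`
draws multivariate normal samples from the implied correlation matrix,
rescales each column to the published group marginals (affine maps leave
rank correlations untouched), and produces the ordinal rating by
quantile-cutting the latent anxiety node at the cumulative rating
probabilities. The published rating means and SDs pin those probabilities
exactly: 0.70 ± 0.46 in the low group is a 30/70 split over {0, 1}, and
2.51 ± 0.50 in the high group a 49/51 split over {2, 3}.

The low-anxiety network's edge weights are not printed in full; they are
derived here from two published summaries — the global expected influence
(sum of edge weights = 0.19) and the maximum node expected influence
(F1/F2 = 0.30) — giving rate–intensity 0.28, F1/F2–F0 0.30, jitter–F0
−0.39. The same arithmetic reproduces the published high-group global
value 0.42 exactly, which is the consistency check that motivated it.

### Vowel synthesis

`synthesize_vowel` is a source-filter model designed so that every target
of the extraction chain has a known value:

* **Source**: an impulse train with sub-sample (linearly interpolated)
  placement, period `T_i = (1/f0(t))(1 + ε_i)` with `ε_i` i.i.d. Gaussian.
  Since `E|ΔT| = 2σ/√π` for i.i.d. Gaussian perturbations,
  `σ = (jitter/100)·√π/2` makes the expected Praat local jitter equal the
  requested percentage; the realized period sequence is returned as ground
  truth. `f0(t)` declines linearly by `f0_drift` (default 8% peak-to-peak)
  — the declination of a natural breath group — which also sweeps the
  harmonics across the formant peaks so that frame-averaged LPC samples
  the envelope rather than a fixed harmonic comb.
* **Glottal spectrum**: one real pole at 0.97 tilts the source downward
  (≈ −6 dB/oct) the way voiced excitation rolls off; the analysis chain's
  0.97 pre-emphasis undoes it exactly. High-passed aspiration noise
  (default −46 dB re the pulse amplitude, above ~400 Hz) adds the
  turbulence component of real phonation without touching the pitch band.
* **Filter**: cascaded two-pole resonators; defaults F1 = 500 Hz (bw 80),
  F2 = 2000 Hz (bw 120), F3 = 2900 Hz (bw 200), giving the population's
  F1/F2 = 0.25. Centers at or above Nyquist fail before synthesis.
* **Prosody**: a trapezoidal syllable envelope (65% duty cycle,
  raised-cosine ramps) at `syllable_rate` events/s, with onsets and count
  returned; RMS is calibrated on the envelope-on samples; white
  measurement noise is added last (default −50 dB).

What the generator does **not** emulate: articulation (no phoneme
inventory, no formant transitions), shimmer or amplitude perturbation,
breath noise bursts, room reverberation, or channel effects. Passing
round-trip tests therefore demonstrate that the extractors implement their
definitions correctly on controlled signals — not that they are robust to
conversational recordings.

## Extraction design choices

* **Framing**: Hamming 512 samples / hop 256 / 0.97 pre-emphasis at a
  22.05 kHz analysis rate (≈ 23 ms windows). Raw (un-emphasized) frames are
  kept alongside: intensity and periodicity use the raw waveform, LPC the
  emphasized one.
* **Voicing**: energy gate (30% quantile of frame RMS, capped at 0.1 × the
  maximum frame RMS so uniformly voiced signals are not thinned by the
  quantile rule) AND a normalized autocorrelation peak ≥ 0.45 in the
  75–400 Hz band, computed after a moving-average low-pass with first null
  near 400 Hz — the usual guard against formant ringing and noise in F0
  tracking.
* **F0**: per-frame autocorrelation argmax with parabolic interpolation;
  the mean is taken over voiced frames.
* **Jitter periods**: cycle markers are picked on a double moving-average
  of the waveform whose null sits near 1.5·F0 (one peak per cycle), then
  each period is refined as the lag maximizing the normalized
  cross-correlation of consecutive full-band cycles (window half-width
  0.6 periods, parabolic peak interpolation). The full-band waveform
  carries the sharp formant-ringing structure that makes sub-sample timing
  possible; an LPC-residual peak picker was tried first and discarded —
  whitening amplifies the high-frequency noise floor and pushes timing
  errors beyond the jitter tolerance. The 0.6-period window is a
  calibrated compromise: shorter windows admit noise, longer ones average
  neighboring periods and deflate jitter.
* **Formants**: per voiced frame, 12th-order LPC by Burg's method (the
  estimator Praat uses; the autocorrelation method is biased several
  percent upward in F1 on 180-Hz-periodic signals). Roots with positive
  imaginary part become candidates (`f = angle·sr/2π`,
  `bw = −(sr/π)·log|root|`); candidates outside [90 Hz, Nyquist − 50] or
  wider than 400 Hz are rejected; the two lowest survivors are F1 and F2,
  averaged across frames.
* **Intensity**: frame RMS averaged over frames above −10 dB of the
  95th-percentile frame RMS (drops pauses and boundary part-frames), then
  `20·log10(·) + 94` dB. The +94 dB calibration puts a full-scale sine
  near 91 dB and conversational speech near the population's ~67 dB;
  absolute SPL is unrecoverable from a file, and the offset cancels in all
  correlations. Relative thresholds make intensity exactly gain-equivariant
  and jitter/formants gain-invariant.
* **Speech rate**: syllables per second over the full (untrimmed) task
  duration (`rate_denominator = "speech"` switches to trimmed time).
  Transcript syllables use the orthographic vowel-group heuristic with a
  one-syllable-per-word minimum; synthesis annotations supply exact counts.
  There is no ASR in the package: transcripts and annotations are inputs.
* **Missing values**: any extractor that cannot produce a value returns
  `NA` and is named in the `flags` attribute; rows with missing features
  are excluded listwise before network estimation.

## Numerical choices

* Graphical-lasso convergence: relative change below `1e-8` (scaled by the
  mean absolute off-diagonal), inner lasso sweeps to a tenth of that;
  the KKT conditions are verified in tests to `1e-4`.
* `λ = 0` is solved by the same coordinate descent (tests tighten the
  tolerance to reach the matrix inverse to `1e-5`).
* PD repairs (Spearman matrix) clip eigenvalues at `1e-6` and renormalize
  the diagonal; `build_precision` refuses rather than repairs, since a
  planted-truth generator must not silently change the truth.
* Bootstrap and permutation machinery funnel all randomness through
  explicit integer seeds; reports are bit-reproducible under the same seed,
  and failed replicates are dropped and counted, with failure above 5%
  escalated to an error.

## Problem sizes in the test-suite

The packaged experiments run at desk scale: 50-seed recovery experiments at
the study's n = 316; permutation-test calibration with 100 random splits at
P = 200 and power with 50 repeats at n = 197/119; bootstrap and
case-dropping stability at B = 40–200 with 10 meta-repeats on noise and a
single n = 5000 run for the near-deterministic regime; and a 20-vowel
extraction battery drawn from the population's published marginals
(F0 ~ N(182, 18) within [150, 215] Hz, jitter ~ N(0.5, 0.07) within
[0.35, 0.65]%, intensity uniform on [60, 74] dB). `run_pipeline` defaults
to B = P = 200 for smoke runs; the CLI's `--paper-settings` flag restores
the study's 1000/1000.

## Known limitations

* The extractors are validated on synthetic vowels; conversational speech
  adds phenomena (formant transitions, creak, reverberation) that no test
  here exercises.
* The F0 tracker assumes a single voiced source in 75–400 Hz; strong
  low-frequency hum would require re-tuning the voicing gates.
* The graphical-lasso edge weights are shrunk toward zero by construction;
  recovery tests score support and sign, not the shrunken magnitudes.
* The CS coefficient inherits the coarseness of its 0.05 grid and the
  p-point expected-influence vectors (here p = 5 or 6): its sampling
  variability at small B is visible in the reports' quantile curves.
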