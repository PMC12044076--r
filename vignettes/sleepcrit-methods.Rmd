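---
title: "Quantifying complexity and criticality in sleep EEG with sleepcrit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying complexity and criticality in sleep EEG with sleepcrit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepcrit)
```

## Scope and model

sleepcrit implements a complete analysis chain for paired
pharmacological sleep-EEG studies in which the question is not "which
oscillations change?" alone, but whether an intervention shifts the
brain's broadband dynamics — its entropy, compressibility and proximity
to a critical regime. The chain is: EDF input (or synthetic generation)
→ band-pass filtering and epoching → per-epoch feature extraction →
within-subject averaging and z-transformation → paired permutation
inference and cross-validated decoding.

Eleven canonical features are computed per 20-s epoch and channel:

* **Corrected band powers** (delta 0.5–4, theta 4–8, alpha 8–12, sigma
  12–16, beta 16–32 Hz). The Welch spectrum (4-s Hann windows, 2-s
  overlap, 0.25 Hz resolution) is parameterized into an aperiodic
  component — a straight line in log10 power vs log10 frequency with
  offset $b$ and exponent $\chi$, so $P(f) \propto f^{-\chi}$ — plus up
  to five Gaussian peaks fitted over 3–32 Hz with widths constrained to
  0.5–12 Hz. Corrected band power is the mean log10 residual (observed
  minus aperiodic) over the band's bins; for delta, the line is
  extrapolated below the fit range and no peaks are fitted there.
* **SpecEn**: Shannon entropy of the 0.5–32 Hz spectrum normalized to
  [0, 1].
* **SampEn**: sample entropy with $m = 2$, $r = 0.2 \cdot \mathrm{SD}$,
  Chebyshev distance, self-matches excluded,
  $\mathrm{SampEn} = -\log(A/B)$.
* **SpecSampEn**: SampEn applied to the ordered sequence of linear PSD
  bin values — sensitive to local spectral patterns that
  permutation-invariant Shannon entropy ignores.
* **LZc**: the signal is binarized at its median (strictly greater maps
  to 1 — a deterministic tie rule, important for integer-quantized EDF
  data), parsed by the LZ76 exhaustive-history rule, and the phrase
  count $c(n)$ is normalized as $c(n)\,\log_2(n)/n$.
* **DFA exponent** $\alpha$: RMS fluctuation of the linearly detrended
  cumulative profile over ~16 log-spaced, non-overlapping window sizes
  from 16 samples to a quarter of the epoch; $\alpha$ is the log–log
  slope. 0.5 indicates white noise, larger values long-range temporal
  correlations, values above 1 unbounded non-stationary dynamics.
* **Aperiodic slope**: the exponent $\chi$ reported with a positive
  sign, so a *reduction* means a *flatter* spectrum — the direction
  associated with a shift toward relatively more excitation and closer
  proximity to a critical regime.

Permutation entropy (Bandt–Pompe, order 3, delay 1) is available as an
optional extra but is not part of the canonical set.

## The synthetic study generator

Because raw clinical sleep EEG can rarely be redistributed, the package
is built around a generator whose output has *known* ground truth, so
every stage of the pipeline is testable end to end. `study_config()`
defaults encode the paired design the analyses expect: 40 subjects (22
young, 18 middle-aged), two nights (placebo/caffeine), 20 channels of
the 10–20 montage at 256 Hz, 20-s epochs with NREM:REM counts in a 3:1
ratio.

Signals are synthesized in the frequency domain: a target log10 PSD is
assembled from the aperiodic line plus Gaussian peaks, and
complex-Gaussian Fourier coefficients with matching expected power are
inverse-transformed. This gives exact control of the aperiodic exponent
and peak heights while preserving realistic spectral estimation noise
(the periodogram fluctuates like a genuine stationary Gaussian
process). Stage physiology is mirrored by construction: the NREM
baseline is steeper ($\chi_0 = 2.0$) with a strong slow-wave peak and a
sigma-spindle peak; REM is flatter ($\chi_0 = 1.5$) with a theta peak.

Condition effects are injected as a slope reduction `d_chi` (positive =
flatter under caffeine) plus per-band Gaussian height changes in log10
power. Two placement rules matter and were chosen deliberately:

* the delta-band effect bump sits at 1.5 Hz with 0.5 Hz width, entirely
  below the 3 Hz fit edge, and
* the beta-band bump is narrow (20 Hz, 1.2 Hz width).

With wide or border-straddling bumps, part of a band effect is absorbed
by the aperiodic line and re-emerges as spurious corrected-power shifts
in *other* bands — a genuine limitation of 1/f-correction with broad
spectral changes, which users should keep in mind when interpreting
corrected beta effects in real data.

The generator does not add a second, independent long-range-correlation
knob: for $0 \le \chi < 1$ a power-law signal has theoretical DFA
$\alpha = (\chi + 1)/2$, and the flattening effect therefore moves the
DFA exponent and the entropy metrics in the physiologically expected
directions automatically, keeping ground truths mutually consistent.
Between-subject variability enters as Gaussian offsets on $\chi$ and
the spectral offset, plus a per-subject multiplier on the condition
effect (truncated at zero); the paired sign-flip test is meaningful
only if subjects carry stable individual baselines, which these offsets
provide. Age modulation of the condition effects (e.g. weaker responses
in a middle-aged group) is available through `age_effect` but defaults
to no modulation; the literature offers no quantitative
age-by-condition effect sizes to adopt, so none are baked in.

Everything is a pure function of the config, including its seed: the
same `study_config()` reproduces bit-identical recordings.

What the generator does *not* emulate: discrete sleep microstructure
(spindle trains, K-complexes as waveforms), volume conduction and
channel covariance, artifacts, non-stationarity within an epoch, and
epoch-to-epoch state drift. Passing tests therefore demonstrate that
the *estimators and inference machinery* behave correctly under known
ground truth — not that real caffeine EEG will show any particular
effect size.

## Numerical choices

* **Welch details.** Hann taper, 50% overlap, per-segment mean removal,
  one-sided density normalization (the PSD integrates to the signal
  variance; Parseval is enforced by test to within 10%).
* **Aperiodic fit.** Robust line fits use an M-estimator
  (`MASS::rlm`) with an ordinary least-squares fallback. Peak
  extraction is iterative: largest positive residual, Gaussian fit with
  bounded center/height/width, subtraction, stop at 5 peaks or when the
  residual maximum falls below `max(0.05, 2 SD)` in log10 units. The
  line and the peak set are then re-estimated in three alternating
  passes; without the alternation a strong peak tilts the initial line
  and biases the exponent by ~0.06, with it the residual bias is ~0.02,
  and the no-peak bias is below 0.005 across $\chi \in [0.5, 2]$.
* **SampEn degenerate cases.** Zero-variance epochs are an error at the
  metric level; the feature extractor records them as flagged cells. If
  no template pair extends ($A = 0$), SampEn returns `+Inf`, and
  within-subject averaging skips non-finite cells rather than imputing.
* **DFA windows.** Non-overlapping windows, trailing partial window
  discarded, linear detrending, at least 6 distinct sizes required.
  Maximum window is capped at $n/4$ so every size averages at least
  four segments.
* **Band-limited DFA.** The Hilbert envelope of a narrowband signal is
  intrinsically smooth below the envelope decorrelation time
  (1/bandwidth): fitting DFA there measures the filter, not the
  dynamics, and yields $\alpha$ near 1 even for white noise. Default
  windows therefore start at six decorrelation times
  (`6 * fs / bandwidth` samples) and one second is trimmed from each
  envelope end to drop filter transients. A small upward bias
  (~0.05–0.08 on 80-s white-noise segments) remains at these scales.
* **Pseudo-T regularization.** The paired permutation statistic is
  $\bar d / (\mathrm{SE}(d) + \varepsilon)$ with
  $\varepsilon = 0.1 \times \mathrm{median}(\mathrm{SE})$ across
  channels — stabilizing near-zero-variance channels, the purpose of a
  pseudo-T, while leaving typical channels essentially unchanged.
  Setting `epsilon = 0` gives the plain paired t statistic.
* **Permutation nulls.** Sign flips are applied to a subject's whole
  channel vector jointly, preserving spatial correlation; each
  permutation contributes its maximum |T| across channels, giving
  strong FWER control. Monte-Carlo nulls use add-one p-values,
  $(1 + \#\{max \ge |T|\})/(n_{perm} + 1)$; with 14 or fewer subjects
  the $2^n$ sign patterns are enumerated exhaustively instead (for 40
  subjects, $2^{40}$ sign patterns rule out literal exhaustion, so
  $10^4$ Monte-Carlo draws are the default).
* **Z-transform pooling.** Each subject's mean and SD come from that
  subject's epoch-level values pooled across channels, epochs and both
  conditions. Pooling across conditions is deliberate: per-condition
  statistics would erase the within-subject condition contrast that the
  analyses target. No cross-subject quantity enters any subject's
  transform, so grouped cross-validation cannot leak test-set
  information through the scaling — this is asserted by test
  (perturbing one subject never changes another's z-scores).
* **Decoding.** Grouped k-fold keeps both recordings of a subject in
  one fold. The SVM uses an RBF kernel with $C = 1$ and kernel scale
  $1/\mathrm{var}(x)$ on the single z-scored feature; LDA is used
  without shrinkage (inputs are one-dimensional). The permutation null
  swaps the two condition labels within a random subset of subjects,
  respecting exchangeability under the paired design, and is corrected
  across channels by the maximum accuracy per permutation. Single-epoch
  decoding reports balanced accuracy (mean of per-class recalls), which
  is exactly 0.5 for any constant classifier regardless of class
  imbalance. The random forest uses nested CV — outer
  leave-5-subjects-out, inner grouped 7-fold grid search over a small
  grid (trees 100/300, depth unlimited/5/10, mtry $\sqrt p$/0.2p) —
  with impurity importances normalized to sum to one per fitted model
  and averaged over repetitions (default 25; the full-scale analysis
  design uses 1000).

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
desk scale, sizes chosen as the smallest that leave the estimators in
their asymptotic regime: DFA/entropy calibrations use 100 signals of
5120 samples; family-wise error calibration uses 500 null studies of 40
subjects × 20 channels with 1000 permutations each; the end-to-end
planted-effect study uses 8 subjects × 60 NREM epochs × 4 channels at
128 Hz with effects d_chi = 0.2, delta −0.3, beta +0.3 (log10 units).
At these sizes the planted sign pattern (flatter slope, lower DFA,
higher SampEn/LZc, higher corrected beta, lower corrected delta under
the active condition) is recovered on all channels and the random
forest concentrates ~95% of its importance on the affected features.

## Known limitations

* The aperiodic model is fixed (no knee), matching the 3–32 Hz range
  where sleep spectra are close to a single power law; spectra with a
  clear knee need a different fit range, not this model.
* Corrected band power inherits the coupling discussed above: broad
  band-power changes and slope changes are not perfectly separable.
* SpecSampEn is an uncommon variant; its absolute values depend on the
  spectral estimator's bin count and should only be compared within a
  fixed configuration.
* The EDF reader covers continuous 16-bit EDF with a uniform sampling
  rate — deliberately minimal, not a general EDF+ implementation.
* Visual sleep staging and visual artifact rejection are out of scope;
  stage labels are inputs, and the amplitude-threshold rejection is an
  explicit automated surrogate.

## A worked example

```{r example, eval = FALSE}
cfg <- study_config(
  n_subjects = 8, age_group_split = c(young = 4, middle = 4),
  channel_names = c("Fz", "Cz", "Pz", "Oz"), fs = 128,
  n_nrem = 30, n_rem = 10, seed = 1)
res <- run_pipeline(pipeline_config(study = cfg, stages = "NREM",
                                    n_perm = 1000, seed = 1))
res$NREM$stats
```

The stats table lists, per feature and channel, the paired pseudo-T,
the max-statistic-corrected p-value, and the paired Cohen's d; with the
default generator effects, slope and DFA rows carry negative
statistics, and the entropy/LZc rows positive ones, under the active
condition.
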