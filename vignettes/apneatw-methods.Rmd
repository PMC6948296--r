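---
title: "Detecting sleep apnea from single-lead ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep apnea from single-lead ECG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apneatw)
```

## The problem

Sleep apnea is conventionally diagnosed with overnight polysomnography, which
is expensive and uncomfortable. A practical alternative screens with a single
ECG lead: apnea episodes leave two well-known fingerprints in the ECG. First,
the heart rate develops a slow cyclic variation (bradycardia during the event,
tachycardia at its resolution) whose period is tens of seconds, i.e. power in
the very-low-frequency (VLF, 0--0.04 Hz) band of the RR-interval series.
Second, respiratory chest movement modulates the R-peak amplitude, so the
amplitude series acts as an ECG-derived respiration (EDR) surrogate whose
spectrum shifts the same way. Normal breathing instead drives respiratory
sinus arrhythmia in the high-frequency band (HF, 0.15--0.4 Hz).

`apneatw` classifies each one-minute ECG segment as apnea or normal, and then
diagnoses the whole recording through the apnea--hypopnea index
(AHI = 60/T x number of apnea minutes, disease if AHI > 5). Its
distinguishing feature is the *time window*: apnea minutes arrive in bouts,
so the classifier's input concatenates the current minute's features with
those of the preceding minutes, letting the network exploit the temporal
dependence that per-minute classifiers discard.

## Pipeline

1. **Denoising.** Linear-phase FIR bandpass, 3--45 Hz passband
   (windowed-sinc, Hamming window, order 330 at 100 Hz, about 1 Hz
   transition bands). Applied once by FFT convolution with the symmetric
   filter's constant group delay removed exactly, so peak times and
   amplitudes are unbiased. We deliberately do not use forward-backward
   filtering: a single compensated pass realises the designed magnitude
   response rather than its square.
2. **R-peak detection.** A Hamilton-style adaptive chain: 30 ms moving
   average (suppresses broadband noise in the derivative while keeping the
   QRS slope), first difference, rectification, 80 ms moving-window
   integration, then an adaptive threshold held at
   `npk + 0.3125 (spk - npk)` between running levels of the last 8 QRS and
   last 8 noise peaks, a 200 ms refractory period, and a search-back that
   rescues a missed beat when the gap exceeds 1.5x the running mean RR.
   Running levels use medians rather than means: with means, a burst of
   accepted noise peaks drags the QRS level down and the threshold collapses
   (runaway false positives). Each detection is refined to the local maximum
   of the filtered signal within +/-20 ms after exact delay compensation.
3. **RR correction.** An RR interval deviating from its 5-point local median
   by more than 20% is replaced by that median (both knobs config-exposed).
   Correction runs once per recording, before segmentation, so a bout
   boundary does not truncate the correction window; per-segment operation
   would change nothing except at segment edges.
4. **Features.** Per minute, 18 features in a frozen order
   (`apnea_feature_names()`): six RR time-domain statistics (MRR, MHR,
   RMSSD, SDNN, NN50, pNN50), six RR spectral features and six EDR
   (R-amplitude) spectral features (VLF, LF, HF band powers by trapezoidal
   integration of a Welch PSD, plus LF/HF, LF/(LF+HF), HF/(LF+HF)).
   RR intervals are assigned to the minute containing their second peak;
   minutes with fewer than 20 beats are invalid and excluded.
5. **Normalisation.** Per-feature z-scores; statistics are fitted on the
   training split only and reused everywhere else, so held-out data never
   leaks into them. Zero-variance features map to 0.
6. **Time-window model.** The input of minute *k* is the concatenation of
   minutes *k-w+1 .. k* (oldest first); `w = 5` by default, giving
   M = 90 inputs and a hidden layer of 2M+1 = 181 relu units by the
   Kolmogorov superposition sizing rule. Two linear outputs are trained
   against one-hot targets by mini-batch SGD with momentum on the summed
   squared error; the apnea score is the difference of the outputs and ties
   resolve to normal. `w = 1` is exactly the plain per-minute MLP baseline.
7. **Evaluation.** Per-segment accuracy/sensitivity/specificity and
   rank-based AUC; per-recording AHI with the strict >5 rule, Pearson
   correlation of predicted against annotated AHI, Bland--Altman agreement
   (bias +/- 1.96 sd limits), a window-size sweep with H recomputed as
   2(18w)+1, and recording-level k-fold cross-validation (folds never split
   a recording, normalisation and training are refit per fold, fold means
   carry t-based 95% CIs).

## Numerical choices

* **Spectral estimation.** The RR tachogram and EDR series are unevenly
  sampled event series; they are cubic-spline interpolated onto a uniform
  4 Hz grid spanning the observed beats of the minute, mean-removed, and
  fed to a Welch estimator (Hann window, 256-point FFT, 50% overlap,
  one-sided density scaling). With ~60 beats per minute the segment holds
  about 240 grid points, so the estimate is effectively a single windowed
  periodogram zero-padded to 256 points; the overlap matters only for
  longer inputs. Band powers integrate the PSD over half-open bands
  [0, 0.04), [0.04, 0.15), [0.15, 0.4) Hz. Ratio conventions: 0/0 = 0 and
  x/0 is capped (default 100); a minute needs at least 4 beats spanning
  more than 10 s or it is invalid.
* **pNN50 denominator.** The count of adjacent-pair differences is divided
  by the number of pairs (N-1) for consistency with NN50's domain; dividing
  by N instead is a config switch (`pnn50_denom = "n"`).
* **MHR** is the mean of the instantaneous rates 60/RR(n), in beats/min.
* **Weight decay.** The sizing rule makes the w = 5 network wide
  (16,653 weights). On cohorts of a few hundred to a few thousand windows it
  memorises the training set (training accuracy near 1 with a large
  generalisation gap) and early stopping alone does not prevent it. A small
  L2 penalty on the connection weights (default `l2 = 3e-2`, validated on
  synthetic development data and config-exposed) restores the generalisation
  of the windowed model while leaving the small w = 1 network essentially
  unchanged. This is the one place we extend the bare
  SGD-with-momentum/early-stopping recipe, and it is disclosed here
  deliberately.
* **Optimiser defaults.** lr 0.01, momentum 0.9, batch 128, at most 200
  epochs, 10% validation split for early stopping with patience 20, best
  weights restored. All seeded: identical seed and data give bit-identical
  fits, and models serialised to JSON (`write_tw_mlp()`, 17 significant
  digits) reproduce predictions exactly.
* **Coverage loss.** Windows containing an invalid segment, spanning a gap,
  or crossing recordings are dropped rather than imputed, so the first
  w-1 minutes of each recording are unpredictable; evaluation T defaults to
  the number of evaluated minutes (a flag restores full-duration T).

## The synthetic generator

External apnea-ECG archives cannot ship with the package, so every stage is
exercised against a generator with exact ground truth. It integrates an
instantaneous RR series into beat times, renders each beat as a
raised-cosine QRS spike (80 ms) scaled by an amplitude series, and adds
Gaussian noise:

* apnea minutes: RR and amplitude modulated at 0.02 Hz (VLF), depth 0.25
  scaled per episode by a severity in U(0.2, 1);
* normal minutes: modulation at 0.25 Hz (HF), depth 0.05;
* per-minute *event coverage* in U(0.02, 1): the oscillation is active
  only on a contiguous sub-interval of each apnea minute, because scored
  events rarely fill the labelled minute — this is the main source of
  ambiguous minutes;
* movement artifacts: 30% of normal minutes carry a VLF burst of depth
  0.15, the main source of false-positive pressure;
* broadband beat-to-beat jitter (RR sd 30 ms, amplitude sd 0.05) setting
  realistic noise floors;
* per-minute labels from a two-state Markov chain, so apnea arrives in
  bouts (class A: 50% apnea, 12-minute mean bouts; class B: 12.5%, 6
  minutes; class C: 3%, 2 minutes), matching the clustering of real
  events that the time window exploits.

The heterogeneity constants were calibrated once, on development
simulations, so that the plain per-minute MLP baseline lands in the
80--90% accuracy range reported for per-minute classifiers in this
literature — hard enough that temporal context has something to add —
and were then frozen. The generator emulates spectral signatures, event
clustering, event-strength heterogeneity and artifacts; it does not emulate
P/T-wave morphology, ectopic beats, electrode pops, or drifting sleep
stages. Passing tests therefore demonstrate correctness of the pipeline and
the reality of the window effect *under these conditions*, not clinical
performance on archival recordings.

## Seeds and problem sizes

All randomness flows through explicit integer seeds (dataset seed, model
seed, fold seed); the test-suite and acceptance harnesses run cohorts of
14--18 recordings of 40--60 minutes — sizes chosen so the full suite
completes comfortably on a laptop while leaving hundreds of windowed test
segments per comparison.

## Known limitations

* Annotated archives distinguish obstructive, central and hypopnea events;
  neither the labels we emulate nor the model do.
* The AHI here counts apnea-labelled minutes per hour, a per-minute
  surrogate of the clinical per-event index.
* The Hamilton-style detector assumes upright R peaks; inverted-lead
  recordings would need a polarity flip upstream.
* Amplitudes are read from the filtered signal; strong baseline wander
  outside 3--45 Hz is removed, but in-band artifacts pass through to the
  EDR features (by design — they are part of what the classifier must
  tolerate).
```
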