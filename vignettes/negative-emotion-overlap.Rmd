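---
title: "How expanding the negative-emotion set degrades physiological emotion recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How expanding the negative-emotion set degrades physiological emotion recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emorec)
```

## The scientific question

Dimensional models place emotions on a valence (pleasantness) by arousal
(activation) plane. Negative emotions — sadness, fear, anger — crowd the
low-valence, high-arousal quadrant, and their physiological signatures
overlap far more than they differ. `emorec` studies a specific consequence:
when an affective-computing protocol *accumulates* negative emotion
categories across recording sessions (session 1: calmness, fear, happiness;
session 2 adds sadness; session 3 adds anger), classifier accuracy on EEG
and ECG features falls, and the features that discriminate affect
dimensions lose their discriminative range.

Because no public recordings accompany this protocol, the package is built
around a synthetic-data generator whose statistical structure encodes
exactly the mechanism under study, plus the full analysis chain: annotator
rating quality control, differential-entropy (DE) EEG features, a
19-feature heart-rate-variability (HRV) battery, block-cross-validated
linear SVM classification, and a volcano-plot differential-feature screen.
Every stage is testable end to end without any external data.

## The synthetic generator

### What the overlap dial does

The single scientific dial is `negative_overlap` $\in [0, 1]$. Each
emotion has a generator profile (EEG: five band-power multipliers; ECG:
mean heart rate, SDNN, LF/HF). Within a session, the profiles of the
low-valence emotions *present in that session* are shrunk toward their
common mean:

$$p_e' = \bar p + (1 - \mathrm{overlap})\,(p_e - \bar p),
\qquad \bar p = \tfrac1{|\mathcal N|}\sum_{e \in \mathcal N} p_e ,$$

linearly for band powers and heart rate, on the log scale for SDNN and
LF/HF (which must stay positive). At 0 the emotions keep their own
profiles; at 1 all negative emotions in the session share one profile.
Session 1 contains a single negative emotion, so its profiles are
untouched at any overlap — the session designs differ only through the
*composition* of their emotion sets, which is the phenomenon under study.

### Profile geometry

The default profiles are chosen so that the negative emotions *straddle*
the positive ones rather than forming a separate cluster:

* **EEG** (`default_band_profiles()`): calmness is alpha-dominant with
  suppressed beta/gamma; happiness is beta/gamma-elevated; sadness is
  theta/alpha heavy, fear beta/gamma heavy with suppressed alpha/theta,
  anger in between with elevated delta. The numbers are additionally
  arranged so that in theta, alpha and beta the log-contrast between the
  negative-group mean and the positive-group geometric mean decreases
  strictly as sadness and then anger join fear. That ordering is what
  makes the volcano points in those bands collapse toward the origin as
  sessions accumulate negative emotions — the generator encodes the
  mechanism, and the analysis chain must recover it.
* **ECG** (`default_heart_profiles()`): cardiac autonomic reactivity
  tracks arousal far more than valence, so the four high-arousal emotions
  (happiness included) share elevated heart rate, depressed SDNN and
  raised LF/HF, while calmness stays slow and variable. The mean of the
  three negative profiles nearly coincides with the happiness profile:
  shrinkage therefore erodes both the negative emotions' mutual
  separation and their contrast with happiness, which is why the balanced
  three-class comparison (calmness/fear/happiness extracted from sessions
  2–3) scores below session 1.

### Variability structure

Realistic data are not one profile plus white noise; the generator layers
variability at four scales, each with an interpretable magnitude:

| level | EEG | ECG |
|---|---|---|
| subject | lognormal band-gain, SD 0.1 | HR offset, SD 3 bpm |
| trial (shared) | lognormal band-gain, SD 0.1 | HR offset SD 0.5 bpm; SDNN ×lognormal(0.05); LF/HF ×lognormal(0.1) |
| trial (per channel) | lognormal gain per channel × band, SD 0.1 | — |
| within trial | per-second band-power jitter, SD 0.4 (log), shared across channels | Ornstein–Uhlenbeck heart-rate wander, SD 4 bpm, correlation time 8 s |

Two of these deserve comment, because they were chosen to avoid a
degenerate evaluation regime rather than by habit:

* **Why small trial-level ECG offsets.** The analysis protocol slides
  60-s windows with 55-s overlap through each trial and block-validates
  them. Windows of one trial are near-duplicates; a handful of compact
  trial clusters in a 19-dimensional feature space is *always* linearly
  separable, so any appreciable trial-level offset lets the SVM memorize
  trials and pins accuracy near 100% for every session regardless of
  class structure. Keeping trial offsets below the within-trial wander
  makes the soft-margin classifier rely on class geometry, which is the
  regime the study design is about (and the regime real cardiac data —
  with its modest emotion effects — occupies).
* **Why per-channel trial gains for EEG.** If trial-level gains are
  shared across channels, all channels of a band carry the *same*
  subject-level noise and the 60 per-channel paired t-tests of the
  volcano stage become one test replicated — significant counts jump
  between 0 and 60 and averages are dominated by single draws.
  Independent per-channel gains (a crude stand-in for spatial response
  variability) decorrelate the channels and stabilize every count-based
  summary.

The generator does *not* emulate: EEG artifacts (ocular, muscle; the
preprocessing hook where an ICA cleaner would plug in is a documented
no-op), realistic ECG morphology (a Gaussian QRS bump, no P/T waves),
volume conduction or any cross-channel covariance beyond shared gains,
non-Gaussian band amplitude distributions, or respiratory sinus arrhythmia
beyond the fixed 0.25 Hz HF modulation. Passing tests therefore
demonstrate that the *analysis chain* behaves correctly under the stated
statistical structure — not that it would reach the same numbers on
recorded data.

### RR process

RR intervals are generated beat by beat:
$RR_i = 60/\mathrm{HR}(t_i) + a_{LF}\sin(2\pi\,0.1\,t_i + \phi_1) +
a_{HF}\sin(2\pi\,0.25\,t_i + \phi_2) + \varepsilon_i$, with 10% of the
SDNN² target in the white term and the rest split between the two
sinusoids in the LF/HF ratio; $\mathrm{HR}(t)$ carries the OU wander.
Intervals are clamped to [0.3, 2.5] s. Ground-truth peak times are
returned so the R-peak detector can be validated against them.

## Feature extraction

### EEG differential entropy

Preprocessing: zero-phase 4th-order Butterworth band-pass 0.3–50 Hz, a
50 Hz band-stop (quality factor 30), and decimation to 200 Hz (the 50 Hz
ceiling sits below the post-decimation Nyquist, so subsampling is exact).
Recordings are cut into non-overlapping 1-s epochs; each epoch of each
channel is band-passed into delta 1–4, theta 4–8, alpha 8–13, beta 13–30
and gamma 30–50 Hz (the dominant convention in the EEG-emotion
literature; configurable), and summarized by the Gaussian closed form of
differential entropy,

$$h = \tfrac12 \ln(2\pi e\,\hat\sigma^2)$$

in nats, with the unbiased variance estimator. 60 channels × 5 bands give
the 300-dimensional epoch vector. Band-filtering the 1-s epoch (rather
than the continuous record) accepts edge effects at the epoch boundary;
with reflective padding these are small, identical across classes, and
irrelevant to contrasts. Note the analytic limits of the chosen filter: a
4th-order Butterworth applied forward–backward has gain
$1/(1+(f/50)^8)$ above the pass-band — about 0.19 at 60 Hz and 0.02 at
80 Hz — so "out-of-band" means strongly, not infinitely, attenuated.

### ECG / HRV battery

Preprocessing band-passes 0.4–10 Hz and decimates to 200 Hz. (The
band-pass is realized as a 10 Hz low-pass at the raw rate, subsampling,
then the full band-pass at 200 Hz: realized directly at 1000 Hz the
transfer function's poles leave the unit circle after coefficient
rounding.) R peaks come from a derivative–square–moving-average energy
detector with per-10-s adaptive thresholds and a 250 ms refractory
period, refined to the local maximum of the filtered signal; on synthetic
trials it recovers ≥ 99% of ground-truth peaks within ±30 ms. Intervals
outside [0.2, 3] s are dropped with a logged count.

Each 60-s window (5-s hop) yields 19 features in a fixed order:

* time/geometric: SDNN (population 1/N form), RMSSD, SDSD (both over the
  N−1 successive differences), NN50 (>50 ms), pNN50 (= 100·NN50/(N−1)),
  TRI (total count / modal bin count, 1/128 s bins), TINN (base width of
  the least-squares triangle anchored at the modal bin, fitted over a
  zero-padded histogram so oversized triangles pay for their overhang);
* frequency: VLF ≤ 0.04, LF 0.04–0.15, HF 0.15–0.4 Hz band powers from a
  Welch periodogram (Hann window, 50% overlap, ≤ 256-point segments) of
  the cubic-spline tachogram resampled at 4 Hz, plus LF/HF and the LF%
  and HF% shares of total power. Windows whose peaks span under 55 s are
  flagged missing — the threshold sits just below the 60-s window so that
  exactly the windows the protocol defines qualify;
* nonlinear: DFA α₁ (box sizes 4–16 beats) and α₂ (16–64), approximate
  entropy (m = 2, tolerance r = 0.2 × window SD; a variance-based mode
  exists because the two conventions circulate), Poincaré SD1 and SD2;
* heart rate, 60 / mean RR.

ApEn includes self-matches and uses strict `< r` Chebyshev matching, so a
constant series gives exactly 0. DFA drops the trailing partial box at
each scale and detrends per box by least squares.

## Rating quality control

Annotator scores (1–5 Likert) are dichotomized at 3, ties going low. The
pairwise annotator distance is 1 − (fraction of clips with equal bits) —
a normalized Hamming disagreement, despite the "Jaccard" name this
quantity carries in the stimulus-curation literature. The outlier rule
compares each annotator's mean off-diagonal distance, centred on the
panel median, against 1.5 × the standard deviation of the distance
matrix's upper triangle (a median-absolute-deviation-style rule with an
SD-based dispersion). A literal variant that thresholds the per-row
*standard deviation* instead is available via `row_stat = "sd"`; it is
kept for reference but cannot flag a uniformly random annotator, whose
distances to everyone are homogeneously large — the deviation form is the
one that recovers planted outliers reliably, and it is the default.
Krippendorff's alpha (coincidence matrix, interval metric by default —
the Likert scales are treated numerically throughout) and Cohen's kappa
quantify panel agreement; the valence–arousal regression is ordinary
least squares of clip-mean arousal on clip-mean valence, separately for
the high- and low-valence sides of the midpoint.

## Classification protocol

Classification is subject-dependent: each subject's samples (1-s DE
epochs or 60-s HRV windows) are split *within each trial* into five
contiguous temporal blocks; fold k tests on block k of every trial.
Features are z-scored with training-fold statistics and a linear SVM
(C = 1, LIBSVM one-vs-one multiclass) is fitted per fold. Accuracy is
averaged over folds, then subjects. Heavily overlapped HRV windows make
adjacent train and test samples share most of their data; that leakage is
inherent to the protocol being reproduced (temporal blocks mitigate, not
eliminate, it) and is discussed above under the generator's variability
structure. The session sweep runs each session's full emotion set plus
the session-1 emotion subset of sessions 2–3, and reports Welch t-tests
between the per-subject subset accuracies and session 1.

## Volcano screen

For a dimension (valence by default), each emotion carries a consensus
score (`consensus_scores()`; above 3 = positive group, below 3 =
negative). Per subject, all samples in each group are averaged, giving
the positive and negative matrices (subjects × 300 at full scale). Per
feature, the fold change F is the ratio of across-subject means, and the
p-value a paired t-test across subjects (a Kruskal–Wallis option exists;
both conventions appear in this literature — the paired t is the stated
primary analysis, the rank test a robustness check). A feature is
up-regulated if F > 201/200 with p < 0.05, down-regulated if
F < 200/201 — deliberately raw α thresholds with no multiplicity
correction, matching volcano-plot practice (Benjamini–Hochberg is
available but off by default). Features with a non-positive group mean
get an undefined fold change and are excluded from regulation calls
(p is still reported); DE of µV-scale signals is positive in practice, so
this path is defensive. The cross-session shrinkage summary counts
significant features and mean |log₂F| per band; a band earns a
"shrinkage" verdict when both fall monotonically across sessions.

## Problem sizes and numerical choices

The default `experiment_config()` runs 5 subjects/session, 16 EEG
channels, 2 trials/emotion, 15-s EEG trials and 80-s ECG trials (five
60-s windows) — a desk-scale design chosen so that a 10-seed replicate
sweep of all three sessions, both modalities, completes in minutes while
every qualitative contrast (session ordering, subset deficit, band-wise
shrinkage) remains detectable above seed-to-seed noise. Full-scale
parameters (15 subjects, 60 channels, 60-s trials) are plain overrides.
Accuracies at desk scale sit above the real-data regime — synthetic
classes are cleaner than recorded ones — so they are read as orderings,
not as predictions of recorded-data accuracy.

Other fixed choices: seeds propagate through a deterministic sub-seed
derivation so that `generate_session()` and the streaming
`simulate_session_features()` produce bit-identical signals; all filters
are zero-phase with reflective padding (3 × filter length); zero-variance
DE segments return −Inf with a warning and are excluded downstream;
degenerate outlier panels (zero dispersion) remove nobody, with a
warning; constant-accuracy t-tests in the sweep are reported as NULL
rather than erroring.

## Known limitations

* The generator's class structure is Gaussian and stationarity
  violations are mild; real EEG/ECG are heavier-tailed and artifact-laden.
* Subject-dependent classification with overlapping windows inflates
  absolute accuracy; cross-subject transfer is out of scope.
* The 19-feature battery fixes one resolution of the literature's
  inconsistent counting of nonlinear HRV features (SD1 and SD2 included,
  their ratio omitted, heart rate counted as the 19th).
* EDF support covers plain 16-bit, one-record-per-second files — enough
  for interchange of synthetic sessions, not a general EDF+ reader.
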