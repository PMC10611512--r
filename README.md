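# emorec

Emotion recognition from EEG and ECG degrades as the set of *negative*
emotion categories grows: sadness, fear and anger crowd the low-valence,
high-arousal corner of the affect plane and their physiological signatures
overlap. `emorec` is an R toolkit for studying that effect with a fully
synthetic, fully reproducible pipeline. It targets researchers in
affective computing and biosignal statistics who want a controlled test
bed for protocol questions — how does accuracy respond to the label-set
composition? which frequency bands lose discriminative features? — without
access to recorded data.

## What the package does

* **Synthetic study designs.** Three cumulative sessions (1: calmness,
  fear, happiness; 2: + sadness; 3: + anger), 15 subjects each by default.
  The generator produces annotator rating tables, 60-channel EEG (band-
  limited Gaussian noise with per-emotion band-power profiles), and
  single-lead ECG (an RR process with per-emotion heart-rate, SDNN and
  LF/HF targets, rendered as a QRS waveform with ground-truth peaks). A
  single dial, `negative_overlap` ∈ [0, 1], shrinks the negative emotions'
  profiles toward their common mean — 0 keeps them distinct, 1 collapses
  them — emulating the fuzzy boundaries among negative emotions.
* **Rating quality control.** Dichotomization of 1–5 Likert scores, the
  normalized-disagreement distance matrix between annotators, a
  MAD-style outlier-annotator rejection rule, Krippendorff's alpha
  (interval/ordinal), Cohen's kappa, and the arousal-on-valence
  regression of clip mean ratings.
* **EEG features.** 0.3–50 Hz zero-phase Butterworth + 50 Hz notch,
  decimation to 200 Hz, non-overlapping 1-s epochs, and the Gaussian
  differential entropy ½·ln(2πeσ²) per channel × band (δ, θ, α, β, γ) —
  a 300-dimensional epoch vector on the full montage.
* **ECG features.** 0.4–10 Hz filtering, adaptive R-peak detection, and a
  19-feature HRV battery per 60-s window (55-s overlap): SDNN, RMSSD,
  SDSD, NN50, pNN50, TRI, TINN; VLF, LF, HF, LF/HF, LF%, HF%; DFA α₁ and
  α₂, approximate entropy, Poincaré SD1/SD2; heart rate.
* **Classification.** Subject-dependent linear SVM under temporal block
  cross-validation (5 contiguous blocks per trial), per-session
  accuracies, confusion matrices, and the balanced comparison in which
  only the session-1 emotions are extracted from sessions 2–3.
* **Volcano screen.** Per-feature fold change F between positive- and
  negative-group subject means along valence or arousal, paired t-tests,
  up/down-regulation calls at F = 201/200 and 200/201 with α = 0.05,
  scalp-layout topography tables, and a cross-session shrinkage summary.

## Worked example

```r
library(emorec)

cfg <- experiment_config(n_subjects = 3, n_channels = 8,
                         negative_overlap = 0.7, seed = 42)
report <- run_full_experiment(cfg)
report
```

```
Synthetic emotion-recognition experiment report
  seed 42, overlap 0.70, 3 subjects/session
 session           scope n_classes accuracy modality
       1            full         3 67.03704      eeg
       2            full         4 47.50000      eeg
       2 session1_subset         3 58.51852      eeg
       3            full         5 36.22222      eeg
       3 session1_subset         3 61.85185      eeg
       1            full         3 97.77778      ecg
       2            full         4 92.50000      ecg
       2 session1_subset         3 97.77778      ecg
       3            full         5 89.33333      ecg
       3 session1_subset         3 94.44444      ecg
Volcano shrinkage (valence):
  band shrinkage n_sig_s1    mlfc_s1 n_sig_s2    mlfc_s2 n_sig_s3    mlfc_s3
 delta      TRUE        6 0.06189095        3 0.05497699        2 0.05368324
 theta     FALSE        3 0.09361426        0 0.02250738        2 0.01381006
 alpha      TRUE        7 0.14610826        1 0.02461312        1 0.01497633
  beta     FALSE        0 0.04771781        0 0.04383734        6 0.03752998
 gamma     FALSE        7 0.15902978        2 0.09937249        6 0.06662899
```

Reading the report: the full-set accuracy falls from session 1 to 3 for
both modalities (67 → 48 → 36% EEG, 98 → 93 → 89% ECG at this small
scale), and the three-class subsets extracted from sessions 2–3 score at
or below session 1 — the presence of sadness and anger degrades
recognition of the original calmness/fear/happiness set. In the
shrinkage table, the alpha band earns a verdict even at this tiny
problem size: both its significant-feature count (7 → 1 → 1) and its
mean |log₂ fold-change| fall monotonically as negative emotions
accumulate. Single-seed counts in the other bands are noisy at three
subjects; the aggregate behaviour over ten replicate seeds is what the
package's acceptance analysis reports.

Individual stages are plain functions if you want the pieces:

```r
tr  <- generate_ecg_trial("fear", duration = 80, seed = 1)
rr  <- detect_r_peaks(preprocess_ecg(tr))
extract_hrv_vector(rr)["LF_HF"]
#>    LF_HF
#> 3.295426
```

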