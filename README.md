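# thermostress

Contactless acute-stress recognition from facial infrared thermography and
peripheral autonomic signals, as a tested, reproducible R pipeline.

Acute mental stress (e.g., induced by a Stroop colour–word task) changes
facial skin temperature through sympathetically driven vasoconstriction and
perspiration: the nose tip, nasal septum and periorbital regions cool, and
temperature variability rises over the forehead, cheeks and maxillary
areas.  The same sympathetic activation raises tonic skin conductance and
the rate of phasic skin-conductance responses (SCRs), shortens RR
intervals, shifts heart-rate-variability (HRV) power toward the
low-frequency band, and speeds up respiration.  This package implements the
full analysis chain needed to detect those changes and classify Rest vs
Stroop sessions per subject:

* **Synthetic cohorts** (`generate_cohort()`, `cohort_config()`,
  `effect_sizes()`) — seeded generation of thermal frame stacks (14 facial
  ROIs painted on a textured face with head motion), EDA at 500 Hz with
  Poisson SCRs, R-peak times with LF (0.1 Hz) and respiratory HF
  modulation, and respiration — with the full ground truth, so every stage
  is testable without human recordings.
* **Thermal imaging** (`segment_face()`, `place_rois()`, `track_centres()`,
  `extract_roi_signals()`, `clean_signal()`) — threshold segmentation in
  the strict (30 °C, 38 °C) skin range, proportional placement of the 14
  ROIs, block-matching centre tracking, per-frame median temperatures, and
  moving-median + 3-SD outlier cleaning; `thermal_features()` computes
  Mean, Std, DMean, DStd per ROI signal (56 features).
* **Electrodermal activity** (`decompose_eda()`, `eda_features()`) — a
  convex tonic/phasic decomposition (sparse nonnegative sudomotor driver
  through a Bateman biexponential response, spline tonic, FISTA solver) and
  the 8 EDA features (windowed tonic/phasic statistics, peak counts, and
  the 0.04–0.25 Hz sympathetic band power `EDAsymp`).
* **Cardiorespiratory features** (`correct_rr()`, `rr_to_hrv_series()`,
  `hrv_time_features()`, `hrv_freq_features()`,
  `hrv_nonlinear_features()`, `resp_frequency()`) — artifact-corrected RR
  series, 4 Hz HRV resampling, and the 10 HRV features (mean/std HRV,
  RMSSD, pNN50, LF%, HF%, LF/HF, Poincaré SD1/SD2, sample entropy) plus
  the respiratory frequency — 75 features per session in total.
* **Statistics** (`compare_sessions()`) — paired Wilcoxon signed-rank tests
  per feature with Benjamini–Hochberg FDR control.
* **Classification** (`filter_select()`, `svm_rfe_cbr_rank()`,
  `loso_accuracy_curve()`, `evaluate_confusion()`) — a two-stage feature
  selection (correlation pre-filter at p ≤ 0.05, then ν-SVM-RBF recursive
  feature elimination with correlation-bias reduction) evaluated by
  leave-one-subject-out (LOSO) cross-validation, yielding accuracy-vs-rank
  curves and confusion matrices.

## Worked example

```r
library(thermostress)

cfg <- cohort_config(n_subjects = 19, seed = 0)   # default stress preset
ft  <- cohort_feature_table(cfg)                  # 38 sessions x 75 features

stats <- compare_sessions(ft)
sum(stats$rejected)
#> [1] 38            # features significantly different between conditions

res <- loso_accuracy_curve(feature_set_view(ft, "full"), mode = "paper")
res
#> <loso_result> mode 'paper': max accuracy 100.00% at k = 1 of 34
head(res$ranking$feature, 3)
#> [1] "LF/HF"     "RESP freq" "HF"

loso_accuracy_curve(feature_set_view(ft, "thermo"))$max_accuracy
#> [1] 0.9473684     # thermal features alone
```

The feature table has one row per subject and session, labelled
`1 = Stroop` (stress) and `2 = Rest`; `res$accuracy` traces accuracy as a
function of the number of top-ranked features and `res$confusion[[k]]`
holds the per-class percentage confusion matrix at each cut-off.
`evaluate_confusion()` turns reported per-class rates into overall
accuracy and type-II error, e.g. rates of 94.74 % and 100 % over two
19-session classes give 97.37 % accuracy.

A thin command-line wrapper for simulation, thermal extraction and full
runs is installed at `inst/cli/thermostress.R`.

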