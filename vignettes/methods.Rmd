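---
title: "Methods: contactless stress detection from thermal and autonomic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless stress detection from thermal and autonomic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thermostress)
```

# The problem and the pipeline

Acute mental stress engages the sympathetic nervous system, which leaves
measurable traces in several peripheral signals at once: facial skin
temperature redistributes (periorbital and nasal cooling, increased
temperature variability over forehead, cheeks and maxillary regions),
tonic skin conductance rises and discrete skin-conductance responses
(SCRs) become denser, RR intervals shorten with a shift of heart-rate
variability toward the low-frequency band, and respiration accelerates.
`thermostress` implements a complete analysis chain from raw signals to a
subject-independent Rest-vs-Stroop classifier:

1. thermal frame stacks → 14 cleaned ROI median-temperature signals → 4
   features each (56 thermal features);
2. skin conductance → convex tonic/phasic decomposition → 8 EDA features;
3. R-peak times and respiration → corrected RR series, 4 Hz HRV series →
   10 HRV features + respiratory frequency;
4. paired Wilcoxon comparisons with FDR control;
5. two-stage feature selection (correlation filter, ν-SVM-RBF recursive
   feature elimination with correlation-bias reduction) with
   leave-one-subject-out (LOSO) evaluation.

Because the human recordings such a study rests on are not redistributable,
the package ships a first-class synthetic-cohort generator that emulates
the statistical structure the analysis assumes, with full ground truth.

# Thermal stage

**Segmentation.** Face pixels are those with temperature strictly inside
(30 °C, 38 °C) — the physiological skin range, which separates skin from
hair and background — intersected with the face-contour polygon provided in
the landmark metadata (separating face from neck/torso).  The inequalities
are strict: a pixel at exactly 30 °C is background.

**ROI placement.** Each of the 14 ROIs (nose tip; central/right/left
forehead; right/left cheek; nasal septum; central/right/left chin;
right/left periorbital; right/left maxillary) receives
`round(area_fraction × face pixels)` pixels — the nearest pixels to its
centre landmark, clipped to the face mask.  The default `area_fraction`
of 0.02 is a package choice; the proportionality rule (ROI size scales
with face size) is the substantive constraint.  ROI shapes are
near-circular pixel balls rather than anatomically irregular regions:
geometry realism does not affect the downstream median statistics.

**Tracking.** ROI centres are tracked frame-to-frame by integer
block matching: an 11 × 11 patch around the previous centre is matched by
sum of squared differences over displacements within ±5 px, ties resolved
toward the smallest displacement.  This satisfies the same contract as a
pyramidal KLT tracker on data whose motion is translational and
integer-valued, which is exactly what the generator produces; a track whose
patch leaves the image is flagged lost at that frame and frozen rather than
silently extrapolated.

**Extraction and cleaning.** The per-frame ROI median is robust to up to
half the ROI pixels being corrupted.  Cleaning applies a 5-sample moving
median (1 s at 5 Hz; symmetric window shrink at the edges) and replaces
samples deviating more than 3 SD from the filtered signal's mean by the
nearest-in-time non-outlier value.  Both steps are iterated to a joint
fixed point (Tukey-style repeated median smoothing): a single pass of a
moving median is not idempotent on noisy data, and the fixed-point
construction is what makes `clean_signal(clean_signal(x)) = clean_signal(x)`
hold exactly.  Outlier statistics are computed once per pass on the whole
session signal, after the median filter.

**Features.** Per ROI signal: mean, sample SD, and mean and sample SD of
the forward first difference scaled by the frame rate (°C/s).  The
differencing scheme and units are package choices; sample (n−1) SDs are
used throughout the feature layer.

# Electrodermal stage

Skin conductance is modelled as tonic + phasic + noise.  The decomposition
solves the convex program

    minimise  ½‖y − M p − B ℓ − C d‖² + α·1ᵀp + ½γ‖ℓ‖²   s.t.  p ≥ 0

where `M` convolves the nonnegative sudomotor driver `p` with a Bateman
biexponential response (rise τ = 0.7 s, decay τ = 2.0 s, peak-normalised so
driver mass is in µS), `B` is a cubic B-spline tonic basis with knots every
10 s, and `C` a linear drift.  The solver is FISTA with an exact
second-order recursive-filter implementation of `M` (no kernel
truncation), a power-iteration step size, and restart; if the objective has
not plateaued at the iteration cap the solver continues in chunks (up to
3×) and accepts only when the active-set stationarity violation is below
α/2, otherwise it raises a decomposition error.  The signal is block-mean
decimated to 25 Hz before solving — the EDA spectrum of interest lies below
0.25 Hz, and block means act as the anti-alias filter.  Defaults α = 0.05
and γ = 0.01 were chosen by planted-event recovery experiments during
development (0.5 µS events recovered to within 0.05 s at realistic noise);
they are exposed as arguments.

Features: tonic mean/SD per non-overlapping 20 s window, averaged across
windows; phasic mean/SD and peak statistics (count, sum, max of local
maxima ≥ 0.01 µS) per 5 s window, averaged, with empty windows
contributing zero; and `EDAsymp`, the Welch power of the raw conductance
in 0.04–0.25 Hz over the whole session (60 s Hann segments, 50 % overlap,
mean detrend).  The peak criterion and the raw-signal choice for `EDAsymp`
are interpretive decisions; both are documented arguments.

# Cardiorespiratory stage

RR artefacts are flagged when a beat deviates from its 11-beat local median
by more than 30 % of that median, or jumps by more than that amount from
both neighbours (the second rule catches alternating artefacts whose
alternation drags the local median along).  Flagged beats are replaced by
natural cubic-spline interpolation over valid beats; if more than half the
series is flagged the series is declared unusable.  Beat times are rebuilt
from the corrected intervals so interval/time consistency is preserved.

The tachogram is interpolated with a natural cubic spline over beat times
and sampled at exactly 4 Hz across the session.  The 4 Hz series is
instantaneous heart rate (bpm) by default — chosen because mean HRV is
expected to *increase* under stress, consistent with heart rate — with an
`unit = "ms"` flag preserving the RR option.

Frequency features use a Welch spectrum (64 s segments, 50 % overlap,
linear detrend): LF = 0.04–0.15 Hz and HF = 0.15–0.40 Hz band powers as
percentages of the total 0.04–0.40 Hz power (the "total power" denominator
excludes VLF; this is a documented package decision).  Nonlinear features:
SD1 is computed from the uncentered mean square of successive differences,
which makes SD1 = RMSSD/√2 an exact identity rather than an approximation;
SD2 = √(2·SD(RR)² − SD1²) with the population SD; sample entropy uses
m = 2, r = 0.2·SD, Chebyshev distance, self-matches excluded.  The
respiratory frequency is the dominant Welch peak in 0.05–1 Hz of the
detrended respiration signal (decimated to ~4 Hz); a peak below five times
the median in-band power raises a no-peak error instead of returning noise.

# Statistics

Every feature is compared between Rest and Stroop with a two-sided paired
Wilcoxon signed-rank test: zero differences discarded (classic
convention), exact null distribution up to n = 25 without ties, normal
approximation with tie correction otherwise.  Benjamini–Hochberg step-up
FDR control is applied across all features of one comparison call; the
family boundary (all features jointly) is a package decision.

# Classification

**Stage 1 — filter.** Point-biserial correlation of each feature with the
class label (1 = Stroop, 2 = Rest); features with p ≤ 0.05 are retained.
Zero-variance features are dropped with a warning.  If nothing passes the
filter the single best feature is kept, so the downstream classifier is
always defined — needed for null-calibration experiments.

**Stage 2 — ν-SVM-RFE with CBR.** Features are z-scored; a ν-SVM with RBF
kernel (LIBSVM defaults: ν = 0.5, γ = 1/p for the current feature count)
is trained at each step, and each feature's criterion is the retraining-
free sensitivity of the margin objective, `c_f = W² − W²₍₋f₎` with
`W² = Σᵢⱼ αᵢαⱼyᵢyⱼK(xᵢ,xⱼ)` and the kernel recomputed without feature `f`
at fixed α.  The *signed* decrease is used deliberately: the absolute
change ranks separating features whose removal *increases* the objective
as unimportant and demonstrably destroys recovery of planted informative
features (1/30 vs 30/30 seeds in the package's planted-truth experiment).
Correlation-bias reduction: clusters of features with |r| > 0.7 (single
linkage) make each other look individually dispensable, so the cluster's
joint contribution `W² − W²₍₋cluster₎` is computed by removing the whole
cluster from the kernel and each member's criterion is floored at its
equal share of that joint contribution.  Averaging the members' own
criteria — a plausible alternative reading — corrects nothing for exact
duplicates, whose individual criteria are identically ≈ 0.  One feature is
eliminated per step, ties broken by original column order; the feature
eliminated last has rank 1.

**LOSO.** Both sessions of a subject always share a fold.  Two ranking
protocols: `paper` ranks once on the full filtered table and only refits
the SVM per fold — this reconstructs a single accuracy-vs-rank curve over
one ranked axis, but leaks the test subject into feature selection; and
`strict`, which recomputes filter and ranking inside every training fold
and is the methodologically preferred, leakage-free protocol.  Null
calibration uses `strict` at the full retained feature set: the paper-mode
global ranking biases null accuracy upward, and taking the maximum over
cut-offs adds selection bias, so neither is a calibrated statistic.  With
that construction the pooled null LOSO accuracy is unbiased at 50 % — for
a held-out subject whose two sessions are exchangeable, any classifier
independent of the test data has exactly ½ expected accuracy.

# The synthetic cohort

The generator's defaults are the study conditions: two 3-minute sessions
(Rest, Stroop) per subject, thermal frames at 5 Hz, physiological signals
at 500 Hz, 19 subjects for the headline run (the study's cohort size after
exclusions).  The planted effect preset reproduces the reported direction
pattern with free magnitudes: −0.3 °C mean shift for nose, septum and
periorbital ROIs and +0.2 °C for the left cheek; 1.5× fluctuation SD for
forehead, cheeks, periorbital and maxillary ROIs; +1 µS tonic shift; SCR
rate 2 → 8 events/min; mean RR 850 → 750 ms; LF amplitude 30 → 40 ms and
HF amplitude 40 → 20 ms; respiration 0.25 → 0.35 Hz.

Between-subject variability is drawn once per subject and shared by both
sessions (baseline temperature SD 0.4 °C global + 0.15 °C per ROI, tonic
2.0 ± 0.5 µS, mean RR ± 60 ms, log-normal modulation scaling), which gives
LOSO its real difficulty: the classifier must generalise across subject
baselines, not memorise them.  Realism constants (pixel noise 0.05 °C —
camera-like; trajectory SD 0.1 °C; EDA noise 0.01 µS; RR noise 5 ms) were
fixed before any classifier experiment and are not tuned.

Faces are rendered as rectangles with the 14 ROI patches at fixed
anatomical positions, plus a fixed face-local spatial texture (amplitude
0.3 °C, excluded from the ROI patches) that translates with head motion.
The texture matters: a contrast-free uniform face makes block matching
degenerate whenever an ROI's temperature crosses the surrounding face
temperature (the SSD surface goes flat and the track drifts); real faces
carry vascular thermal texture that anchors trackers in exactly this way.
Head motion is a bounded ±1 px random walk.  All randomness derives from
the root seed by a two-level stream-splitting scheme (root → per-subject
seeds → per-component session seeds), so cohorts are bit-identical across
runs and components are reproducible in isolation.

What the generator does **not** emulate: anatomically realistic face
geometry or occlusions, non-rigid motion, ECG waveform morphology (R-peak
times are emitted directly), EDA motion artefacts beyond white noise, and
any RGB video (landmarks are emitted as metadata).  Passing tests
therefore demonstrate the correctness of the *analysis* under the stated
signal model, not robustness to every failure mode of real recordings.

# Problem sizes and numerical choices

The packaged tests run the headline preset at the full study size
(19 subjects, 180 s sessions, 64 × 64 px frames) once, and use reduced
cohorts (8 subjects, 120 s, 40 × 40 px) for replicated calibration
experiments — the properties checked there (null calibration, effect-rank
monotonicity) are size-invariant, and 40 px is the smallest frame in which
the 11 × 11 tracking patch never leaves the image under the motion walk.
Session durations below 120 s are avoided because the spectral HRV
features require two 64 s Welch segments.

Degenerate inputs are errors, not silent results: fewer than 3 non-collinear
registration points, empty face masks, ROI centres outside the face, RR
series with > 50 % artefacts, HRV series with > 3 s coverage gaps,
spectra without an in-band peak, and non-convergent EDA decompositions all
raise classed conditions (`thermostress_error` subclasses).

# Known limitations

* The block-matching tracker handles integer translations only; sub-pixel
  or rotational motion would need the full pyramidal KLT it stands in for.
* The ν-SVM-RFE criterion is a fixed-α sensitivity, not a retrained margin;
  its behaviour at very small feature counts (p ≤ 2) is noisy, which is
  one reason the accuracy-vs-rank curve rather than a single cut-off is
  reported.
* `paper`-mode LOSO reconstructs a single globally ranked accuracy curve (the construction many applied studies report) and
  therefore inherits its selection leakage; `strict` mode is provided and
  preferred for honest error estimates.
* The exact CBR correction of the cited gas-sensor RFE variant is not
  publicly specified; the joint-cluster-contribution rule implemented here
  is one faithful reading, with the correlation threshold exposed.
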