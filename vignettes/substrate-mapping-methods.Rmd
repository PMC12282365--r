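---
title: "Methods: multi-domain EGM features and leakage-aware classification of VT ablation targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-domain EGM features and leakage-aware classification of VT ablation targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vtsubstrate)
```

## The problem

Re-entrant ventricular tachycardia (VT) is sustained by slow-conducting
channels through infarct scar. Ablating the channel requires knowing where it
is, but mapping the arrhythmia itself is often impossible (most VTs are
haemodynamically unstable). Substrate mapping records intracardiac
electrograms (EGMs) point by point during sinus rhythm (SR) or pacing and
looks for the electrophysiological footprint of the channel. `vtsubstrate`
implements an integrated analysis of such maps: a 46-feature multi-domain
description of every mapping point, distance-based labeling of points near VT
critical sites, mixed-effects association screening, and a machine-learning
classification protocol that respects the grouped structure of the data.
Because clinical mapping-system exports are proprietary and the kind of
animal dataset this analysis is designed for is not openly downloadable, the
package ships a synthetic electroanatomical-study generator that reproduces
the statistical structure the analysis assumes, so the entire pipeline is
testable end to end.

## The feature registry

Each mapping point contributes one unipolar and one bipolar EGM sampled at
2034.5 Hz, with a QRS window (ventricular activation, from the surface ECG)
and a post-QRS window (T-wave for unipolar; everything after the QRS for
bipolar). The 46 features span four domains:

* **Functional** — activation time (`LATB`, latest qualifying deflection of
  the bipolar EGM), repolarization time (`RT`, maximum T-wave upslope of the
  unipolar EGM, the Wyatt convention), activation-recovery interval
  (`ARIB = RT - LATB`, an action-potential-duration surrogate), durations,
  peak-to-peak amplitudes, negative-deflection counts, and maximum/mean
  absolute slopes per window.
* **Spatial** — `GradAT`, `GradRT`, `GradARI`: for each point, the mean of
  `|dv|/distance` over neighbours within 10 mm (closed ball, 3D chord
  distance, computed per map).
* **Spectral** — centre-of-mass frequency (`fB`, `fU`) and spectral peak
  count (`PB`, `PU`) from a Hann-tapered periodogram clipped to the
  channel's band maximum.
* **Time-frequency** — total and fractional band energies from a Smoothed
  Pseudo Wigner-Ville Distribution (SPWVD), 4 bands x 2 windows per channel
  (0–160 Hz in 40-Hz bands for bipolar, 0–80 Hz in 20-Hz bands for
  unipolar), plus per-window totals.

The registry counts 46 distinct features of which 2 are *general parameters*
shared by both channel models: `LATB` (the activation map underlying the
activation-time gradient) and `GradAT` itself. The bipolar model therefore
has 20 + 2 = 22 inputs and the unipolar model 24 + 2 = 26, and all
repolarization information (`RT`, `ARIB`, `GradRT`, `GradARI`) belongs to
the unipolar model only — repolarization is annotated on the unipolar
T-wave, and `ARIB`, despite the B subscript it carries in the field's
notation, is a repolarization quantity. This accounting is the only one
consistent with the printed 46/22/26 split; we document it as the package's
reading rather than an established convention.

## Preprocessing and the two-track filtering decision

Unipolar and bipolar EGMs are band-pass filtered at 0.5–20 Hz and 0.5–40 Hz
respectively, with a 4th-order Butterworth applied forward-backward
(zero-phase, so LAT/RT timings are not shifted), after demeaning and with
reflect-padding against end transients. Annotation (LAT, RT) happens after
filtering.

The spectral bands, however, extend to 160 Hz (bipolar) and 80 Hz
(unipolar) — far above those passbands — and high-frequency fractional
energies are among the most informative features. The only coherent reading
is that morphology/annotation features use the filtered traces while
spectral and time-frequency features are computed on the unfiltered,
acquisition-bandwidth traces. `extract_features()` implements exactly that
split. The acquisition bandwidths themselves (0.5–500 Hz unipolar, 30–300 Hz
bipolar) are treated as metadata and never re-applied.

Detector conventions the source methods leave open, fixed here and exposed
as arguments: a *deflection* for LAT is a negative-going swing (local
maximum to following local minimum) exceeding 20% of the window's
peak-to-peak amplitude, annotated at the swing midpoint; EGM duration
thresholds the rectified, running-median-smoothed (10 ms) signal at 20% of
its window maximum; deflection counting uses a prominence-style depth rule
at the same 20% level.

## The SPWVD

The time-frequency distribution is a Cohen's-class SPWVD computed on the
analytic signal (suppressing cross-terms between positive and negative
frequencies), with separable Gaussian-tapered smoothing windows: a
time-smoothing window of length `round(0.03 N)` samples and a lag
(frequency-smoothing) window of length `round(0.15 N)`, with the taper
attenuated to 0.25 at the window ends. The three parameters (0.03, 0.15,
0.25) are stated by the method this package implements but their exact units
and window families are not recoverable; the interpretation above is a
documented design decision, and correctness is asserted through
*distribution properties* rather than kernel-exact values: the integral
equals the signal energy within 2%, a pure tone localizes within one
frequency bin, and a chirp's ridge is monotone. Signals are FFT-resampled to
five times the channel's band maximum before the SPWVD (400 Hz unipolar,
800 Hz bipolar): the distribution is O(N * Lg * Lh) per trace, and nothing
above the band maximum is used. Small negative excursions of the
distribution are clipped and the matrix renormalized to the exact signal
energy, so band fractions are true proportions in [0, 1].

## Labeling and leakage groups

Points within 6 mm (closed ball — the boundary convention is documented and
configurable) of any VT critical site form the positive class; each positive
point's group is its nearest site (ties to the lowest site id), negatives
group by map. Duplicated points (identical coordinates within 0.01 mm and
identical traces) are removed first. These site groups are the leakage
units: `grouped_split()` (80/20) and `make_folds()` (10-fold, 10 repeats)
never place one group on both sides of any boundary, because points that
describe the same critical site are near-replicates whose separation would
inflate performance. Negatives are re-randomized across folds in every
repeat. The 3–10 mm radius sweep produces nested label sets with
non-decreasing prevalence by construction.

## Association analysis

Features with training-set |skewness| > 2 (the cutoff is this package's
choice) are log1p-transformed after shifting to positive support; all
features are z-scored with training statistics only. Single-variable
logistic regressions with a random intercept per substrate map
(Laplace-approximated ML via `lme4::glmer`) screen all 46 features;
significance uses Bonferroni correction at 0.05/46 ≈ 0.0011, computed from
the tested count rather than hard-coded. Significant features then pass an
iterative worst-first VIF prune (drop the largest VIF until all ≤ 10;
ordering is unspecified in the source and worst-first is our choice), and
the survivors enter one joint mixed model together with map-type indicator
covariates (SR as reference). Odds ratios are per 1 SD. Non-convergence is
flagged in the result, never silent.

## Classification protocol

Classifiers are deliberately standard with fixed hyperparameters: random
forest (100 trees, minimum leaf size 1), SVM (Gaussian kernel, box
constraint 1, Platt-calibrated probabilities for ROC), KNN (k = 10,
Euclidean), and logistic regression as the reference. The package's
contribution is the protocol around them: grouped split, repeated grouped
CV, stratified undersampling at exact 1:1 or 1:5 ratios (all positives
kept; negatives sampled per map by largest-remainder quota), out-of-bag
permutation-importance ranking, sequential feature addition (top 20 kept by
default — the stability-over-optimality choice), a PCA baseline retaining
the fewest components reaching 90% training variance, and evaluation at the
ROC operating point closest to the upper-left corner. The CV repeat with the
highest AUC fixes the operating threshold; test metrics are computed once,
at that CV-derived threshold (the conservative reading — no test-side
threshold tuning). CIs over CV repeats are percentile bootstrap (1000
resamples, seeded). The model suite crosses signal type and map source into
exactly 10 configurations; BIV maps contribute to the all-maps model but are
never modelled alone (too few points).

## The synthetic-study generator

`generate_study()` emulates the study conditions the analysis was designed
for, not any particular dataset:

* Four subjects, each with an SR map (250 points) and LV/RV/BIV paced maps
  (180/180/120 points) on a shared per-subject ellipsoidal shell (axis ratio
  1:1:1.3). Per-map point counts echo the real-world ordering (SR densest,
  BIV sparsest) at roughly one-quarter scale so the full pipeline runs in
  minutes on one CPU.
* The shell is *scaled from the target prevalence*: on a convex shell the
  set of points within chord radius r of a site is a cap of area ~ pi r^2,
  so solving total area = n_sites * pi r^2 / 0.0731 gives the 7.31% positive
  prevalence by construction rather than by tuning. Sites sit along two
  3-site channels (early/mid/late diastolic) through a contiguous scar cap
  covering 25% of the shell, spaced so the 6-mm labeling balls stay
  disjoint.
* Activation time is a propagation field (distance from the pacing origin at
  1.5 mm/ms, slowed 1.8x inside scar); ARI is a smooth base field plus
  spatially rough noise (SD 3 ms) and a 25 ms bump at critical sites (so the
  ARI gradient is genuinely elevated there); RT = LAT + ARI identically.
* EGMs are single-template morphologies with parametric distortions rather
  than biophysical simulations — the analysis only consumes feature-level
  statistical structure. The bipolar trace is the difference of two 3-mm
  offset unipolar sources (the far-field T-wave cancels almost completely).
  Near-channel effects follow the association directions the analysis
  screens for: amplitude loss that *saturates across the scar* (so voltage
  alone separates scar from healthy tissue but not the channel from the
  rest of the scar — the channel must be found through repolarization
  gradients, T-wave flattening, raised central frequency and late/intra-QRS
  high-frequency components), late fractionated bursts (40–160 Hz) whose
  log-odds carry a per-map random intercept (SD 0.5) for the mixed model to
  absorb, and per-point effect jitter (U(0.6, 1.1)) so no single feature is
  a clean detector.
* All randomness derives from one root seed; equal seeds give byte-identical
  studies.

What the generator does **not** emulate: real catheter-contact artefacts,
far-field ventricular composites, anisotropic conduction, mesh-based (rather
than chord) distances, annotation-review errors, and any particular animal's
anatomy. Passing the end-to-end checks therefore shows the *pipeline* is
correct and leakage-free under the assumed structure — not that the printed
real-data performance transfers.

## Numerical choices and degenerate inputs

Zero-variance features are flagged and excluded from models; missing feature
values (e.g. gradients of isolated points, undetectable LAT on flat
signals) propagate as NA and are imputed by training-fold medians only at
the classification stage; duplicate coordinates are excluded from gradient
neighbourhoods (no division by zero); a silent window yields zero total
energy with undefined fractions; degenerate single-class CV folds are
skipped and logged; ties at the labeling radius are inside (closed ball) and
nearest-site ties go to the lowest site id — both conventions documented
because the source states neither.

## Problem sizes used by the shipped checks

The default synthetic study (16 maps, ~2,900 points, ~7% prevalence) drives
the end-to-end checks: the SR-unipolar random forest reaches held-out AUC
well above 0.75, a 10-shuffle permutation null brackets AUC 0.5, and each
single-parameter benchmark (GradAT, GradARI, voltage) trails the
multi-feature forest — the qualitative pattern the integrated approach is
meant to demonstrate, at desk scale. The odds-ratio recovery battery uses 50
replicates of 20 maps x 500 points with a true OR of 2.0. The orchestration
test runs a 2-subject study with a 5-fold x 2-repeat CV; these sizes are the
package's own test-design choices and are stated here so they can be scaled
up by users with more patience.

## Known limitations

Chord (not geodesic) distances everywhere; one representative beat per point
(no multi-beat averaging); the SPWVD parameter interpretation above; no
random slopes in the mixed models; no hyperparameter search beyond the fixed
values; and the synthetic generator's idealizations listed above.
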