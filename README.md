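# vtsubstrate

Localizing ventricular-tachycardia (VT) ablation targets from substrate maps.

Re-entrant VT lives in slow-conducting channels through infarct scar, but the
arrhythmia itself is usually too unstable to map. Substrate mapping instead
records intracardiac electrograms (EGMs) point by point during sinus rhythm
or pacing. `vtsubstrate` turns such electroanatomical maps into ablation-
target predictions for cardiac electrophysiology researchers:

* **46-feature extraction** per mapping point from paired unipolar/bipolar
  EGMs (sampled at 2034.5 Hz, band-passed 0.5–20 / 0.5–40 Hz for morphology):
  functional features (LAT from the latest bipolar deflection; RT as the
  maximum unipolar T-wave upslope; ARI = RT − LAT; durations, amplitudes,
  deflection counts, slopes), spatial gradients of AT/RT/ARI
  (mean |Δv|/distance over 10-mm neighbourhoods), spectral features (central
  frequency, spectral peaks), and Smoothed Pseudo Wigner-Ville (SPWVD)
  band-energy fractions over 2 windows × 4 bands per channel. The bipolar
  model uses 22 features, the unipolar model 26, with 2 shared general
  parameters (LATB, GradAT).
* **Distance-based labeling**: points within 6 mm of a VT critical site
  (entry/isthmus/exit of the diastolic pathway) form the positive class
  (prevalence ≈ 7%), with a 3–10 mm sensitivity sweep.
* **Mixed-effects association screening**: per-feature logistic regressions
  with a random intercept per map, Bonferroni correction (0.05/46), VIF
  pruning (> 10) and a joint multivariable model — odds ratios per 1 SD.
* **Leakage-aware classification protocol**: 80/20 split and 10×10-fold CV
  grouped by VT site (points describing the same site never straddle a
  boundary), stratified 1:1 / 1:5 undersampling, random-forest permutation-
  importance feature pruning (top 20), PCA baseline, a 10-configuration
  suite crossing signal type (both/unipolar/bipolar) with map source
  (all/SR/LV/RV), evaluation at the ROC point closest to the upper-left
  corner, and single-feature benchmarks (GradAT, GradARI, voltage).
* **A seeded synthetic-study generator** that reproduces the statistical
  structure this analysis assumes (scar, channels, critical sites,
  repolarization heterogeneity, late potentials with per-map random effects),
  so everything above is testable without access to clinical exports.

## Worked example

```r
library(vtsubstrate)

study <- generate_study(sim_config(seed = 1))   # 4 subjects, 16 maps
study
#> <vts_study: 4 subjects, 16 maps, 2920 points, 24 VT critical sites>

features <- build_feature_table(study, radius_mm = 6)   # extract + label
mean(features$label)
#> [1] 0.07054795

features <- normalize_features(features,
                               intersect(build_registry()$name, names(features)))

# SR-map, unipolar-only random forest: split by VT-site group, rank by RF
# importance, keep the top 20, 10x10-fold grouped CV, evaluate held out
sr <- dplyr::filter(features, is_SR == 1)
split <- grouped_split(sr, frac = 0.8, seed = 11)
rank <- rf_importance(sr, registry_features(model = "unipolar"),
                      rows = split$train, seed = 3)
ev <- train_eval(sr, split, model_config("RF", rank$feature[1:20]),
                 k = 10, repeats = 10, seed = 5)
ev
#> <vts_eval RF (20 features, undersample none)>
#>   CV AUC 0.985 (95% CI 0.983-0.986 over 10 repeats)
#>   test AUC 0.996 | F1 83.7% | PPV 72.0% | Se 100.0% | Sp 96.2%
```

The CV AUC is the mean over 10 repeats of grouped 10-fold cross-validation;
the test row is computed once on the held-out 20%, at the operating
threshold chosen by the best CV repeat (closest-to-top-left ROC point). On
synthetic data the discrimination is higher than one should expect on real
maps — the generator's point of comparison is the protocol, not the animal.

Traditional single-parameter benchmarks trail the integrated model on the
same held-out points:

```r
single_feature_benchmark(features[features$is_SR == 1, ], rows = split$test)
#> # A tibble: 3 × 3
#>   feature column    auc
#> 1 GradAT  GradAT  0.820
#> 2 GradARI GradARI 0.870
#> 3 voltage AB      0.912
```

`run_pipeline(run_config(seed = 1))` chains simulate → deduplicate → extract
→ label → associate → model suite → distance sensitivity and
`render_report()` lays the results out as per-map summaries, an odds-ratio
table, the 10-row model table and the AUC-versus-radius table;
`autoplot()` methods draw the correlation heatmap, OR forest plot, CV
dispersion and AUC/prevalence bars.

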