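# cardiotex

Radiomics texture analysis of the left-ventricular myocardium on cardiac
CT, for detecting hypertensive remodeling. The package is aimed at
imaging-research groups who want a fully reproducible, testable version of
the classic radiomics workflow: polygonal ROI → gray-level normalization →
large feature vector → screened classifier zoo → a single ensemble score
per subject → feature-relevance and group-comparison statistics.

## What it computes

* **μ ± 3σ normalization.** Pixel values inside the ROI are clipped to
  `[μ − 3σ, μ + 3σ]` and mapped to integer levels `1..Ng`
  (`normalize_mu3sigma()`), removing brightness/contrast variation.
* **377 features per ROI** (`extract_all()`, `extract_features()`):
  9 histogram + 5 gradient + 220 gray-level co-occurrence (11 Haralick
  statistics × 5 distances × 4 directions) + 20 run-length + 5
  autoregressive + 20 Haar wavelet energies + 98 geometry descriptors,
  under MaZda-style names (`S(1,0)DifEntrp`, `Horzl_RLNonUni`, `GeoEl`, …).
* **Classifier zoo** (`train_zoo()`): PLS-DA, NB, GLM, LR, FLM, DL, DT,
  RF, GBT, aNN, SVM on a stratified 70:30 split, with training-side
  screening (`screen_features()`) and autoscaling (`autoscale()`).
* **EML score** (`eml_report()`): for models with cross-validation
  accuracy > 60%,

  `EML(x) = Σ_m s_m(x) · acc_m · conf_m(x)`, `s_m = +1` for an HTN vote,
  `−1` for an NC vote — with the Youden-optimal cutoff, DeLong AUC ± SE,
  confusion-matrix metrics, and the Pearson correlation of the score with
  LV septum width.
* **Shadow-feature relevance** (`run_boruta()`): Boruta-style loop —
  permuted shadow copies, random-forest importance, max-shadow threshold,
  binomial aggregation over iterations.
* **Group statistics** (`smile_table()`, `clinical_summary()`,
  `dagostino_pearson()`, `ttest_summary()`, `bh_fdr()`, `chi2_test()`):
  pooled Student t with BH-FDR, Yates-corrected χ², fold changes and
  smile-plot coordinates (−log10 adjusted p vs log2 FC).
* **Synthetic cohorts** (`cohort_spec()`, `generate_cohort()`): a
  two-class image cohort (default 83 HTN vs 75 NC) calibrated to the
  published septum-width, ROI-area and elongation group summaries, so the
  full pipeline runs and is tested without any patient data.

Results are tibbles or small S3 objects with `tidy()` / `glance()` /
`autoplot()` methods; `run_pipeline(pipeline_config(...))` executes the
whole analysis and can write every stage artifact (CSV/JSON) plus a
seed-stamped `summary.json`.

## Worked example

```r
library(cardiotex)

spec <- cohort_spec(n_htn = 30, n_nc = 30, seed = 7, image_size = 64)
cfg  <- pipeline_config(seed = 7, spec = spec, cv_folds = 3,
                        tuning_budget = 1, num_trees = 100,
                        boruta_iter = 50, boruta_trees = 60)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 60 subjects, 377 features ( 364 retained )
#>   ensemble: 11 models, accuracy 0.944 , AUC 0.988
#>   smile-flagged: 15 ; boruta-confirmed: 6
```

60 synthetic subjects were simulated, 377 features extracted per ROI, 364
survived screening, all eleven models beat the 60% cross-validation gate,
and the fused EML score classifies the 18 test subjects with accuracy
0.944 and AUC 0.988 (a strong, small-cohort synthetic effect; see the
vignette for calibrated settings that land near the reference AUC of
~0.73). Per-model and ensemble details:

```r
glance(res$eml)
#> # A tibble: 1 × 10
#>   n_models   auc auc_se auc_p_value cutoff accuracy sensitivity specificity …
#> 1       11 0.988 0.0175   1.13e-171  -3.76    0.944       0.889           1

head(dplyr::arrange(tidy(res$boruta), dplyr::desc(hit_count)), 5)
#> # A tibble: 5 × 5
#>   feature         hit_count hit_fraction      p_value decision
#> 1 WavEnHH_s-1            44         0.88 0.0000000324 confirmed
#> 2 Sigma                  43         0.86 0.000000210  confirmed
#> 3 S(1,-1)DifEntrp        42         0.84 0.00000116   confirmed
#> 4 S(1,0)DifEntrp         40         0.8  0.0000239    confirmed
#> 5 S(1,-1)Contrast        40         0.8  0.0000239    confirmed
```

The relevance stage confirms difference-entropy and residual-variance
texture features — the same families flagged in the clinical study this
pipeline reimplements. `plot_smile(res$smile)`, `autoplot(res$eml)`,
`plot_score_groups(res$eml)` and `plot_score_septum(res$eml, clinical)`
reproduce the standard figures (smile plot, ROC, score-by-group box plot,
score-vs-septum scatter).

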