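# nucmorph

Quantitative histomorphometry of H&E tissue-microarray spots for
recurrence prognosis in node-negative gastric adenocarcinoma.

Node-negative gastric cancer usually does well after resection, so the
real clinical question is which minority of patients will recur and
might benefit from adjuvant chemotherapy. `nucmorph` implements an
image-analysis answer: it segments every nucleus in one H&E TMA spot
per patient, summarizes nuclear morphology and tissue architecture in
a named 189-feature vector, learns a small stable feature subset on a
training cohort, trains a grid of standard classifiers, calls
recurrence from the winning model's probability, and carries the calls
into Kaplan–Meier / log-rank / Cox survival analysis and
immunohistochemistry (HER2, Ki67) association tests. A synthetic TMA
generator with ground-truth masks and outcome cohorts makes the whole
pipeline runnable and testable without patient data.

## The method in brief

* **Stain separation** — Beer–Lambert optical densities projected onto
  the standard H&E stain basis (`color_deconvolve()`).
* **Segmentation** — Otsu threshold on the hematoxylin density, then a
  marker-controlled watershed on the smoothed distance transform, with
  30–5000 px² area filtering (`segment_nuclei()`).
* **Features (189)** — per spot: 100 nuclear-shape aggregates (25
  descriptors × mean/SD/median/min-max ratio, including exact Hu
  moments and Fourier boundary descriptors), 30 texture aggregates
  (GLCM contrast/energy/entropy/inverse variance + intensity invariant
  moment, per RGB channel), 39 orientation-disorder aggregates (13
  Haralick-family descriptors of nuclear-angle co-occurrence over
  5-nearest-neighbor graphs × mean/SD/range), 12 Voronoi and 8
  Delaunay architecture aggregates using the bounded disorder
  statistic `1 − 1/(1 + SD/mean)` (`compute_spot_features()`).
* **Selection** — Wilcoxon rank-sum, mRMR and random-forest rankings,
  each stabilized over 100 iterations of randomized stratified 3-fold
  splits; each scheme's bin is its 5 most frequently selected features
  (`stability_select()`).
* **Classification** — {LDA, QDA, linear SVM, random forest} × the 3
  bins = 12 combinations, scored by repeated cross-validation; the
  best combination by mean AUC becomes the image classifier, and a
  spot is called recurrence-positive iff its predicted probability
  exceeds 0.5 (`train_eval_grid()`, `pick_best_combo()`,
  `predict_recurrence()`).
* **Downstream statistics** — product-limit curves, log-rank tests,
  Efron-tie Cox models with Wald CIs, Fisher/chi-square marker
  association with the Ki67 index binarized at 14%
  (`km_curve()`, `logrank_test()`, `cox_fit()`, `association_test()`).

## Worked example

```r
library(nucmorph)

# 1. A synthetic spot with ground truth, segmented and featurized
sp  <- spot_sim_params(n_nuclei = 50, width = 320, height = 320,
                       clustering = 0, seed = 7)
sim <- generate_spot_image(sp)
seg <- segment_nuclei(color_deconvolve(sim$image)$hematoxylin)
seg$n_nuclei
#> [1] 50
fv <- compute_spot_features(seg, sim$image, spot_id = "demo")
length(fv)
#> [1] 189
round(fv[c("shape:area_ratio:mean", "orient:entropy:mean",
           "voronoi:area:disorder")], 3)
#>  shape:area_ratio:mean    orient:entropy:mean  voronoi:area:disorder
#>                  0.800                  2.464                  0.251
```

The spot's nuclei fill ~80% of their enclosing circles (regular
ellipses), carry substantial orientation-co-occurrence entropy (the
default κ = 4 leaves real angular spread), and sit in a mildly
irregular tessellation.

```r
# 2. A 160-patient cohort: select, train, call, analyze survival
sim <- generate_cohort(cohort_sim_params(n_patients = 160, seed = 3))
sp  <- split_cohort(sim, n_train = 60, seed = 3)
y   <- factor(sp$train$cohort$recurrence, levels = 0:1)

bin <- stability_select(sp$train$features, y, "WRST", seed = 1)
bin$features
#> [1] "orient:intensity_entropy:range" "shape:perimeter_ratio:sd"
#> [3] "voronoi:perimeter:disorder"     "orient:intensity_average:sd"
#> [5] "orient:energy:range"

model <- train_model(sp$train$features, y, bin$features, "MSV", seed = 2)
calls <- predict_recurrence(model, sp$test$features)
auc_score(calls$probability, factor(sp$test$cohort$recurrence, levels = 0:1))
#> [1] 0.9989035

tc <- sp$test$cohort; tc$call <- calls$label
logrank_test(tc$time, tc$event, tc$call)$p_value
#> [1] 2.550995e-15
cox_fit(tc, c("call", "t_stage", "histology", "invasion"))[1, ]
#>   variable hazard_ratio  ci_low  ci_high      p_value
#> 1     call      10.0007  4.5799  21.8376 7.523265e-09
```

The five selected features are exactly the disorder-linked features
the generator shifts; the held-out AUC is near-perfect at the
generator's default 1.5-SD effect; and classifier-positive patients
carry a large independent hazard in the multivariate Cox model.

`run_pipeline(default_run_config(demo = TRUE))` chains all stages —
including rendering and segmenting every patient's spot image — into a
run directory with per-stage CSVs and a reproducibility manifest.

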