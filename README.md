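# radiocascade

Texture radiomics for telling **solitary pulmonary capillary
haemangioma (SPCH)** — a rare benign lung tumour — apart from
**lepidic-predominant adenocarcinoma (LPA)** on chest CT.  Both present
as ground-glass nodules and are hard to distinguish even for
experienced readers; misclassification means unnecessary lung surgery.
The package is aimed at medical-image-analysis researchers who want a
complete, reproducible implementation of the divide-and-conquer
radiomics approach for this imbalanced two-class problem, runnable
end-to-end without any patient data.

## What it computes

**Features.** For each lesion (CT volume + binary mask), 26 radiomic
features: 5 histogram features (skewness, kurtosis, 75th / 97.5th
percentile, uniformity) and 21 grey-level co-occurrence matrix (GLCM)
features of the Haralick family, built from all horizontally adjacent
in-mask voxel pairs with symmetric accumulation:

```
p(i,j) = (# adjacent pairs with levels i,j) / (total pairs)
contrast = Σᵢⱼ (i−j)² p(i,j),   correlation = (Σᵢⱼ ij·p − μxμy)/(σxσy),  ...
```

**Model.** A two-level cascade with a linear SVM at each node and
SPCH as the positive class:

* *Root*: PCA of the unstandardised feature matrix → 2 components; an
  SVM on the scores; the decision threshold is pushed as far as it can
  go **subject to forwarding 100% of training SPCH**, picking out the
  LPA cases that are confidently LPA (gate output `P1 ∈ {0, 1}`).
* *Leaf*: on forwarded cases only, 2 features chosen by sequential
  forward selection (leave-one-out balanced-accuracy criterion), an
  SVM, and Platt calibration (`P2 ∈ [0, 1]`).

The SPCH probability is `P = P1 × P2`.  A single-stage baseline (3–6
forward-selected features, one SVM) is the comparator.

**Evaluation.** Leave-one-out cross-validation with full pipeline
refitting per fold; rank-based AUC; sensitivity/specificity/accuracy
at a probability threshold; and the Hanley–McNeil z-test for two
correlated AUCs, `z = (A1−A2)/√(SE1² + SE2² − 2 r SE1 SE2)`, with the
correlation term `r` interpolated from a tabulated binormal-model
surface.  Univariate group statistics follow the standard reporting
recipe: mean-centred Levene test, then pooled or Welch two-sample
t-test per feature.

**Data.** A seeded synthetic GGN cohort generator (13 SPCH vs 49 LPA
by default, with LPA an easy/hard mixture) makes the whole pipeline
testable; the printed per-feature summary statistics of the clinical
reference cohort ship as a plain-text table (`reference_summaries()`).

## Worked example

```r
library(radiocascade)

ft <- cohort_features(default_spec(seed = 1))   # simulate + extract
m  <- fit_cascade(ft)
summary(m)
#> Cascade model summary
#>   PCA-2 explained variance fraction: 0.9999
#>   root gate: tau = 0.45753 | picked out 33 cases | forwarded-set PPV = 0.448
#>   leaf features: sum_average, skewness
#>   training cases: 62 ( 29 forwarded )

cv_c <- loocv_scores(ft, trainer = "cascade")
cv_b <- loocv_scores(ft, trainer = "baseline")
roc_summary(cv_c$P, cv_c$label)
#> AUC = 0.9490
#> At threshold 0.5: sensitivity 92.3%, specificity 100.0%, accuracy 98.4%
compare_auc(cv_c$P, cv_b$P, cv_c$label)
#> Correlated AUC comparison (Hanley-McNeil)
#>   A1 = 0.9490 (SE 0.0436)   A2 = 0.6860 (SE 0.0889)
#>   within-class rank correlation = 0.198 -> r = 0.182
#>   z = 2.870, two-sided p = 0.0041
```

Read: two principal components carry >99.9% of raw feature variance;
the gate removes 33 confident-LPA cases while forwarding all 13 SPCH;
out-of-fold, the cascade ranks cases far better than the baseline
(AUC 0.949 vs 0.686), and the correlated-AUC test calls that
difference significant.  (Numbers are from the seed-1 synthetic
cohort; your exact values depend only on the seed.)

There is also a command-line wrapper:

```sh
Rscript inst/cli/radiocascade.R simulate --out cohort/ --seed 1
Rscript inst/cli/radiocascade.R extract  --manifest cohort/manifest.csv --out features.csv
Rscript inst/cli/radiocascade.R loocv    --features features.csv --out results/run
Rscript inst/cli/radiocascade.R table-stats --features features.csv --out stats.csv
```

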