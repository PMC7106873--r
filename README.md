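# ldfuse

Feature-level fusion of multimodal biomedical feature tables for disease
classification, with honest cross-validated evaluation. The package is aimed
at studies that collect several numeric feature blocks per subject — e.g.
regional MRI volumes, regional PET uptake and CSF biomarkers for
NC/MCI/AD diagnosis — where subjects have missing entries or whole missing
modalities, and the feature blocks carry both dense noise and occasional
grossly corrupted samples.

## The method

Each modality is a matrix `A` (d features × n samples). The pipeline is:

1. **KNN imputation** — a missing entry is the inverse-distance-weighted
   mean of the K nearest samples observing that feature,
   `w_i = (1/d_i) / Σ_j (1/d_j)`, distances Euclidean over co-observed
   features (K = 5 by default).
2. **Low-rank representation denoising** — per modality, solve

   ```
   min_{X,E}  ||X||* + λ ||E||_{2,1}   s.t.  A = A X + E
   ```

   by inexact ALM (`||X||*` = nuclear norm, `||E||_{2,1}` = sum of column
   norms). `A X` is the denoised modality; the column-sparse `E` captures
   corrupted samples. On noiseless rank-r input the solution equals the
   shape-interaction matrix `V_r V_rᵀ`, which the tests verify.
3. **Discriminant correlation analysis fusion** — per feature-set pair,
   unitize the between-class scatter `S = Φ Φᵀ`
   (`Φ = [√m_j (ā_j − ā)]_j`), diagonalize the transformed cross matrix by
   SVD with `W_ca = U Σ^{-1/2}`, `W_cb = V Σ^{-1/2}`, project
   (`A* = W_a A`, `B* = W_b B`) and concatenate in series. Three or more
   modalities are fused by a left-fold cascade.
4. **Linear SVM under repeated stratified 10-fold CV** — reporting ACC,
   SEN, SPE, BAC, PPV, NPV (mean ± SD over all folds) and pooled ROC/AUC.
   Every fitted statistic (imputer, LRR dictionary, DCA transform, scaler,
   SVM) is learned on training folds only.

A synthetic generator (`simulate_multimodal()`) produces datasets with
known low-rank class structure, column-sparse corruption and exact-count
missingness, so the whole pipeline is testable without restricted clinical
data.

## Worked example

```r
library(ldfuse)

d <- simulate_multimodal(sim_config(seed = 1))
d
#> Multimodal dataset: 150 samples, 3 modalities
#>   MRI: 93 features, 1395 missing cells
#>   PET: 93 features, 1395 missing cells
#>   CSF: 3 features, 45 missing cells
#> Classes: NC (50), MCI (50), AD (50)

sub <- subset_task(d, positive = "AD", negative = "NC")
cv <- repeated_cv(sub, ldf_pipeline(), n_folds = 10, n_repeats = 2, seed = 1)
cv
#> Repeated CV: 10 folds x 2 repeats, positive = 'AD' (fold protocol)
#>   ACC: 98.00 +/- 4.10 %
#>   SEN: 98.00 +/- 6.16 %
#>   SPE: 98.00 +/- 6.16 %
#>   BAC: 98.00 +/- 4.10 %
#>   PPV: 98.33 +/- 5.13 %
#>   NPV: 98.33 +/- 5.13 %
#>   AUC (pooled): 0.998
```

Read: on this synthetic AD-vs-NC task (50 + 50 subjects, 10% missing cells,
10% corrupted samples), the fused pipeline classifies 98% of held-out
subjects correctly, with sensitivity and specificity balanced; the ± values
are the SD across the 20 fold results. `plot(cv)` draws the pooled ROC
curve. A single fitted model with a `predict` method is available as
`fit <- ldf(d); predict(fit, newdata)`, and `compare_methods()` evaluates
the fusion pipeline against KNN/EM/SVD-impute-then-concatenate and CCA
baselines on identical folds.

There is also a thin CLI over the same functions
(`exec/ldfuse simulate|impute|denoise|fuse|evaluate|run`), driven by flags
or a YAML config; `run` writes a metrics table, per-fold results, ROC
points and a reproducibility manifest.

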