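# boostfill

Missing-value imputation for mixed-type tabular data — continuous,
categorical and Boolean columns in one table — combining low-rank
matrix-factorization completion with per-column gradient-boosted
ensembles, refined over sequential passes.

## Who this is for

Anyone holding a samples-by-variables table with holes in it: gene- or
protein-expression matrices with dropouts, clinical and epidemiological
registries with partial records, survey data with non-responses. Most
downstream models require a complete matrix, and naive fills (zeros,
column means) ignore the structure that ties columns together. `boostfill`
exploits that structure twice — once linearly, once non-linearly.

## The method

Given a table **X** with missing mask **Ω**, the engine runs four stages:

1. **Preprocessing.** Missing-value aliases (`NA`, `#DIV/0!`, `#VALUE!`,
   empty cells, …) are normalized to `NA`; zeros can optionally be treated
   as missing. Each column is typed by a strict majority rule: if more
   than 60% of its non-missing cells parse as numbers it is *continuous*
   (text cells coerced to `NA`); if more than 60% are non-numeric tokens
   it is *categorical* (numeric cells coerced); otherwise the column is
   *excluded* and passed through untouched. Categorical columns are
   label-encoded (lexicographic codes `0..K−1`), and remaining gaps are
   pre-filled by column mean/mode, k-nearest neighbours, or a mix. The
   stage yields three aligned tables: clean, encoded, pre-imputed.

2. **Adaptive factorization.** The pre-imputed matrix is completed by a
   low-rank model: non-negative matrix factorization
   **X ≈ W·H** (multiplicative updates) when every observed value is
   non-negative, truncated SVD **X ≈ U·D·Vᵀ** (column-mean-centered)
   otherwise. An outer loop alternates fit → reconstruct → refill of the
   originally-missing cells until their relative change drops below a
   tolerance. Observed cells are never altered in the default
   `nan_only` mode; `full` mode returns the denoised reconstruction.

3. **Boosted per-column imputation.** Each column with missing cells is
   imputed from all the others: the target column is removed from the
   completed matrix, an XGBoost regressor (continuous) or classifier
   (categorical) is trained on the rows where the target is observed, and
   an ensemble of 3–9 models — each fit on an independent 70% row
   subsample — predicts the missing rows. Regressors average predictions;
   classifiers average class-probability vectors and take the argmax.
   Hyperparameter search (seeded random search with a validation split)
   runs only when the dataset passes a gate: more than 50 samples,
   sample-to-feature ratio at least 4, and at most 100 missing columns;
   otherwise fixed defaults are used.

4. **Iterative refinement.** Stages 3 repeats for 1–9 passes. Columns
   are visited in ascending order of missing count with in-place
   (Gauss–Seidel) updates, so later columns see earlier columns' fresh
   imputations; parameters tuned in pass 1 are cached and reused.

A benchmark harness generates synthetic mixed-type tables with known
latent low-rank structure, masks cells completely at random (MCAR), and
scores imputations on the masked cells only (RMSE for continuous,
proportion correct for categorical).

## Worked example

```r
library(boostfill)

syn    <- generate_synthetic(n_rows = 200, n_cont = 8, n_cat = 2,
                             n_bool = 1, latent_rank = 3, seed = 1)
masked <- mask_mcar(syn$data, fraction = 0.2, seed = 2)
fit    <- boostfill(masked$masked, n_iterations = 2, master_seed = 7)
fit
#> <boostfill> 200 rows x 11 columns; 440 cells imputed over 2 pass(es)
#>   factorization: svd (rank 8)

glance(fit)
#> # A tibble: 1 × 9
#>   n_rows n_cols n_missing_cells n_excluded n_iterations final_change mf_method
#> 1    200     11             440          0            2        0.227 svd

score_imputation(fit$imputed_clean, syn$truth, masked$mask, fit$profiles)
#> # A tibble: 1 × 4
#>   rmse_continuous accuracy_categorical n_masked_continuous n_masked_categorical
#> 1           0.912                0.544                 326                  114
```

The 440 masked cells are recovered with RMSE 0.91 on the continuous
columns (the column-mean baseline on the same mask sits near 1.2) and
54% exact category recovery on the 3-class categorical and Boolean
columns. `tidy(fit)` lists one record per column per pass;
`autoplot(fit)` plots the per-pass mean absolute change of the imputed
cells, which should settle as the feedback loop converges.

For file-based workflows there is a command-line launcher:

```sh
inst/cli/boostfill impute --input data.csv --output-dir out --seed 7
inst/cli/boostfill benchmark --output-dir bench --rows 200 --seed 7
```

`impute` writes `imputed_clean.csv`, `imputed_encoded.csv`, a
`manifest.json` sufficient to reproduce the run bit-identically, and a
log.

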