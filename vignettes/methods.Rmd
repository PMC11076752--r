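---
title: "How boostfill imputes mixed-type tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How boostfill imputes mixed-type tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boostfill)
```

`boostfill` fills missing cells in a table whose columns may be
continuous, categorical or Boolean. This vignette explains the model and
its assumptions, the knobs that matter, the numerical choices, what the
synthetic generator does and does not emulate, and the design decisions
taken where the design was genuinely open.

## The model

The engine treats imputation as a chained-prediction problem with a
linear warm start. Let $X \in \mathbb{R}^{n \times p}$ be the encoded
table and $\Omega$ the set of observed cells.

**Warm start by low-rank completion.** Missing cells are first filled by
a simple rule (column mean/mode or kNN), then refined by a low-rank
model: find $W \in \mathbb{R}^{n \times r}_{\ge 0}$,
$H \in \mathbb{R}^{r \times p}_{\ge 0}$ minimizing
$\lVert X - WH \rVert_F^2$ (NMF, multiplicative updates) when all
observed values are non-negative, or the truncated SVD of the
column-centered matrix otherwise. An outer loop alternates *fit* →
*reconstruct* → *refill the originally-missing cells*, so the factor
model is progressively estimated on better and better data while
observed cells stay untouched. This warm start reduces the bias that a
pure mean fill would hand to the supervised stage.

**Non-linear refinement by chained boosting.** Each column $j$ with
missing cells is then predicted from the other columns: train an XGBoost
model on the rows where $X_{\cdot j}$ is observed, predict the rest. An
ensemble of $m$ models, each trained on an independent 70% row subsample
drawn without replacement, is averaged — predictions for a regressor,
class-probability vectors (then argmax) for a classifier, because a
literal mean of nominal class codes has no meaning. Passes repeat with
in-place updates: within a pass, later columns see earlier columns'
fresh values (Gauss–Seidel style), and subsequent passes re-predict
every originally-missing cell from the previous pass's state.

**Assumptions.** The approach assumes missingness is ignorable given the
observed columns (MAR at most; the benchmark generates MCAR), that
columns carry mutual information (a table of independent columns gains
nothing over a mean fill), and that a modest number of latent factors
plus tree-friendly non-linearities capture the dependence structure. It
does not model imputation uncertainty: a single completed table is
returned, not multiple draws.

## Column typing and preprocessing

Cells matching a closed alias set (`NaN`, `NAN`, `Nan`, `nan`, `NA`,
`#NA`, `N/A`, `NA#`, `#VALUE!`, `#DIV/0!`, plus empty and
whitespace-only strings) become `NA`. The alias list is deliberately
closed — an open-ended list is untestable — and extensible via the
`tokens` argument. Zeros can optionally be declared missing
(`impute_zeros`), which matters for dropout-ridden expression data.

A column is typed by strict majority over its **non-missing** cells:
more than 60% numeric ⇒ continuous, more than 60% non-numeric ⇒
categorical, anything else (including an exact 60/40 split) ⇒ excluded,
carried through output untouched and never imputed. Computing the
fractions over non-missing cells means deleting cells can never silently
flip a column's type. Boolean tokens (`TRUE`/`False`/…) are a two-class
categorical: they need no separate learner path. Minority cells of a
typed column are coerced to `NA` and counted in the profile
(`n_coerced`), making the coercion auditable.

Label encoding assigns codes $0..K-1$ in C-locale lexicographic order of
category text — determinism across platforms was preferred over
first-appearance order, which depends on row order.

## Tunable parameters

| knob | default | meaning |
|---|---|---|
| `pre_impute_strategy` | `column_mean` | warm-start fill: mean/mode, kNN (`k = 5`, Euclidean on min-max-scaled mean-filled matrix), or `mix_type` (mean for continuous, kNN for categorical) |
| `mf_method` | `auto` | NMF if all observed values ≥ 0, else SVD; `off` skips the warm start |
| `mf_rank` | `auto` = `min(8, n−1, p−1)` | factorization rank; small ranks regularize |
| `mf_mode` | `nan_only` | refill only missing cells; `full` returns the denoised reconstruction everywhere |
| `n_models` | 3 (range 3–9) | ensemble size; gains beyond 3 are usually marginal |
| `n_iterations` | 3 (range 1–9) | refinement passes; the loop reports but never stops on convergence |
| `use_tuning` | `FALSE` | random-search tuning where the gate allows; `n_trials` (default 20) should be raised, not lowered — few-trial searches underperform the fixed defaults |
| `master_seed` | 42 | drives every random draw |

The tuning gate (more than 50 samples, sample-to-feature ratio ≥ 4, at
most 100 missing columns) exists because a search scored on a 20%
validation split of a small table mostly fits noise. When the gate
denies, fixed defaults are used: 300 trees, depth 6, learning rate 0.1,
row/column subsample 0.8, minimum child weight 1, L2 = 1 — stable
mid-range values stated explicitly so runs are reproducible. The search
space spans learning rate log-uniform on [0.01, 0.3], depth 3–9,
100–600 trees, subsample [0.6, 0.9], column subsample [0.5, 1],
minimum child weight [1, 10], L2 log-uniform on [0.001, 10].

The 70% ensemble subsample is *data-level* row sampling without
replacement, separate from XGBoost's internal per-tree `subsample`
(0.8); both are exposed. Sampling without replacement was chosen over
bootstrap so that each model sees 70% distinct rows, maximizing
between-model diversity at this rate.

## Numerical choices

- **NMF scaling.** Columns are scaled to $[0,1]$ by their maxima before
  factorization, so label codes and wide continuous columns share scale.
  A full min-max transform (subtracting the column minimum) was rejected:
  the affine shift raises the rank of a low-rank matrix by one, which
  visibly degrades completion of exactly low-rank data. Pure rescaling
  is rank-preserving. SVD needs no scaling; it is column-mean-centered,
  which also preserves low-rank structure.
- **Outer loop.** Default cap 10 iterations, tolerance $10^{-4}$
  relative $\ell_1$ change on the refilled cells; inner NMF cap 500
  updates at relative objective tolerance $10^{-4}$. On exactly rank-1
  inputs the loop converges linearly; callers wanting oracle-grade
  accuracy raise `max_outer_iters`.
- **Clipping.** NMF refills are clipped at 0 (the method's range
  contract); SVD reconstructions are never clipped.
- **Ties.** Modal fills and classifier argmax ties break toward the
  smallest code, i.e. the lexicographically first category.
- **Degenerate columns.** A column with fewer than 10 observed rows, or
  a categorical column with a single observed class, cannot support a
  supervised model; such columns fall back to their pre-imputed values
  and the fallback is recorded in `tidy()` output. All-missing columns
  are excluded with a warning at typing time.
- **Column visit order.** Ascending missing count, ties by original
  position: easiest columns stabilize first, so harder columns see
  better features. The spec of the update is Gauss–Seidel within a pass;
  a buffered (Jacobi) mode is deliberately not offered — two update
  semantics double the test surface for little practical gain.
- **Seeds.** Every stochastic step (NMF init, tuning splits and
  candidates, ensemble subsamples) derives its seed from `master_seed`
  plus a fixed offset per stage, column and pass, so runs are
  bit-identical and individual stages remain independently
  reproducible.

## The synthetic generator

`generate_synthetic()` builds the study conditions for validation: a
non-negative continuous block $WH$ with exact latent rank (absolute
Gaussian factors) plus Gaussian noise (default SD = 5% of the noiseless
range), and categorical/Boolean columns derived by quantile-thresholding
the latent row factors, so every column is genuinely predictable from
the others. Benchmarks mask this fully observed table MCAR at
1%–40% and score only masked cells.

What the generator does **not** emulate: missingness that depends on
values (MAR/MNAR), heavy-tailed or zero-inflated marginals, outliers,
batch structure, and columns with no mutual information. Passing
benchmarks on these tables therefore demonstrates that the engine
recovers low-rank-plus-threshold structure under MCAR — not that it is
superior on any particular real dataset. The benchmark sizes used by the
test suite and the acceptance script (tables up to 500×20, ten seeded
replicates, single pass, no tuning) were chosen as the smallest
configuration at which the engine's advantage over a column-mean fill
is stable across seeds.

## Known limitations

- Tables with more features than samples gate out of tuning and strain
  the per-column models; the engine targets $n > p$ data.
- Excluded (mixed-type) columns are never imputed; their information is
  also never used as features.
- Single imputation only: no between-imputation variance, no pooling.
- The categorical accuracy of the benchmark counts exact matches; no
  partial credit for ordinal closeness.
- Runtime scales with the number of missing columns times passes times
  ensemble size; very wide tables should use `subgroup_size` for the
  factorization and a single pass first.
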