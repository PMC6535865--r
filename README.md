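# amnd

Attention-weighted multi-NMF feature fusion for breast-cancer prognosis
classification.

## The problem

Five-year survival of breast-cancer patients is predicted from two
modalities: a high-dimensional, nonnegative gene-expression matrix and a
small set of clinical covariates (age at diagnosis, tumor size, grade,
...). Expression data need aggressive dimensionality reduction before a
classifier can use them, and no single reduction captures everything: the
package therefore extracts features with **five different nonnegative
matrix factorization (NMF) solvers** and lets each patient's clinical
profile decide, through an attention mechanism, how much to trust each
solver's representation.

## The model

Given a nonnegative expression matrix `V (m × n)`, each solver finds
`V ≈ W H` with `W (m × r) ≥ 0`, `H (r × n) ≥ 0`; row *i* of `W` is sample
*i*'s feature vector. The five solvers — multiplicative updates (`mu`),
alternating exact nonnegative least squares (`als`), ALS with
optimal-brain-surgery pruning of negative coefficients (`alsobs`),
projected gradient with Armijo backtracking (`pg`), and
Frobenius-regularized NMF (`pnmf`) — all start from the same deterministic
NNDSVD (SVD-based) initialization.

For sample *i* with clinical vector `c(i)` and solver-*j* features
`f_j(i)`, attention scores are the bilinear forms

    w_j(i) = f_j(i)' X c(i),      ŵ(i) = softmax(w(i)),

with one trainable matrix `X (r × d_c)`. The fused representation
`F(i) = Σ_j ŵ_j(i) f_j(i)` is concatenated with `c(i)` and classified by a
feed-forward network (sigmoid output, binary cross-entropy), trained
end-to-end so that gradients flow into `X` as well. Ablation variants
(uniform 0.2 weights, clinical-only, expression-only, single-solver) are
the same model family under `model_config(variant = ...)`.

Evaluation follows the repeated-repartition protocol: stratified 80/10/10
splits (per class, validation and test each get `round(0.1 · class size)`
samples), re-split / re-train / re-test over many seeds, and report mean
AUC, accuracy, precision, recall and F1 on the test parts. A seeded
synthetic cohort generator (planted low-rank expression, partially
informative clinical features, ~75/25 outcome imbalance) makes every part
of the pipeline testable without any external download.

## Worked example

```r
library(amnd)

cohort <- generate_synthetic_cohort(cohort_config(m = 300, n = 200, r0 = 5, seed = 1))
cohort
#> amnd synthetic cohort: 300 samples x 200 genes, 25 clinical features;
#> 225 long-term / 75 short-term (seed 1)

run <- amnd_run(cohort$expression, cohort$clinical, cohort$labels,
                r = 10, split_seed = 1,
                solver_cfg = solver_config(max_outer_iter = 50),
                model_cfg = model_config(variant = "amnd", seed = 1))
run$metrics
#> # A tibble: 1 × 7
#>     auc   acc   pre recall    f1 n_pos n_neg
#> 1 0.790 0.733 0.733      1 0.846    22     8

glance(run$model)
#> # A tibble: 1 × 4
#>   variant epochs best_epoch best_val_auc
#> 1 amnd        33         13        0.858

head(attention_weights(run$model, run$stack, run$clinical), 3)
#> # A tibble: 3 × 6
#>   sample_id    mu   als alsobs    pg  pnmf
#> 1 S0001     0.185 0.211  0.203 0.216 0.185
#> 2 S0002     0.208 0.192  0.192 0.199 0.208
#> 3 S0003     0.217 0.188  0.192 0.189 0.215
```

The run factorizes the normalized expression matrix with all five solvers,
trains the attention-fusion classifier on the 80% training part (early
stopping on validation AUC), and reports test-part metrics: here AUC 0.79
on the 30 held-out samples, with recall 1 (every long-term survivor
found) at precision 0.73. The attention weights hover near the uniform
0.2 — per-sample deviations are what the bilinear score learned from the
clinical data. `autoplot()` methods exist for factorizations (objective
traces), ROC curves, training histories and repeated-experiment reports;
`tidy()`/`glance()` return tibbles throughout.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/amnd.R simulate --m 300 --n 200 --seed 1 --out cohort/
Rscript inst/cli/amnd.R factorize --expression cohort/expression.tsv \
    --clinical cohort/clinical.tsv --labels cohort/labels.tsv \
    --rank 10 --out fact/
Rscript inst/cli/amnd.R train    ... --variant amnd --out run/
Rscript inst/cli/amnd.R evaluate ... --variants amnd,only_clinical --n_repeats 10 --out eval/
```

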