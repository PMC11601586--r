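# rewirekit

Interpretable latent-factor analysis of transcriptional rewiring in
single-cell RNA-seq data.

Exposures like cigarette smoke do not just shift individual genes up or down
— they rewire the co-expression programs that cells run. Standard single-cell
pipelines (cluster cells, test genes one at a time) cannot see this:
univariate differential expression misses genes that matter only jointly, and
cell clustering says nothing about gene modules. rewirekit implements the
complementary analysis for researchers studying condition-induced injury in
complex tissues: it clusters *genes* into identifiable overlapping latent
factors, asks which factors discriminate exposed from control cells with
finite-sample error control, couples the factors to protein–protein
interaction subnetworks, and tests whether a factor's gene signature predicts
exposure in other cell types and independent datasets.

## The model and the method

Expression follows an overlapping factor model `X = Z Aᵀ + E` with
`Z ~ N(0, C)`. Identifiability is anchored by *pure variables* — genes
loading on exactly one factor. The estimator is a three-step procedure on the
gene–gene correlation matrix Σ:

1. **Pure-variable detection.** With `Mᵢ = maxⱼ |Σᵢⱼ|` and
   `Sᵢ = {j : |Σᵢⱼ| ≥ Mᵢ − 2δ}`, gene *i* is pure iff every `j ∈ Sᵢ` has
   `|Mⱼ − |Σᵢⱼ|| ≤ 2δ`; grouping the pure genes fixes the factor count K.
2. **Latent covariance** Ĉ from sign-corrected averages over pure blocks.
3. **Mixed-row allocation** by `min ‖a‖₁ s.t. ‖Ĉa − hⱼ‖∞ ≤ λ` (a linear
   program), giving the genes × factors allocation matrix Â.

The supervised stage scores cells on the factors
(`Ẑ = X_c Â (ÂᵀÂ)⁻¹`), builds second-order Gaussian knockoffs Z̃ of the
scores, computes `Wⱼ = |β̂ⱼ| − |β̂ⱼ₊K|` from an ℓ₁-regularized fit of the
condition on `[Ẑ, Z̃]`, applies the knockoff threshold at FDR 0.1, and
repeats 300 times: factors selected in ≥ 20% of iterations ("spec") are
significant. Interactions are searched among score products anchored on the
selected marginals after residualization; model significance comes from
replicated stratified 10-fold CV with permutation testing. Selected factor
gene sets transfer to other cell types/datasets as weighted sums of z-scored
expression, scored by rank AUC and Mann–Whitney p.

A synthetic single-cell generator with known ground truth (Poisson-log-normal
counts, ~90% zeros, two exposure groups, mice, cell types, a batch-shifted
second dataset, and a planted module interactome) makes every stage testable
without any download.

## Worked example

```r
library(rewirekit)

# plant a ground-truth model and simulate two batch-shifted count datasets
truth <- make_truth(seed = 5)                      # p=300 genes, K=6 factors
simA  <- simulate_cells(truth, n_cells = 2000, dataset_tag = "A", seed = 51)
simB  <- simulate_cells(truth, n_cells = 2000, dataset_tag = "B",
                        batch = TRUE, seed = 52)
simA$X
#> ExpressionMatrix: 2000 cells x 300 genes [A, raw counts]
#>   condition: 1000 control / 1000 exposed; cell types: AT2, AT1, ciliated

# preprocess and fit the factor model on dataset A
XA <- sparsity_filter(normalize_log(simA$X))
XB <- sparsity_filter(normalize_log(simB$X))
model <- fit_love(XA, seed = 5)
model
#> LoveModel: K = 6 factors over 300 genes (delta = 0.08, lambda = 0.05)
#>   pure set sizes: 4, 5, 3, 5, 5, 4

# transfer the factor tracking planted signal factor 1 to dataset B
gs    <- factor_gene_set(model, 1, "A", "all")     # 49 genes with weights
score <- project_score(gs, XB)
predict_group(score, XB$condition)
#> $auc            [1] 0.928
#> $mann_whitney_p [1] 2.53e-111
```

The fitted model recovers the planted factor structure (each pure set is a
subset of one planted factor), and the transferred gene-set score separates
exposed from control cells in the independent batch-shifted dataset with
AUC 0.93; under permuted labels the same score gives AUC ≈ 0.51 — chance, as
it should.

The supervised stage on the same data (`multistage_select()`,
`interaction_search()`, `cv_significance()`) selects the two planted signal
factors and their interaction; `run_unsupervised()` / `run_supervised()`
chain the full per-condition network path and the per-cell-type selection +
cross-prediction grid, with a seed-complete run manifest. A command-line
front end over these functions ships in `inst/scripts/rewirekit.R`
(subcommands `simulate`, `qc`, `love`, `networks`, `slide`, `crosspred`,
`run`).

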