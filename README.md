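# omicsgraphnet

Graph-convolutional classification of multi-omics cancer cohorts, with
two-stage biomarker ranking and a cross-validated baseline comparison
harness.

## What it does, and for whom

Bulk tumor profiling studies routinely produce paired gene-expression
and DNA-methylation matrices for the same patients, plus targeted
DNA-sequencing variant calls. omicsgraphnet is for computational
biologists who want to (a) classify cancer vs non-cancer samples by
*integrating* those omics blocks rather than concatenating them, and
(b) extract a ranked, compact biomarker panel from the trained model.

Each omics block `X ∈ ℝ^{n×p}` (samples × features) induces a
sample-similarity graph: `A_ij = sim(x_i, x_j)` (cosine), zeroed below
a threshold τ and on the diagonal, then symmetrically normalized as

    Â = D̃^{-1/2} (A + I) D̃^{-1/2},   D̃_ii = Σ_j (A + I)_ij .

A per-omics graph convolutional network stacks layers
`H^(d+1) = σ(Â H^(d) W^(d))` (LeakyReLU slope 0.25, hidden width 400)
followed by fully connected layers (→200→2). The per-omics score rows
are fused by a terminal affine head; summed cross-entropy losses
`L = Σ_l α_l L_GCN_l + λ L_F` are minimized full-batch with Adam in a
pretrain-then-fine-tune schedule. Variant calls drive a rule-based
therapy annotation that is attached to predictions but never enters
training.

Biomarker selection is two-stage: Welch's t-test with strict
`p < 0.05` and `|log2FC| > 0.5` (expression) or mean beta-value
difference `> 0.2` (methylation), then feature-ablation influence
ranking by `ΔF1 = F1_with − F1_without` on the validation partition.
Evaluation reports sensitivity, specificity, accuracy, precision,
AUC-ROC, macro F1 and weighted F1, and `compare_models()` benchmarks
the GCN against CNN, logistic-regression and naive-Bayes baselines on
identical cross-validation folds.

A synthetic-cohort generator with known ground truth
(`generate_cohort()`) makes the whole pipeline testable without any
data downloads. See `vignettes/multiomics-gcn-methods.Rmd` for the
full model description and design rationale.

## Worked example

```r
library(omicsgraphnet)

# a synthetic cohort: 150 cancer + 150 control samples,
# 200 expression + 300 methylation features, 20 + 30 informative
co     <- generate_cohort(synthetic_spec(seed = 7))
cohort <- align_cohort(list(co$expression, co$methylation),
                       co$labels, co$variants)
sp     <- split_dataset(cohort$labels, seed = 7)   # 55/15/30 stratified

cfg <- train_config(pretrain_epochs = 500, finetune_epochs = 500,
                    seed = 7)
fit  <- gcn_fit(cohort, train_ids = sp$train, config = cfg)
pred <- predict(fit, ids = sp$test, rules = default_therapy_rules())

evaluate_predictions(cohort$labels[sp$test], pred$fused$class,
                     pred$fused$prob[, 2])
#> <metrics_report>
#>   sensitivity  1.0000
#>   specificity  0.9778
#>   accuracy     0.9889
#>   precision    0.9783
#>   auc_roc      1.0000
#>   macro_f1     0.9889
#>   weighted_f1  0.9889
#>   confusion    tp=45 fp=1 tn=44 fn=0
```

The model classifies the 90 held-out samples with one false positive;
`pred$therapy` lists candidate targeted agents for each test sample
whose variants match the rule table. Feature ranking on the same fit:

```r
inf  <- influence_scores(fit, eval_ids = sp$validation)
st   <- feature_stats(cohort$matrices[[1]], cohort$labels)
kept <- primary_filter(st)                       # p < 0.05, |log2FC| > 0.5
top  <- select_top_features(add_influence(st[st$feature_id %in% kept, ],
                                          inf), 20)
mean(top$feature_id %in% co$manifest$informative_expression)
#> [1] 1
```

All 20 top-ranked expression features are truly informative ones
planted by the generator.

A command-line front end for shell pipelines is installed at
`system.file("cli", "omicsgraphnet", package = "omicsgraphnet")` with
subcommands `simulate`, `train`, `select-features`, `evaluate` and
`compare`, each taking `--config <yaml> --seed <int> --out <dir>`.

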