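# icbpairs

Predicting response to immune checkpoint blockade (ICB) therapy from
bulk RNA-seq is hampered by tiny clinical cohorts: published melanoma
ICB studies with expression data each have fewer than 60 patients, and
only ~1/3 of patients respond. `icbpairs` implements, as a tested and
reusable R pipeline, two strategies for that regime:

* **merge cohorts** over their common genes to raise the sample size,
  and
* **encode each sample with rank-based pair features over immune
  checkpoint genes**,

$$f_{x,y}(i) = \mathbf{1}\{\exp_x(i) > \exp_y(i)\},$$

a binary indicator of whether checkpoint gene *x* is expressed above
checkpoint gene *y* within sample *i*. Candidate pairs must contain at
least one of six anchor genes (PD-1, PDL-1, CTLA4, CD28, CD80, CD86) —
the checkpoints directly engaged by anti-PD-1/anti-CTLA-4 therapy — and
a 26-gene panel with 6 anchors gives C(6,2) + 6·20 = **135 pairs**.
Because the encoding depends only on within-sample orderings it is
invariant to per-sample monotone distortions, which makes it markedly
more robust to cross-study batch effects than raw expression.

The package covers the full workflow:

| step | functions |
|---|---|
| I/O + unit harmonization (counts/FPKM → TPM) | `read_expression()`, `fpkm_to_tpm()`, `counts_to_tpm()`, `to_tpm()` |
| response standardization (CR/PR vs PD/SD/…) | `standardize_response()`, `default_response_mapping()` |
| panel + pair encoding | `checkpoint_panel()`, `enumerate_pairs()`, `encode_pair_features()` |
| multi-study merging + batch QC | `merge_studies()`, `cluster_samples()`, `batch_purity()`, `batch_mixing_score()`, `batch_standardize()`, `assess_batch()` |
| models + evaluation | `fit_and_select()`, `cross_validate()`, `roc_points()`, `auc()`, `selection_profile()`, `selection_consistency()` |
| synthetic multi-cohort data | `simulation_config()`, `simulate_studies()`, `null_permutation()` |
| experiment orchestration | `experiment_config()`, `run_experiment()`, `compare_runs()` |

Results are tibbles throughout; fitted cross-validation objects support
`tidy()`, `glance()` and `autoplot()` (mean ROC curve), and selection
profiles plot with `plot_selection_profile()`.

## Worked example

Simulate three cohorts (42/27/56 patients, ~1/3 responders, per-study
batch distortions, a planted class signal on 10 checkpoint pairs), merge
them, encode pair features and evaluate a lasso classifier under 10×10
stratified cross-validation:

```r
library(icbpairs)

sim    <- simulate_studies(simulation_config(effect_delta = 2, seed = 1))
merged <- merge_studies(sim$studies)
merged
#> <merged_dataset: 2026 common genes x 125 samples from 3 studies>

pairs    <- enumerate_pairs(checkpoint_panel())   # 135 pairs
features <- encode_pair_features(merged$expression, pairs)

cv <- cross_validate(features, merged$metadata$label,
                     method = "lasso_logistic", folds = 10,
                     replicates = 10, seed = 1)
glance(cv)
#> # A tibble: 1 × 6
#>   method         mean_auc  sd_auc folds replicates n_samples
#>   <chr>             <dbl>   <dbl> <dbl>      <dbl>     <int>
#> 1 lasso_logistic    0.985 0.00525    10         10       125
```

The mean AUC of 0.985 is the average over 10 cross-validation
replicates of the pooled out-of-fold AUC, and its small spread (0.005)
reflects the stability that merging buys. Features selected most often
across the 100 fold-level fits are the planted ones:

```r
prof <- selection_profile(cv)
head(dplyr::arrange(filter_selection(prof), dplyr::desc(probability)), 5)
#> # A tibble: 5 × 3
#>   method         feature       probability
#>   <chr>          <chr>               <dbl>
#> 1 lasso_logistic CD28>CD40L           1
#> 2 lasso_logistic CD28>CD200           1
#> 3 lasso_logistic CD28>ICOS            1
#> 4 lasso_logistic CD28>CD200R1         0.99
#> 5 lasso_logistic CD28>TNFRSF14        0.98
```

(`CD28>CD40L` reads "CD28 expressed above CD40L"; in this simulation the
planted pairs share the anchor hub CD28, and a selection probability of
1 means every fold fit kept the feature.) Batch robustness in one line —
raw expression separates the three studies completely, pair features mix
them substantially better:

```r
raw <- log2(t(expr_values(merged$expression)) + 1)
rownames(raw) <- merged$metadata$sample_id
batch_mixing_score(raw,      merged$metadata$study_id)  # 0     (separated)
batch_mixing_score(features, merged$metadata$study_id)  # 0.256 (mixed-er)
```

`run_experiment()` wires these stages into a configured, seeded run that
writes a result bundle (metrics JSON, ROC/selection/consistency TSVs and
a manifest) from on-disk TSV inputs, and `compare_runs()` lays several
bundles out as a merged-vs-single × features × method grid.

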