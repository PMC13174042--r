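# gestureEF

Links what a surgeon *does* during the nerve-sparing step of
robot-assisted radical prostatectomy to whether the patient recovers
erectile function (EF) one year later. The unit of analysis is the
**contextualized gesture** (CG): a discrete surgical gesture (peel/push,
cold cut, spread, retraction, ...) annotated with its anatomic location
(lateral fascia, prostatic pedicle, ...) and functional purpose (release
of the neurovascular bundle, ...). A case is an ordered sequence of
hundreds of CGs plus clinical covariates; the outcome is binary intact EF,
defined from the SHIM questionnaire as total ≥ 17 or question-2 ≥ 4.

The package implements the complete analysis for audiences in surgical
data science and clinical sequence modelling:

* **Data model and I/O** — vocabularies with reserved PAD/CLS ids,
  validated case records, canonical CSV/JSON annotation files
  (`read_annotations()`, `write_annotations()`).
* **Synthetic cohorts with known ground truth** — class-conditional Markov
  chains over the joint CG vocabulary with *planted* discriminative
  bigrams and outcome-shifted clinical covariates (`sim_config()`,
  `generate_cohort()`), calibrated to the published cohort facts
  (~147 cases, ~35% EF-intact, median 446 gestures per case, a sequential
  CG pair ~4.3× more frequent in recovery cases). The motivating clinical
  dataset is confidential, so this module makes every stage testable.
* **The predictive model** — a transformer encoder over the CG sequence
  with a learnable CLS token: per-channel embeddings are summed, scaled
  dot-product attention (softmax(QKᵀ/√d_k)V) captures long-range
  dependencies, and the CLS representation — optionally concatenated with
  a fully connected network over six clinical features — feeds a binary
  classifier head. Trained end-to-end with AdamW until convergence.
  Implemented in RcppArmadillo with analytic backpropagation (verified by
  finite differences); no deep-learning framework required.
* **Evaluation** — Monte-Carlo cross-validation in the published design:
  147 cases → 118 train+validation / 29 test, then repeated 94/24 inner
  splits; the per-iteration hold-out AUC distribution gives the mean and
  percentile 95% CI (`monte_carlo_cv()`). A four-row input ablation
  (gesture; +anatomy; +anatomy+function; +clinical) under paired splits
  (`ablation_table()`), and descriptive cohort tables including the
  Sankey-ready (gesture, function, anatomy) triple counts
  (`cohort_summary()`).
* **Explainability** — per-case token attention (final-layer CLS row,
  head-averaged) weights a bag-of-words over CG unigrams and consecutive
  ordered CG pairs; class-conditional weighted frequencies, enrichment
  ratios and label-permutation p-values rank features by outcome
  direction (`weighted_frequencies()`, `permutation_pvalues()`,
  `rank_features()`).
* **Pipeline** — `run_pipeline()` chains simulate → evaluate → explain,
  writing CSV/Markdown reports and a reproducibility manifest; a thin CLI
  wrapper lives at `inst/cli/gestureEF.R`.

## Worked example

Generate a small synthetic cohort (the default planted signal is the pair
*cold cut → spread at the lateral fascia during neurovascular-bundle
release*, enriched in the EF-intact class), cross-validate the full-input
model, and rank sequential CG pairs:

```r
library(gestureEF)

sim <- generate_cohort(sim_config(n_cases = 60, seed = 42))
ds <- sim$dataset
ds
#> <cohort_dataset: 60 cases (27 EF-intact), vocab 8/4/4>
cohort_summary(ds)
#> <cohort_summary: 60 cases, 30786 gestures; length median 508 (IQR 310-650)>
realized_enrichment(ds, 2L, 3L, default_cg_states())
#> [1] 3.03

cfg <- model_config(embed_dim = 16, n_layers = 2, n_heads = 2,
                    ffn_dim = 32, dropout = 0, max_len = 192,
                    learning_rate = 3e-3, batch_size = 32,
                    max_epochs = 25, early_stop_patience = 25,
                    val_fraction = 0, swa = TRUE, embed_init_sd = 1)
rep <- monte_carlo_cv(ds, cfg,
                      cv_plan(n_iterations = 5, master_seed = 7,
                              stratify = TRUE),
                      collect_attention = TRUE)
rep
#> <auc_report gesture+anatomy+function: AUC 0.560 [95% CI 0.412, 0.672] over 5 iterations>

fs <- permutation_pvalues(
  weighted_frequencies(ds, aggregate_attention(rep)),
  n_perm = 499, seed = 7)
rank_features(fs, top_k = 3, min_cases = 5, type = "pair")
#> Top features enriched in EF recovery:
#>   cold cut|lateral fascia|release neurovascular bundle ->
#>     spread|lateral fascia|release neurovascular bundle
#>     weighted_freq_pos 0.0204, weighted_freq_neg 0.0060,
#>     ratio 3.38, p = 0.002
#>   ... (two further pairs)
```

Reading the numbers: the realized per-case frequency ratio of the planted
pair is 3.03 (the configured 4.3× transition boost is diluted by row
renormalization and the stationary shift — see the methods vignette); the
explainability stage ranks exactly that pair first among
recovery-enriched sequential features with permutation p = 0.002. The
cross-validated AUC on a 60-case cohort is modest (0.56) — hold-out AUC at
this sample size is noisy, and discrimination rises with cohort size and
iteration count; the vignette discusses the model's information ceiling
on single-motif synthetic cohorts.

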