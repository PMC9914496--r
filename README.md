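# tcrhla

Peptide-agnostic prediction of T cell receptor (TCR) binding to Class I
HLA alleles, from repertoire data.

Every peripheral T cell passed thymic selection on some HLA allele of its
host, so TCR repertoires carry a statistical imprint of host HLA type:
the germline-encoded CDR1/CDR2 loops (fixed by the Vβ gene) contact the
MHC α-helices, and part of CDR3 touches the MHC directly. `tcrhla` turns
that imprint into predictive models for immunoinformaticians working with
curated TCR–HLA pair tables (McPAS/VDJdb-style) or bulk repertoire
sequencing with donor HLA typing:

* **V-gene naive Bayes** (`nb_fit`) — scores a pair by the posterior
  `P(h | v) = P(h) P(v | h) / P(v)` estimated from positive pairs; with no
  smoothing this equals `count(h, v) / count(v)` exactly. A clustered
  log-posterior matrix (`nb_log_matrix`) exposes the association
  structure.
* **Neural binding predictor** (`binding_fit`) — a CDR3 autoencoder
  embedding plus learned 50-dim V/J gene embeddings (E_t), a character-CNN
  allele encoder producing a 100-dim E_h, and an MLP head
  (hidden = half of |E_th|, Leaky ReLU, sigmoid), trained with Adam
  (lr 0.007, weight decay 0.001), distribution-matched negative sampling,
  donor-aware 80/20 splits and early stopping on validation AUC.
* **Two-stage training for ambiguous labels** (`two_stage_fit`) — for
  bulk repertoires where each TCR k carries a candidate set H_k (its
  donor's typing): round 1 treats every candidate pair as positive; round
  2 keeps only each TCR's top-scoring candidate as positive, demotes the
  rest to negatives, and retrains.
* **CD4/CD8 classifier** (`cd4cd8_fit`, `filter_top_cd8`) — filters
  unsorted repertoires to confident CD8 calls before Class I prediction.
* **Evaluation under ambiguity** (`group_accuracy`, `ga_null_curve`,
  `max_auc_bound`, `shared_tcr_associations`, `association_recall_test`)
  — including the analytic ceiling on ROC AUC when only 1 of m labelled
  positives is truly positive: `AUC_max = (m + 1) / (2m)`, i.e. 0.625 for
  the typical 2 A + 2 B candidate sets.
* **Synthetic repertoire generators** (`simulate_pth`, `simulate_bse`,
  `simulate_cd4cd8`, `make_noisy_pth`) — planted V–HLA associations,
  CDR3 motifs and hidden per-donor truth, so every estimator is testable
  without external downloads.

All neural components are implemented natively in base R matrix code; the
package has no compiled code and no hard dependencies beyond base R.

## Worked example

Simulate a paired table with a planted association (16 alleles, 12 V
genes, preferred-gene probability 0.9, per-allele frequencies Zipf-like),
fit both models, then rebuild the ambiguous regime and score it:

```r
library(tcrhla)

hla <- default_hla_pool(8, 8); v <- default_v_pool(12)
spec <- generator_spec(n_tcrs = 2000, hla_pool = hla, v_pool = v,
                       association = planted_association(names(hla), names(v), 0.9),
                       seed = 42)
pairs <- simulate_pth(spec)

nb <- nb_fit(pairs)
nb
#> V-gene naive Bayes binding model
#>   alleles: 16  V genes: 12  training pairs: 2000
round(predict(nb, "V01-01")[1, 1:4], 3)
#> A*01:01 A*02:01 A*03:01 A*04:01
#>   0.902   0.003   0.002   0.002

cfg <- binding_config(ae_epochs = 20, max_epochs = 20, patience = 5, seed = 1)
fit <- binding_fit(pairs, cfg)
fit
#> TCR-HLA binding model
#>   pairs: 4000  alleles: 16  V genes: 12
#>   input dim: 230  hidden: 115
#>   best epoch 12 (validation AUC 0.920), test AUC 0.913

noisy <- make_noisy_pth(pairs, k_extra = 3, seed = 7)   # 4 candidates per TCR
group_accuracy(model_scorer(fit), noisy)
#> Group accuracy: 0.6780 over 2000 TCRs
max_auc_bound(4)
#> [1] 0.625
```

The naive Bayes posterior concentrates on the planted preferred allele of
`V01-01` (0.902 ≈ the planted strength 0.9). The neural model reaches a
held-out AUC of 0.91 on the clean pairs; on the ambiguous version the
right quantity is group accuracy — here 0.68 of TCRs have their top-ranked
allele (out of all 16) inside their 4-allele candidate set, against a
4/16 = 0.25 chance rate — while any AUC computed against the ambiguous
labels is capped at 0.625 no matter how good the model is.

For bulk repertoires, `as_bse_examples()` converts donor repertoires read
by `read_repertoire()` (AIRR-style TSVs plus a typing table) into
ambiguous examples for `two_stage_fit()`, and
`shared_tcr_associations()` / `association_recall_test()` provide the
donor co-occurrence cross-check with chi-squared reporting.

## Vignette

`vignettes/tcr-hla-binding.Rmd` documents the models, their assumptions,
every tunable that matters, the synthetic-data design, numerical choices
and known limitations.
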