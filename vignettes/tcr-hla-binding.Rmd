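---
title: "Peptide-agnostic TCR–HLA binding prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-agnostic TCR–HLA binding prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

T cells recognise peptides presented on MHC molecules (HLA in humans)
through their T cell receptor. While the hypervariable CDR3 loop of the
TCR β chain dominates peptide specificity, the germline-encoded CDR1 and
CDR2 loops — fully determined by the Vβ gene — contact the MHC α-helices,
and part of CDR3 touches the MHC directly. Because every peripheral T cell
passed thymic selection on *some* host HLA allele, repertoires carry a
statistical imprint of the host's HLA type. `tcrhla` models that imprint
to predict, for a TCR β chain (CDR3 amino-acid sequence plus V/J gene
labels) and a Class I HLA allele (loci A and B), whether the two are
associated — ignoring the peptide entirely.

Two data regimes are supported:

* **Paired tables (PTH)** — curated (TCR, HLA) pairs where the restricting
  allele of each TCR is known. These train ordinary supervised models.
* **Bulk repertoires (BSE)** — per-donor TCR lists with the donor's HLA
  typing (typically 2 A + 2 B alleles) but *no* per-TCR label. Each TCR is
  assumed selected on one, unknown, allele of its donor: a
  multiple-instance (ambiguous-label) problem.

## Canonical representations and preprocessing

All models consume one canonical record format: `cdr3b` (uppercase
20-letter amino-acid string), `v_gene` (`"V05-01"`, two two-digit fields),
`j_gene` (`"J02"`, one-field family) and `hla` (`"A*02:01"`, locus and two
two-digit fields). `filter_pth()` applies the standard cleaning rules for
curated pair tables — non-human rows, missing or multiple HLA annotations,
and missing CDR3 sequences are dropped and tallied by reason, so the audit
log always conserves the input row count. Incomplete designations
(`"A*02"`, `"A2"`, `"V05"`) are completed to the most frequent full label
of their group via a `frequency_catalog()`; by default the catalog is
estimated from the table being cleaned, since no single reference
population is canonical. Allele suffixes are stripped (`V01-02:01` →
`V01-02`) and the first option of slash-separated lists is kept
(`V13-01/3/4` → `V13-01`). Normalization is idempotent, and duplicate
(TCR, HLA) pairs after normalization are collapsed with a logged count —
the conservative choice, since curated tables often list the same pair
from several studies. C-locus alleles in donor typings are discarded (with
a count): too few records exist to model locus C, and predictions for it
would be wrong by construction.

## The V-gene naive Bayes model

Since CDR1/CDR2 are determined by the Vβ gene, a first model drops the
CDR3 entirely and scores a pair by the posterior

$$P(h_i \mid v_j) = \frac{P(h_i)\, P(v_j \mid h_i)}{P(v_j)},$$

with all three factors estimated as empirical frequencies over positive
training pairs (`nb_fit()`). Unsmoothed, the posterior collapses to
`count(h, v) / count(v)` exactly — the package tests assert this identity
at machine precision. An optional Laplace pseudo-count `smoothing_alpha`
(default 0, plain frequencies) keeps scores finite for (h, v) cells unseen
in training, which otherwise break cross-dataset transfer; a *wholly*
unseen V gene carries no information and receives the prior $P(h)$.
`nb_log_matrix()` exposes the association structure as
$\log(P(h_i \mid v_j) + \epsilon)$ with $\epsilon = 10^{-5}$, with row and
column leaf orders from single-link hierarchical clustering; the distance
is Euclidean on the log-matrix rows/columns, a choice the package makes
explicit because only the linkage is standard for this display.

## The neural binding model

`binding_fit()` trains a binary predictor on positive pairs plus sampled
negatives.

**TCR encoding `E_t`.** CDR3 sequences are one-hot encoded over 21
channels (20 amino acids + a stop symbol placed immediately after the last
residue, zero padding beyond it) and compressed by a dense autoencoder
(`cdr3_autoencoder()`) pretrained on the sequences alone for a configurable
number of epochs (default 300) — no allele information ever reaches the
pretraining. The encoder half initializes the CDR3 branch of the
supervised model and is fine-tuned with it by default
(`freeze_cdr3_encoder = FALSE`); freezing is available and faster, but the
fine-tuned encoder is the default because sequence-level signal (e.g.
motifs) is only linearly exposed to the classifier after supervised
reshaping. The latent dimension defaults to 30 (configurable): small
enough to regularise, large enough that reconstruction accuracy on typical
CDR3 corpora is high. V and J genes are categorical features with learned
50-dimensional embedding tables (one table per feature; α-chain fields get
their own tables when `use_alpha = TRUE`), plus one reserved unknown-token
row so cross-dataset gene labels never crash encoding.

**HLA encoding `E_h`.** The canonical allele *string* (`"A*02:01"`) is
treated as a character sequence: each character gets a 14-dimensional
learned embedding, followed by two convolution blocks (kernel sizes 3 and
2, ReLU, pairwise max-pooling) and two dense layers with dropout 0.1,
producing a 100-dimensional vector. Encoding the allele name rather than
an HLA protein sequence is an interpretive choice: the allele is a
categorical label whose string structure (locus, group, protein) lets the
encoder share statistical strength across related alleles; the encoder is
a self-contained module, so a protein-sequence encoder could be swapped in
behind the same interface.

**Head and training.** `E_t` and `E_h` are concatenated into `E_th` and
passed through one hidden linear layer of half the input dimension (Leaky
ReLU, dropout 0.1) and a sigmoid output. The loss is binary cross-entropy
— the natural likelihood for a 0/1 target — optimised by Adam with
learning rate 0.007 and weight decay 0.001 (the binding model's standard
operating point; the CD4/CD8 classifier uses 0.0005/0.0005 and plain
ReLU). Negatives are (TCR, HLA) combinations absent from the positive set,
built by reusing the TCR multiset as-is and drawing alleles from the
positives' empirical allele distribution with rejection of existing pairs
— so both marginals match the positives and a model that ignores one side
of the pair cannot beat AUC 0.5. Data are split 80/20 into a training and
a test side, with 10% of the training side carved out as internal
validation; when donor labels exist all splits are donor-aware (no donor
on two sides). Training stops when validation AUC has not improved for
`patience` epochs (default 20) and the best-epoch weights are restored.
The embedding tables are drawn from a standard normal — the usual
embedding initialisation; substantially smaller scales starve the
allele branch of gradient and the pair interaction is then not learned.

All neural components are implemented natively in base R matrix code
(`R/nn.R`): dense layers, embedding tables, 1-d convolutions with
max-pooling, inverted dropout and Adam, with hand-derived backward passes
verified against numerical differentiation during development. Training
is deterministic given the configuration seed.

## Ambiguous labels and the two-stage scheme

For bulk repertoires each TCR `t_k` carries a candidate set `H_k` (its
donor's typing). `two_stage_fit()` implements hard-relabel training:

1. **Stage 1** — every (t_k, h), h ∈ H_k is a positive; negatives pair
   t_k with non-candidate alleles under the same marginal-matching rule.
2. **Stage 2** — the trained model scores each TCR's candidates; the
   single top-scoring candidate becomes the TCR's positive and all other
   candidates become negatives, and the model is retrained. Ties are
   broken towards the lexicographically first allele and counted.

Further rounds iterate step 2. The default is two rounds; retraining
warm-starts from the previous round's weights (configurable off) — the
relabelled data differ only in labels, so discarding the learned encoders
each round would waste most of the signal. Stage-2 negatives are topped up
with non-candidate draws only where a TCR has fewer losing candidates than
the configured negative ratio, keeping class balance comparable across
stages. Held-out donors are evaluated after every round with group
accuracy and AUC; evaluation always uses the *original* candidate sets,
never the relabelled ones — the donor typing is the only ground truth
available. With singleton candidate sets the whole scheme reduces exactly
to ordinary supervised training (a property the test suite asserts by
comparing training histories).

## Evaluation under ambiguity

**The AUC ceiling.** With positives defined as candidate pairs (m per
TCR, exactly one truly associated) and negatives as non-candidate pairs,
even a perfect scorer is capped: a random labelled positive is the true
pair with probability 1/m (and outranks every negative), otherwise one of
the m − 1 decoys, whose scores are exchangeable with the negatives'. Hence

$$\mathrm{AUC}_{\max} = \frac{1}{m} + \frac{m-1}{2m} = \frac{m+1}{2m},$$

0.625 at m = 4 (`max_auc_bound()`). Because the closed form is a
large-universe idealisation, `oracle_ambiguity_auc()` validates it by
direct Monte-Carlo simulation with a perfect oracle on a finite universe;
the two agree within sampling noise, and the acceptance suite anchors on
the m = 4 value.

**Group accuracy (GA).** The fraction of TCRs whose top-ranked allele
over the *whole* universe lies in their candidate set
(`group_accuracy()`). The universe is all alleles observed in the dataset;
argmax ties break to the lexicographically first allele. GA is compared
with a scrambled-label null (`ga_null_curve()`): candidate sets are
permuted across TCRs (preserving set sizes) at a grid of sample-size
fractions, with means and standard errors over R = 10 realizations. The
per-fraction standard errors shrink with sample size, which is what makes
GA a usable effect-size scale for real repertoires.

**Donor co-occurrence cross-validation.** An orthogonal, model-free
check (`shared_tcr_associations()`): a TCR carried by at least `T1` donors
is scored per allele by the fraction of its carrier donors typed with that
allele, normalised by the allele's population frequency, and the ratio
vector renormalised to sum 1; the TCR is called associated with its top
allele when that entry exceeds `r1`. Typical operating points are
(T1 = 15, r1 = 0.5) for large cohorts and (T1 = 5, r1 = 0.25) for small
ones. `association_recall_test()` then asks how often the model ranks the
called allele first, against the 1/|universe| random expectation, with a
continuity-corrected 1-df chi-squared test per allele and significance
stars at 0.05/0.01/0.001. The population frequency defaults to the
empirical allele frequency over the input donors when no external table is
given.

## The CD4/CD8 classifier

Class I binding applies to CD8 cells, so unsorted repertoires are first
passed through `cd4cd8_fit()`: the TCR encoding `E_t`, one hidden layer of
half the input width (ReLU, dropout 0.1), sigmoid output (1 = CD8).
`filter_top_cd8()` keeps the `ceiling(top_fraction * n)` most confident
CD8 calls with a stable, input-order tie-break. The selection fraction has
**no default**: reported operating points for this step differ by orders
of magnitude (a top-5% cut versus far stricter ones), so the caller must
choose one explicitly; both styles are only a parameter away.

## Synthetic data: what it emulates and what it does not

The generators (`generator_spec()`, `simulate_pth()`, `simulate_bse()`,
`simulate_cd4cd8()`, `make_noisy_pth()`) provide a fully controlled test
surface with known planted structure:

* allele and V-gene pools with Zipf-like (1/rank) population frequencies —
  the qualitative shape of real HLA and V-gene usage (a few common labels,
  a long tail); 64 alleles (32 A + 32 B) and 30 V genes by default;
* a planted conditional `A[h, v] = P(v | h)` (`planted_association()`,
  preferred-gene probability 0.9 by default) carrying the CDR1/CDR2-level
  signal;
* CDR3 sequences drawn i.i.d.-uniform over the 20 amino acids with lengths
  from a bell-shaped distribution over 8–18 residues peaked near 13
  (configurable), into which per-allele k-mer motifs — or a CD8-specific
  motif — are written at a random position with probability
  `motif_strength` (default 0.8);
* donors drawing 2 A + 2 B alleles with replacement (homozygotes possible;
  candidate sets keep unique alleles), each TCR's true allele uniform
  within the donor's set and returned in a separate truth map used only by
  recovery tests;
* `make_noisy_pth()` rebuilds the ambiguous regime from a labelled table by
  adding `k_extra = 3` decoy alleles per TCR, drawn without replacement
  from the table's empirical allele distribution excluding the truth — so
  candidate sets have exactly 4 distinct alleles and always contain the
  truth.

The generators deliberately do **not** model VDJ recombination, thymic
selection biology, clone-size distributions, or realistic joint
CDR3/V-gene statistics. Passing tests on planted data therefore
demonstrates that the estimators recover the structure they target under
controlled conditions — not that real repertoires carry signal of that
strength. Two distributional subtleties are worth knowing: with a heavily
skewed allele pool, (a) excluding the true allele when sampling decoys and
(b) rejecting existing pairs when sampling negatives both perturb the
respective allele marginals by a few percent; the package's
distribution-matching property tests use evenly weighted pools so these
small, well-understood biases do not mask genuine defects.

On the CD8 motif strength: a motif present in a fraction `s` of CD8
sequences and absent from CD4 caps the achievable CD4/CD8 AUC at
`s + (1 - s)/2` — motif-free CD8 sequences are exchangeable with CD4 ones.
At `s = 0.7` that ceiling is exactly 0.85, leaving a high-recovery check
no room; the package therefore uses a single default motif strength of
0.8 everywhere (ceiling 0.9), the same value used for the per-allele PTH
motifs, and treats `s` as an explicit knob for studying the trade-off.

## Numerical choices and test scales

* CDR3 padding length defaults to the data's maximum length + 1 (at least
  12) for the autoencoder, or 25 via `binding_config()` when set
  explicitly; overlong sequences at *prediction* time are truncated, while
  at encoding time they are an error.
* Probabilities from the sigmoid are clamped to [1e-7, 1 − 1e-7] inside
  the cross-entropy; the naive Bayes log-matrix offset is 1e-5.
* All argmax-style selections (stage-2 relabeling, GA, `score_all_hla()`
  rankings, `filter_top_cd8()`) have documented deterministic tie-breaks:
  lexicographic on the allele string, or input order for row selections.
* Degenerate inputs are conditions with stable classes
  (`"empty_training"`, `"cannot_split"`, `"single_class"`,
  `"unparseable_hla"`, ...), so callers can trap them precisely.
* The test and acceptance suites run the neural trainers at reduced scale
  as the package's own choice of problem sizes: planted-signal recovery
  uses 3 000–20 000 TCRs with autoencoder pretraining of 12–30 epochs and
  supervised caps of 12–40 epochs with patience 4–6. The planted signals
  are strong enough that convergence is reached well before these caps;
  the defaults (300 / 200 / 20) remain the recommended operating point for
  real data.

## Known limitations

* The Vα-based analogue of the naive Bayes model is not implemented: in
  curated tables the α-chain subset is dominated by a single allele, which
  makes the estimate degenerate. α-chain fields participate only through
  the neural encoding (`use_alpha`).
* Only loci A and B are modelled; other loci are storable labels but no
  Class II-specific (or C-locus) logic exists.
* The character-CNN allele encoder sees allele *names*; structural
  similarity between alleles with different group digits is invisible to
  it beyond what training instils.
* Hard argmax relabeling (no EM-style soft responsibilities) is the only
  stage-2 scheme; with weak signal the relabeled positives can lock in
  early mistakes, which is why per-round held-out metrics are reported.
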