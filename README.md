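# ademiner

Sentence-level extraction of potential adverse drug event (ADE) relations
from medical case reports.

Case reports in the biomedical literature are a major, under-used source of
drug-safety signals: they describe, in free text, conditions that developed
after administration of a drug. `ademiner` implements a complete
machine-learning pipeline for turning such text into ranked
(drug, adverse event) pairs:

1. **Corpus model** — a standoff-annotation representation of case-report
   abstracts (documents → sentences → tokens and typed entity mentions with
   character offsets, plus gold drug–condition relations), with a plain
   JSON on-disk dialect and the line-oriented SRE instance format.
2. **Dictionary NER** — greedy longest-match tagging of drugs and
   conditions from DrugBank-style and MedDRA-style lexicons, filling the
   gaps left by sparse human annotation.
3. **Instance builder** — every drug–condition pair co-occurring in a
   sentence becomes a classification candidate; gold pairs are `TRUE`,
   machine-completed co-occurrences become the `FALSE` class; gold
   relations with mutually overlapping (nested) spans are dropped.
4. **Shallow linguistic kernel** — the relation similarity
   `K = K̂_FB + K̂_B + K̂_BA + K̂_LC`, a sum of normalized bag-of-n-gram
   kernels over the fore-between, between and between-after sentence
   segments plus a positional local-context token-feature kernel, together
   with an explicit feature map `φ` such that `⟨φ(x), φ(y)⟩ = K(x, y)`
   exactly.
5. **Classifier** — a linear SVM on `φ` (therefore the kernel machine),
   with deterministic training, persistence, and margin-scored prediction.
6. **Evaluation** — precision/recall/F over the `TRUE` class,
   document-level k-fold cross-validation, and learning-curve experiments.
7. **Novelty comparison** — aggregation of positive predictions into
   normalized identifier pairs and set difference against a drug-label
   side-effect reference, flagging potentially under-reported events.
8. **Synthetic corpus generator** — template-based corpora with a
   ground-truth ledger, so the whole pipeline is testable end to end
   without external data.

## Worked example

```r
library(ademiner)

# a synthetic annotated corpus of 200 case reports with a ground-truth ledger
gen <- generate_corpus(synth_config(n_docs = 200, seed = 7))
corpus_stats(gen$corpus)
#> # A tibble: 1 × 6
#>   documents drugs conditions sentences_with_candidates true_relations
#>       <int> <int>      <int>                     <int>          <int>
#> 1       200   600        640                       600            400
#> # ℹ 1 more variable: false_relations <int>

# 10-fold document-level cross-validation of the kernel SVM
cv <- cross_validate(gen$corpus, k = 10, seed = 7)
glance(cv)
#> # A tibble: 1 × 7
#>      tp    fp    fn    tn precision recall f_score
#>   <int> <int> <int> <int>     <dbl>  <dbl>   <dbl>
#> 1   400     0     0   240         1      1       1
```

The pooled confusion counts are over the `TRUE` (adverse-event) relation
class: on noise-free synthetic text whose causal trigger phrases sit in the
between-entity segment, the classifier recovers every planted relation
(F = 1.00). With 10% label noise the same experiment plateaus near F ≈ 0.93
and the fold-to-fold standard deviation shrinks roughly tenfold between
10-document and 2000-document corpora — the classic learning-curve shape.

To inspect what the model learned and to flag novel pairs:

```r
model <- train_classifier(build_dataset(gen$corpus), seed = 7)
tidy(model)          # strongest kernel features per namespace
preds <- predict(model, build_dataset(gen$corpus))
ledger <- aggregate_pairs(preds, build_dataset(gen$corpus))
sider <- load_reference(system.file("extdata",
          "synthetic_sider_reference.tsv", package = "ademiner"))
novel_pairs(ledger, sider)
```

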