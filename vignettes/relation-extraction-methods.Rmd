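---
title: "Extracting adverse drug event relations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting adverse drug event relations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ademiner)
```

## The problem

Published case reports assert, in free text, that a condition arose after
administration of a drug. A drug and a condition mentioned in the same
sentence are *not* necessarily in such a relation: the condition may be
the indication, a pre-existing comorbidity, or simply co-mentioned.
`ademiner` frames the task as binary classification of sentence-level
(drug mention, condition mention) pairs: `TRUE` if the sentence asserts a
potential adverse event relation between them, `FALSE` otherwise. The
positive class is what pharmacovigilance cares about, so every evaluation
metric in the package is computed over `TRUE` pairs.

## Corpus model and negative-pair construction

Annotated corpora in this domain are *sparsely* annotated: only entities
participating in an adverse-event relation are marked. A supervised
classifier also needs negatives. The package follows the standard recipe:

1. run dictionary NER (drug and condition lexicons) over the corpus and
   add machine mentions wherever no human annotation covers the text;
2. enumerate all drug x condition pairs per sentence, with human and
   machine mentions on equal footing;
3. label pairs present in the gold annotation `TRUE`, all others `FALSE`.

Because the machine mentions were, by construction, not part of any gold
relation, the co-occurrence pairs they create are exactly the negative
class. Candidates are keyed by character offsets, never by surface
strings: two occurrences of the same drug name are distinct mentions.

**Nested annotations.** A gold relation whose member spans overlap (the
drug name embedded inside the condition phrase, as in *acute lithium
toxicity*) has no token context between its members and cannot be
represented as an ordered pair of disjoint spans. `remove_nested()` drops
every gold relation whose drug and condition character spans intersect.
The published account of this filter gives only the containment example;
span *intersection* generalizes it, is exactly testable, and subsumes
containment. Mentions are kept — only the relation is dropped.

**Dictionary NER.** Matching is greedy, longest-first, left-to-right,
case-insensitive, and token-sequence based (a dictionary term can never
fire inside a word). Existing annotation always wins: a lexicon hit whose
token window touches any already-present mention is discarded, which also
makes `annotate_corpus()` idempotent. When drug and condition lexicons
claim the same key, the longer match wins; at equal length the drug
reading wins — an arbitrary but fixed tie-break. No stemming or fuzzy
matching is applied by default (`normalize_plural = TRUE` enables a naive
plural fold); commercial NER systems do more, and their settings are not
public, so the package keeps the matcher transparent and exact.

**Tokenization** is pluggable (any function mapping a sentence string to
a token table with lemma, POS and orthographic class); the bundled
default is deterministic, splitting alphanumeric runs and single
punctuation marks, lower-casing for lemmas and using a small
closed-class/suffix heuristic tagger. It makes no linguistic claims; it
exists so that the feature extractor has the attributes it needs and so
that results are reproducible to the byte.

## The shallow linguistic kernel

The similarity between two relation candidates is a sum of four
normalized sub-kernels,

$$K(x, y) = \hat K_{FB}(x,y) + \hat K_{B}(x,y) + \hat K_{BA}(x,y)
          + \hat K_{LC}(x,y),$$

where each $\hat K_s = K_s(x,y) / \sqrt{K_s(x,x)\,K_s(y,y)}$ (defined as
0 when either self-similarity vanishes) and $K_s$ is the dot product of
bag-of-pattern count vectors:

* **Global contexts** (`FB`, `B`, `BA`): contiguous lemma n-grams of
  length 1..`n_max` over three segments of the sentence — fore-between
  (sentence start through the second candidate entity), between (strictly
  between the entities) and between-after (first entity through sentence
  end). The candidate entities participate as single placeholder units
  `DRUG_CAND` / `COND_CAND` when `blind_entities = TRUE` (the default):
  the classifier then learns *contextual* evidence ("X induced Y")
  rather than memorizing drug names. The segment definitions deliberately
  include the blinded entities at the segment boundaries — patterns such
  as "DRUG_CAND induced" are the very signal the kernel exists for. The
  fore and after extents are the whole sentence; case-report sentences
  are short and clipping would add a parameter with no clear benefit.
* **Local contexts** (`LC`): for each candidate entity, every token at
  relative position $r \in [-w, +w]$ outside the entity's own span
  contributes one feature per attribute (surface form, lemma, POS,
  orthographic class); a neighbouring token inside *another* entity
  mention exposes its entity flag in place of the orthographic class. The
  two entities' namespaces are normalized jointly as one `LC` sub-kernel.

Defaults `n_max = 3`, `window = 2` follow the kernel family's published
origin and are exposed via `kernel_params()`. Sub-kernels are summed
unweighted; weighting schemes exist but introduce hyper-parameters the
available evidence cannot fix.

**Explicit feature map.** Because every sub-kernel is a normalized dot
product of count vectors, the map $\phi$ that concatenates each
namespace's count vector scaled by $1/\sqrt{K_s(x,x)}$ satisfies
$\langle \phi(x), \phi(y) \rangle = K(x, y)$ *exactly* in exact
arithmetic. The package trains a linear SVM on $\phi$ (sparse matrix via
`featurize()`), which is the kernel machine but scales linearly in the
number of candidates instead of quadratically. The equivalence is a
tested invariant (maximum absolute deviation below 1e-10 on random
candidate samples), not an assumption; kernel symmetry, the $0 \le K \le
4$ bound and positive semidefiniteness of random Gram matrices are tested
alongside it.

## Classifier

`train_classifier()` fits a soft-margin linear SVM (libsvm via e1071) on
the feature map with `C = 1` and no class reweighting — positive and
negative pair counts in this construction are near-balanced, and the
reference systems in this field run with default costs. Choices that
matter for reproducibility:

* instances are sorted by instance id before fitting, so training is
  invariant to dataset shuffling;
* the explicit weight vector is recovered from the support vectors and
  re-oriented so that `TRUE` scores positive (libsvm orients its decision
  function by the first label it happens to see);
* prediction uses the stored kernel parameters — a model cannot be
  applied to features extracted under different settings;
* a margin score of exactly 0 predicts `FALSE`: for a signal-detection
  tool, precision is the conservative side of a tie.

## Evaluation

Folds in `cross_validate()` partition *documents*, never candidates: all
pairs from one case report stay on one side of every split, so
near-duplicate sentences within a report cannot leak between training
and test. The headline number pools confusion counts across folds
(micro-averaging); per-fold values feed dispersion estimates. Whether the
original evaluation in this literature split by document or by instance
is usually unstated; document-level splitting is the stricter choice.
Presentation rounds to two decimals; computation never rounds.

A fold whose training side happens to be single-class (possible at very
small corpus sizes) falls back to a majority-class constant predictor
rather than aborting the whole experiment.

`learning_curve()` samples document subsets without replacement at each
ladder size, runs k-fold CV on each, and aggregates mean and SD of the
metrics across folds and repeats. With `repeats = 1` the SD reflects only
fold-to-fold variance *within* one subset; at small sizes the variance
*between* subsets dominates, so experiments that compare dispersion
across sizes should draw several subsamples per size (the acceptance
experiment uses 3 for sizes up to 200; at the full corpus size the
"subsample" is the corpus itself and one round suffices).

## The synthetic corpus generator

`generate_corpus()` produces corpora whose shape mirrors annotated
case-report corpora — short sentences, one drug and one or two condition
mentions each, sparse gold relations — with a ledger recording every
planted pair, its label, its ids and its annotation status. The ledger is
the single source of expected values for the package's tests: no test
asserts a magic number that the generator did not itself record.

Design of the defaults (all overridable in `synth_config()`):

* 2 trigger sentences and 1 distractor sentence per document, one
  drug-condition pair each; a fifth of distractors carry a second
  condition, so multi-candidate sentences and the $d \cdot c - g$
  arithmetic are exercised. A 30-drug / 40-condition vocabulary (every
  fourth condition two tokens long) keeps entity repetition realistic at
  the default corpus sizes.
* the causal signal of trigger templates lives strictly in the
  between-entity segment and within trigram reach ("induced severe",
  "developed after"), so the between sub-kernel suffices by
  construction; distractor templates co-mention without any causal
  vocabulary. This makes noise-free corpora linearly separable under the
  kernel — the point of the recovery benchmark is to verify the pipeline
  loses nothing, not to simulate linguistic difficulty.
* `label_noise` flips a planted label (a flipped trigger keeps its causal
  text but loses its gold relation, and vice versa), which is irreducible
  annotation noise of exactly the kind real corpora contain; the
  benchmark uses 0 for the recovery experiment and 0.1 for the learning
  curve.
* `unannotated_frac` removes human annotation from mentions of `FALSE`
  pairs (gold relations must reference annotated mentions), which is what
  dictionary NER is there to repair.

What the generator does **not** emulate: real lexical variety, anaphora,
coordination ("nausea, vomiting and rash"), frequency annotations like
"(3/4)", distant intra-sentence relations, or abbreviations. Passing
the synthetic benchmarks therefore demonstrates that the machinery is
correct and self-consistent — not that the published F-score transfers to
any particular real corpus, which requires the real corpus and a real NER
system.

## Numerical and engineering choices

* All character offsets are 0-based half-open against sentence text; all
  spans are validated on read, and a standoff JSON write/read/write cycle
  is byte-identical.
* Every stochastic step (generation, fold assignment, subsampling) is
  seed-scoped with `withr::with_seed`; two runs with one seed agree to
  the byte.
* Benchmark problem sizes — 200 documents (noise 0) for the recovery
  experiment, 2000 documents (noise 0.1) for the learning curve, 50
  candidates for the kernel-algebra checks, 1000 random sentences for the
  matcher oracle — were chosen so the full suite exercises every claim at
  meaningful scale while remaining comfortable on a laptop core.
* Features unseen at training time are dropped at prediction (they carry
  zero weight in a linear model, so predictions are unchanged); the
  feature vocabulary is stored in the model.

## Known limitations

* The dictionary matcher is exact after case folding; morphological or
  fuzzy matching beyond the optional plural fold is out of scope.
* Relations never cross sentence boundaries.
* The bundled annotator's POS tags are heuristic; for real corpora a
  proper tagger should be plugged in via the `annotator` argument.
* No probability calibration: scores are SVM margins, ordered but not
  probabilistic.
* The novelty comparison is a set difference in identifier space with a
  support threshold; it deliberately implements no disproportionality
  statistics.
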