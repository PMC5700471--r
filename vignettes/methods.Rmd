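---
title: "Methods: phenotype concept recognition with a CRF and validation rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype concept recognition with a CRF and validation rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorec)
```

## Overview

`phenorec` recognizes Human Phenotype Ontology (HPO) term mentions in
abstracts. The pipeline has two stages with deliberately opposite biases:
a statistical sequence labeler whose feature set pushes recall, and a
dictionary-plus-rules validation stage that first *adds* further
candidates (recall again) and then *removes* implausible ones
(precision). This document records the model, the parameters that matter,
the numerical and design choices made where the design was genuinely
open, and what the synthetic test world does and does not establish.

## Corpus and offset conventions

Gold corpora are directories of single-line abstracts plus annotation
files, one record per line:

```
[27::42] HP_0000110 | renal dysplasia
```

Offsets are **0-based, half-open, counted in Unicode characters**. The
convention is forced by arithmetic: 42 − 27 = 15 = `nchar("renal
dysplasia")`; byte offsets would break on any non-ASCII abstract. Both
the ASCII pipe and the Unicode divider `∣` are accepted on input; the
writer always emits `|`. Accessions are canonicalized to `HP_` + 7
digits. When an annotation's span disagrees with the document text the
reader keeps the file's offsets (offsets are the evaluation key) and
records the conflict in a validation report; a strict mode fails instead.

## Preprocessing

The downstream rules depend only on *tag classes* — noun, adjective,
preposition, determiner, coordination — so preprocessing is defined as a
contract (Penn Treebank tags, lower-case lemmas, offsets that always
slice back to the token) with a pluggable backend. The bundled default
is:

* a rule sentence splitter (sentence punctuation followed by whitespace
  and an upper-case letter or digit, guarded by an abbreviation list and
  a decimal-number check);
* a regex tokenizer that keeps hyphenated words as single tokens
  (phenotype vocabulary is hyphen-rich);
* a closed-class lexicon plus suffix-heuristic tagger and a rule
  lemmatizer (plural and participle stripping, small irregular table).

This is not a statistical tagger; on open-class words outside its
heuristics it defaults to `NN`, which is the conservative choice for the
rules (they only ever act on confidently closed-class material). Gold
spans that cross token boundaries are projected onto the covering tokens
(recall-preserving) and counted, never silently dropped.

## Features

Six families, each independently switchable (the ablation axes). "Window
size *w*" means offsets −*w*…+*w* **excluding 0**; the current token is
covered by the corresponding non-context family. One deviation: the
lexical stop-word feature includes offset 0, because no non-context
stop-word feature exists and the current token's stop-word status would
otherwise be unobservable. Out-of-sentence positions emit `_BOS_`/`_EOS_`
sentinels.

| family | features | default |
|---|---|---|
| baseline | current token text | always on |
| linguistic | lemma, POS | on |
| orthographic | word case; presence of digit, brackets, slash, dash, quote, double quote, parentheses | on |
| morphological | prefixes len 2–3, suffixes len 1–4, word shape + collapsed shape, character bigrams | on |
| context | lemma ±2, POS ±4, shape ±2, neighbour prefixes/suffixes ±1 | on |
| lexical | stop-word flags in ±4 | on |
| other | Brown cluster path (+4- and 6-bit prefixes), token length class | on |

Open choices resolved here: neighbour affix lengths "from 1 and 4" are
read as the set {1, 4}, mirroring the phrasing used for prefixes
"from 2 and 3" = {2, 3} (both remain configurable); token length classes
use bins 1, 2–3, 4–6, 7–10, 11+; character bigrams are position-free
adjacent pairs. Word shape maps upper case to `X`, lower case to `x`,
digits to `d`, everything else verbatim, with a run-squeezed collapsed
variant (`HP_0000077` → `XX_ddddddd` / `X_d`).

Brown clusters are trained on the corpus text at build time (no label
information, hence no leakage): greedy agglomerative merging of word
classes that minimizes the loss in average mutual information of the
class bigram distribution, with a working width of 50 classes; each word
receives its class's bit path in the merge tree. A precomputed map can be
supplied instead.

## Sequence model

A linear-chain CRF over the `{B, I, O}` alphabet with per-token sparse
binary attributes tied to each state, plus begin/transition/end weights.
Since the label set is complete and tiny, the `possible_states` /
`possible_transitions` switches are saturated: every state and transition
weight exists regardless; they are recorded in the configuration for
fidelity.

Training is stochastic gradient descent on the negative log-likelihood
with learning rate `eta0 / (1 + lambda * eta0 * t)`, `lambda = c2 / N`,
and multiplicative L2 decay; defaults `c2 = 1`, `eta0 = 0.3`, 60 epochs,
relative-loss stopping at 1e-5. The reference configuration also prints
an L1 coefficient of 0.9833 even though a pure SGD-with-L2 optimizer has
no L1 path; we honour it as an elastic-net companion, applied as a
per-epoch proximal soft-threshold of `c1 * eta / N` on state and
transition weights. At these data scales its effect is a mild sparsifier;
setting `c1 = 0` recovers plain L2 SGD. Gradients use log-domain
forward–backward; decoding is Viterbi. Training is deterministic given
the configuration seed (epoch shuffles use a private Mersenne Twister).

Cross-validation folds are assigned at **document** level (sentence-level
splitting would leak an abstract's vocabulary across the train/test
boundary), deterministically given a seed, with fold sizes differing by
at most one.

## Dictionary and word lists

The validation dictionary maps normalized surfaces (lower-case, collapsed
whitespace — no stemming, because phenotype surfaces are
inflection-sensitive) to ontology ids. It contains ontology names and
synonyms, the **training fold's** annotation surfaces, and generated
variations; per fold it is rebuilt so that no surface occurring only in
test-fold annotations can enter a rule (a property test enforces this).

The variation grammar is exemplified, not enumerated, in its source; the
implementation covers: `"<head> <connector> <tail>"` ⇄ `"<tail> <head>"`
with connectors `of`, `of the`, `in the` (configurable), and
singular/plural toggling restricted to common-HPO-noun heads. Every
generated surface carries exactly the content words of the original.

Five editable word lists ship as plain text (one phrase per line, `#`
comments): common HPO nouns, connector phrases, positive-connotation
nouns, exact stop phrases, partial stop phrases. They are configuration,
not code; the defaults are seeded from the canonical examples
("abnormalities", "malformations"; "development"; "hippocampus").

## Validation rules

Pipeline order: dictionary mentions → entity variations → longer
entities → smaller entities → one second identification pass → general
errors → incorrect structure → negative connotation → stop words.
Identification rules never remove; removal rules never add; every removal
stores a reason, so per-reason counts reconcile exactly with
before/after totals. Deduplication is by span, earliest phase wins.
Nested candidates from distinct dictionary entries are all retained
(superclass mentions inside subclass mentions are wanted, not noise).

Design points worth recording:

* **Expansion direction.** The boundary-expansion rule is implemented in
  both directions. The canonical example ("rib anomalies" growing to
  "spine and rib anomalies") adds material to the *left* of the seed even
  though its prose labels the move "to the right"; we treat the label as
  an erratum and pin the leftward case in a test.
* **Digit-led spans.** The observed correction `"36 schwannomas"` →
  `"schwannomas"` is split across the two phases to preserve
  monotonicity: the smaller-entities rule (identification) emits the
  candidate stripped of leading digit-only tokens, and the
  incorrect-structure rule (removal) removes candidates that *start*
  with a digit-only token.
* **Distributed conjuncts.** Splitting `"pits of the palms and soles"`
  yields `"pits of the palms"` directly (a contiguous subspan). The
  distributed form `"pits of the soles"` has no contiguous span, and a
  candidate without a span cannot be evaluated; it is therefore anchored
  to its own occurrence elsewhere in the document if one exists, else
  dropped. The behaviour is flag-controlled (`distribute`).
* **Second validation.** Runs exactly once (two passes total); fixtures
  confirm a third pass adds nothing.
* **Unbalanced punctuation.** "Containing only a single
  quote/parenthesis" is read as unbalanced quote or parenthesis
  characters.

## Evaluation and corpus extension

Scoring is exact-span micro P/R/F keyed on (document, start, end);
ontology-id equality is optional (`id_strict`), since id assignment for
CRF-origin spans is best-effort dictionary lookup. The false-positive
filter drops predictions absent from gold whose surface exact-matches the
dictionary; true positives are untouched, so recall is invariant by
construction and F cannot decrease — the size of the jump estimates how
much apparent error is gold under-annotation. Corpus extension
(`build_gsc_plus`) appends predictions whose surface exact-matches an
ontology name/synonym or an existing gold surface at a not-yet-annotated
span; matching is case-insensitive with whitespace normalization
(strict-case mode available). The inconsistency report flags four suspect
classes: partially annotated repeated surfaces, surfaces with no
standalone ontology meaning, unannotated nested dictionary surfaces, and
unannotated superclass mentions elsewhere in the document.

## The synthetic world

The generator emulates the corpus format and the documented annotation
phenomena: single-line abstracts; terms of the forms "abnormality of the
\<part\>" (synonym "\<part\> abnormality") and single-token terms;
mention-level variation rewriting; coordinated mentions with optionally
annotated nested conjuncts; deliberately unannotated mentions; planted
positive-connotation and stop-word distractors. Default rates (variation
0.3, coordination 0.2, nesting 0.5, under-annotation 0.15, distractors
0.3 per document) were chosen once as a plausible density of each
phenomenon in a small curated corpus and are not tuned to test outcomes;
every planted mention is recorded in a ledger so tests assert against
construction, not against the pipeline.

What a green test does establish: format round-trips, offset arithmetic,
the BIO projection, rule semantics on the quoted examples, leakage
freedom, monotonicity of the two phases, recall invariance of the
filter, and that the full train→predict→validate loop recovers a
separable vocabulary (F ≥ 0.9). What it does not establish: performance
on real abstracts. The synthetic vocabulary is closed and separable,
sentences are templated, and the tagger sees only easy syntax — so
absolute metrics here say nothing about the published corpus-scale
numbers, which additionally depend on tool versions that are not
recoverable. The acceptance script therefore reports no machine targets;
directional claims (identification ↑ recall, removal ↑ precision,
filter ↑ F) are asserted on the synthetic corpus instead.

## Known limitations

* The bundled tagger is heuristic; uncommon adjectives default to `NN`,
  which can over-extend nominal runs in the variation rule. The
  preprocessing contract allows swapping in a statistical tagger.
* Surfaces mapping to several ontology ids keep all ids; no
  disambiguation is attempted (evaluation is span-based).
* Brown clustering is the merge-only greedy variant without an exchange
  refinement pass; adequate for small corpora, not optimized for large
  vocabularies.
* Negation and uncertainty scope are out of scope beyond the
  negative-connotation heuristic.
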