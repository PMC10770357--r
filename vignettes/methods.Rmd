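---
title: "Methods: term resolution, dialogue state, and cohort analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: term resolution, dialogue state, and cohort analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncovoice)
```

## The problem

Spoken queries about cancer genomics founder on vocabulary: gene symbols
("TP53", "PIK3CA") are out-of-vocabulary for general-purpose speech
recognizers, which emit noisy transcriptions like "tee pee five three" or
"pick three see ay". `oncovoice` implements a desk-scale engine for this
setting: it resolves noisy transcriptions to canonical attribute values,
tracks a three-slot conversational state, and answers the resulting query
against a harmonized cohort knowledge base. Typed text stands in for the
speech-to-text hand-off throughout; audio processing is out of scope.

## Term resolution: the four-stage chain

A query utterance passes through stages in a fixed order, and the first
stage that resolves wins:

1. **Personal pronunciations** — per-user overrides ("when I say 'kay ras'
   I mean KRAS"), keyed by `(user, normalized transcription)`. They exist
   precisely to repair failed mappings, so they outrank every other stage
   for their owner, and only for their owner.
2. **Exact matching** — the normalized utterance is looked up against the
   normalized canonical values and synonyms of the lexicon. When the least
   disambiguation is required this stage resolves and the rest are skipped.
3. **Crowdsourced-utterance lookup** — the normalized utterance is looked
   up among stored pronunciation transcriptions. It resolves only when all
   matching records agree on a single target; ambiguous transcriptions fall
   through to prediction rather than erroring, because this stage is only
   trustworthy when it maps to one value.
4. **Predicted matching** — a 200-tree random forest over features of the
   transcription votes for a `(attribute type, canonical value)` class.
   The per-tree votes are tallied explicitly; ties are split by a seeded
   uniform draw, so identical (input, model, seed) triples always reproduce
   the same answer. The vote fraction of the winning class is reported as
   the confidence. The forest itself is fit with `ranger`.

All lookup keys pass through one normalizer: lowercase, punctuation
stripped, whitespace collapsed, then a token-wise rule-based English
lemmatizer ("mutations" → "mutation"). Tokens containing digits, and short
tokens generally, are exempt from lemmatization so gene symbols are never
stemmed. Using the same transform for stored transcriptions and incoming
queries keeps the lookup symmetric. Input that is empty after cleaning
yields `NA`, a distinct signal the chain treats as unresolvable.

### Features

The featurizer is fit on the training partition only and is a
deterministic function of the normalized string:

* character n-grams, n ∈ {2, 3, 4}, over the string with boundary markers
  (`^`, `$`, spaces as `_`), TF-IDF weighted with smoothed IDF; n-grams
  unseen in training contribute zero;
* n-grams (n ∈ {1, 2, 3}) of a phonetic key computed per whitespace token.
  The keyer folds common digraphs (ph→f, gh→g, ck→k, kn→n, wr→r), drops
  vowels, maps consonants to Soundex-style sound classes and collapses
  runs, so "kras", "krass" and "kay rass"-style variants collide. A compact
  in-package keyer was chosen over heavier phonetic algorithms: the
  classifier only needs a noise-tolerant collision channel, not a faithful
  pronunciation model, and an auditable 40-line transform is easier to
  reason about in tests;
* a vowel-group syllable count (digits count one syllable each, since
  symbols are spoken digit by digit) and length features (characters,
  tokens, digits).

### Training protocol and evaluation

`train_matcher()` shuffles the corpus with a seeded permutation and takes
`floor(f·N)` records for training (at the published corpus size of 24,093
and f = 0.9 this gives partitions of 21,683 and 2,410). The featurizer and
forest see only the training partition. `evaluate_matcher()` reports the
fraction of held-out records the *full chain* resolves correctly — with
crowdsourced lookup backed by the training partition only — alongside the
exact-only baseline, which the chain can never underperform because exact
matching is its second stage.

## Synthetic pronunciation corpus

Because no human pronunciation corpus ships with the package, a seeded
generator produces one with known truth. `generate_lexicon()` builds
gene-like symbols (letters + digits), multiword cancer types with
synonyms, and the three standard data types (mutations, copy number
alterations, gene expression). `generate_utterance_corpus()` then emits
`variants_per_term` transcriptions per term under a fixed perturbation
inventory — digit spell-out ("53" → "five three"), letter-name expansion
("tp" → "tee pee"), phonetic substitutions (c→k, s→z, vowel swaps), token
splitting/joining, and character drops — each applied independently with
probability `noise_level`. At noise 0 every transcription equals its term.
The defaults (noise 0.3, 10 variants per term, a 63-term lexicon) are the
package's reference conditions; at those conditions the held-out
full-chain accuracy clears 0.80 by a wide margin while the exact-only
baseline sits near 0.25, which is the qualitative regime the chain is
designed for.

What the generator does **not** emulate: accent structure, speaker-level
consistency, recognizer language-model biases, and real homophone
collisions between gene symbols. Passing tests therefore demonstrate that
the chain recovers terms under heavy but *synthetic* transcription noise;
accuracy on human speech transcriptions is a property of the corpus, not
of this code, and should be re-measured when one is available.

## Dialogue state

The navigation state has three slots — gene, cancer type, data type — all
empty in a fresh session. Incoming values update their own slot and never
touch the others, so attributes can arrive incrementally and in any order,
and "how about PIK3CA?" after a complete query switches only the gene.
Response dispatch is a pure function of the fill pattern and intent: all
three slots on a navigate intent give a gene summary; data type + cancer
type without a gene give a cohort overview (most frequently altered
genes); anything less prompts for the first missing attribute. The
prompting order (data type, then cancer type, then gene) is a fixed
convention chosen so the conversation narrows from assay to cohort to
gene. Intent triggers are fixed keyword patterns ("compare … with …",
"split by <gene>", "reset", "help"), the package's stand-in for a voice
platform's interaction model; carrier phrases ("tell me about …",
"show me …") are stripped before the mapper sees the utterance for the
same reason. Comparing two cancer types while the gene slot is filled is
permitted; comparing with an empty focal slot is an error with
explanatory text rather than a crash.

## Harmonization rules (ingest)

The mutation dialect is a minimal five-column TSV (`sample_id`, `gene`,
`variant_class`, `impact`, semicolon-separated `callers`); full MAF exports
can be projected onto it. Records pass a consensus policy:

* **MAJORITY mode** (multi-caller exome harmonization): an SNV needs at
  least 2 of the 4 configured callers (MuTect2, SomaticSniper, Varscan,
  MuSE); indels, which only two of those callers emit, need *both* MuTect2
  and Varscan.
* **UNION mode** (caller-union whole-genome call sets): any one caller of
  the configured pair suffices.

Surviving records must carry MODERATE or HIGH functional impact (impact is
taken as a pre-computed input column; effect prediction is out of scope)
and a gene on the coding-sequence whitelist. Gene symbols match
case-sensitively after uppercase normalization at load (with a warning
when any symbol changes). `build_knowledge_base()` optionally restricts
the manifest to samples present in both the mutation and CNA inputs, the
rule used for cohorts distributed only with complete DNA data.

Frequency denominators use the per-assay sample manifest, not the union of
samples across assays, because assays cover different sample subsets;
multiple qualifying mutations in one (sample, gene) count once.

## Analytics

* `mutation_frequency()` / `top_mutated_genes()`: distinct altered samples
  over the mutation-assay manifest; ranking ties break alphabetically for
  reproducible output.
* `cna_frequency()`: amplification and deletion frequencies over the
  CNA-assay manifest; categories are input facts.
* `compare_attributes()`: data-type comparison builds a 2×2 contingency of
  alteration status over samples present in both assays; gene comparison
  reports both frequencies plus the co-mutated count; cancer-type
  comparison reports the focal gene's frequency in each cohort.
* `split_by()`: expression of one gene stratified by the post-filter
  mutation status of another, summarized per group and tested with a
  two-sided Wilcoxon rank-sum (normal approximation; a Welch t-test is
  available via `test = "welch"`). The rank-sum default needs no
  distributional assumption on expression; an empty group degrades to a
  descriptive result with a warning rather than an error.
* `render_result()` writes a PNG figure and a TSV whose bytes are a
  deterministic function of the result.

## Synthetic cohorts and what the tests show

`generate_cohort()` plants per-gene mutation rates, amplification/deletion
rates, per-gene Gaussian expression, and expression shifts (in sd units)
in samples mutant for a partner gene. A planted mutation always carries
qualifying evidence — two guaranteed callers plus extras firing at the
caller sensitivity, or both indel callers, and MODERATE/HIGH impact — so
the post-filter frequency is an exact binomial draw of the planted rate;
separately, spurious sub-threshold records (single-caller, or multi-caller
with LOW/MODIFIER impact) are emitted at the false-call rate so the
consensus filter has genuine work to do. This split of roles makes
recovery analyzable: the pipeline's post-filter count must equal the
planted count *exactly*, and the observed frequency differs from the
planted rate only by binomial sampling.

The recovery checks exploit that structure. At n = 1,000 the tests assert
exact count recovery for every gene, and rate containment in per-gene
exact binomial 99% intervals with the number of misses bounded by the
99.9% binomial quantile for the number of intervals checked — with 60
simultaneous 99% intervals, one stray miss is expected behavior for a
perfectly calibrated generator, so a joint all-must-pass assertion would
reject correct code about half the time. The split-by checks use a
two-gene design (partition gene at rate 0.5, n = 200, so ~100 per group):
a planted 2 sd shift must give p < 0.01, and under the null (shift 0) the
rejection rate at α = 0.05 over 200 seeded replicates must lie in
[0.01, 0.10].

Problem sizes throughout (630-record corpora, cohorts of 50–1,000
samples, 200 null replicates) were chosen so the full suite exercises
every statistical claim in well under a minute while keeping sampling
error small relative to each assertion's margin.

## Known limitations

* The matcher treats all three attribute types jointly in one classifier;
  no platform-side slot elicitation narrows the candidate set first.
* Word embeddings are not part of the default feature set; the featurizer
  is pluggable if a context-aware representation becomes worthwhile.
* Expression values are taken as given (assumed normalized/log-scale);
  no re-normalization is applied.
* CNA categories and variant impact are input facts; segmentation,
  thresholds and effect prediction happen upstream.
* Response wording is this package's own minimal template set.
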