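# oncovoice

Conversational exploration of cancer cohort genomics, with noisy-term
resolution. `oncovoice` is for bioinformaticians and tool builders who want
a voice-assistant-style query loop over cohort genomic data without any
cloud speech stack: typed utterances stand in for speech-to-text output,
and everything runs locally against TSV knowledge bases.

It has three scientific parts:

1. **Out-of-vocabulary term mapping.** Spoken gene symbols are mangled by
   general-purpose recognizers ("TP53" → "tee pee five three"). A query
   transcription *t* is resolved through a chain of stages — per-user
   personal pronunciations, exact matching of the normalized string against
   the lexicon (canonical values + synonyms), crowdsourced-utterance lookup
   (resolving only when all stored records with that transcription agree on
   one target), and finally a 200-tree random-forest classifier over
   character n-gram TF-IDF, phonetic-key n-gram, syllable and length
   features of *t*, with class = (attribute type, canonical value). The
   forest's per-tree votes are tallied explicitly; the majority class wins,
   ties split by a seeded uniform draw, confidence = vote fraction.
2. **Dialogue state.** A three-slot navigation state (GENE, CANCER TYPE,
   DATA TYPE) updated incrementally and in any order; the response class is
   a pure function of the fill pattern and intent (gene summary, cohort
   overview, prompt for the missing slot, compare view, split-by view).
3. **Cohort analytics over a harmonized knowledge base.** Ingest applies
   multi-caller consensus rules (SNVs: called by ≥ 2 of MuTect2,
   SomaticSniper, Varscan, MuSE; indels: by both MuTect2 and Varscan — or
   caller unions in UNION mode), a MODERATE/HIGH functional-impact gate and
   a coding-gene whitelist. The explorer computes alteration frequencies
   (f = altered samples / assay manifest size), rankings, 2×2 cross-assay
   contingencies, and mutation-stratified expression comparisons tested
   with a two-sided Wilcoxon rank-sum.

Seeded generators produce synthetic cohorts and pronunciation corpora with
known planted structure, so every claim above is testable without any
download. See the methods vignette (`vignettes/methods.Rmd`) for the
modeling choices and their rationale.

## Worked example

Build a synthetic breast-cancer cohort, harmonize it into a knowledge
base, and hold a conversation:

```r
library(oncovoice)

spec <- cohort_spec(n_samples = 200, seed = 5)
raw  <- generate_cohort(spec)
mut  <- raw$mutations; mut$callers <- strsplit(mut$callers, ";")
kb   <- tempfile()
build_knowledge_base(mut, raw$cna, raw$expression, consensus_policy(),
                     whitelist = spec$genes$gene, kb_dir = kb,
                     cancer_type = "breast cancer",
                     sample_manifest = raw$manifest)

lex <- term_lexicon(rbind(
  data.frame(value = spec$genes$gene, attribute_type = "GENE", synonyms = ""),
  data.frame(value = "breast cancer", attribute_type = "CANCER_TYPE",
             synonyms = "breast carcinoma"),
  data.frame(value = c("mutations", "copy number alterations", "gene expression"),
             attribute_type = "DATA_TYPE",
             synonyms = c("mutation", "copy number|cna", "expression"))))

run_repl(kb, lex, input = c(
  "tell me about mutations", "show me breast cancer", "tp53",
  "how about pik3ca", "gene expression", "split by tp53"))
```

which prints:

```
Which cancer type would you like to explore?
Most frequently mutated genes in breast cancer: TP53 (59%), PIK3CA (55%), KRAS (54%), MYC (52%), BRCA1 (48%).
TP53 is mutated in 59.0% of breast cancer samples (118 of 200).
PIK3CA is mutated in 54.5% of breast cancer samples (109 of 200).
PIK3CA expression in breast cancer: mean 6.23, median 6.34 over 200 samples.
PIK3CA expression by TP53 status: mutant mean 7.04 (n=118), wild-type mean 5.07 (n=82), p = 1.09e-24.
```

Line by line: with only a data type set, the engine prompts for the
cohort; with data type + cancer type it lists the most frequently mutated
genes (the generator planted rates descending from 0.6, and TP53 indeed
ranks first); naming a gene gives its post-filter mutation frequency
(118/200 = 59.0%); "how about pik3ca" switches only the gene slot;
switching the data type to expression summarizes it; and "split by tp53"
stratifies PIK3CA expression by TP53 mutation status — the generator
planted a +2 sd shift in TP53-mutant samples, which the rank-sum test
flags at p ≈ 1e-24.

The same flow is available from a shell via `inst/cli/oncovoice` with
subcommands `ingest`, `train-oov`, `eval-oov`, `chat`, `simulate-cohort`
and `simulate-utterances`.

To train and evaluate the term matcher on a synthetic pronunciation
corpus:

```r
lex    <- generate_lexicon(50, 10, 3, seed = 7)
corpus <- generate_utterance_corpus(lex, perturbation_spec(0.3, 10, seed = 7))
fit    <- train_matcher(corpus, train_fraction = 0.9, seed = 7)
train  <- split_corpus(corpus, 0.9, seed = 7)$train
evaluate_matcher(fit$model, fit$heldout, lex, train, seed = 7)[c("accuracy", "baseline_accuracy")]
#> $accuracy
#> [1] 0.9206349
#> $baseline_accuracy
#> [1] 0.2857143
```

The full resolution chain recovers 92% of held-out noisy transcriptions
versus 29% for exact matching alone.

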