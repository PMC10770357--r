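# Shared fixtures, all built in code.

# small lexicon with real-looking attribute values
make_test_lexicon <- function(extra_genes = character(0)) {
  term_lexicon(rbind(
    data.frame(value = c("TP53", "PIK3CA", "KRAS", "MYC", extra_genes),
               attribute_type = "GENE", synonyms = ""),
    data.frame(value = c("breast cancer", "lung cancer"),
               attribute_type = "CANCER_TYPE",
               synonyms = c("breast carcinoma", "lung carcinoma")),
    data.frame(value = c("mutations", "copy number alterations",
                         "gene expression"),
               attribute_type = "DATA_TYPE",
               synonyms = c("mutation", "copy number|cna", "expression"))))
}

# utterance corpus as a data frame (already normalized)
make_corpus <- function(transcription, target_value, attribute_type) {
  data.frame(transcription = transcription, target_value = target_value,
             attribute_type = attribute_type, speaker_id = NA_character_,
             norm = normalize_text(transcription))
}

# tiny hand-built cohort: 10 samples, TP53 mutated in 4, PIK3CA in 3,
# KRAS in 1; TP53 amplified in 3, deleted in 2
make_toy_cohort <- function() {
  samples <- sprintf("S%02d", 1:10)
  mutations <- data.frame(
    sample_id = c("S01", "S02", "S03", "S04",       # TP53
                  "S01", "S05", "S06",              # PIK3CA
                  "S07",                            # KRAS
                  "S02"),                           # TP53 again (same sample)
    gene = c(rep("TP53", 4), rep("PIK3CA", 3), "KRAS", "TP53"),
    variant_class = "SNV", impact = "MODERATE",
    callers = I(rep(list(c("mutect2", "varscan")), 9)))
  cna <- data.frame(
    sample_id = c("S01", "S02", "S03", "S04", "S05",
                  samples),
    gene = c(rep("TP53", 5), rep("PIK3CA", 10)),
    category = c("amplification", "amplification", "amplification",
                 "deletion", "deletion", rep("neutral", 10)))
  set.seed(42)
  expr <- matrix(rnorm(20, mean = 5), nrow = 2,
                 dimnames = list(c("TP53", "PIK3CA"), samples))
  manifest <- data.frame(sample_id = samples, mutations = 1L, cna = 1L,
                         expression = 1L)
  cohort_dataset("breast cancer", mutations, cna, expr, manifest)
}

# raw mutation records builder for filter tests
make_mut_record <- function(sample_id, gene, variant_class, impact, callers) {
  data.frame(sample_id = sample_id, gene = gene,
             variant_class = variant_class, impact = impact,
             callers = I(list(callers)))
}
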