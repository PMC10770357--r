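pol <- consensus_policy()

test_that("consensus filter applies the caller and impact rules", {
  recs <- rbind(
    make_mut_record("S1", "TP53", "SNV", "MODERATE", c("mutect2", "muse")),
    make_mut_record("S2", "TP53", "SNV", "MODERATE", "mutect2"),
    make_mut_record("S3", "TP53", "DEL", "HIGH", "varscan"),
    make_mut_record("S4", "TP53", "DEL", "HIGH", c("mutect2", "varscan")),
    make_mut_record("S5", "TP53", "SNV", "HIGH",
                    c("mutect2", "somaticsniper", "muse")),
    make_mut_record("S6", "TP53", "SNV", "LOW",
                    c("mutect2", "somaticsniper", "muse")),
    make_mut_record("S7", "TP53", "INS", "MODERATE", c("mutect2", "varscan")),
    make_mut_record("S8", "TP53", "INS", "MODERATE", "mutect2"))
  kept <- apply_consensus_filter(recs, pol)
  expect_setequal(kept$sample_id, c("S1", "S4", "S5", "S7"))
})

test_that("union mode keeps single-caller records of the configured pair", {
  upol <- consensus_policy(mode = "UNION",
                           snv_caller_set = c("mutect2", "varscan"),
                           indel_caller_set = c("mutect2", "varscan"))
  recs <- rbind(
    make_mut_record("S1", "TP53", "SNV", "MODERATE", "mutect2"),
    make_mut_record("S2", "TP53", "DEL", "HIGH", "varscan"),
    make_mut_record("S3", "TP53", "SNV", "MODERATE", "muse"))
  kept <- apply_consensus_filter(recs, upol)
  expect_setequal(kept$sample_id, c("S1", "S2"))
})

test_that("filter matches a brute-force oracle on a generated 1000-record table", {
  spec <- cohort_spec(n_samples = 250, seed = 17, false_call_rate = 0.15)
  raw <- generate_cohort(spec)
  recs <- raw$mutations
  recs$callers <- strsplit(recs$callers, ";", fixed = TRUE)
  expect_gte(nrow(recs), 1000)
  kept <- apply_consensus_filter(recs, pol)
  # independent re-statement of the rules, row by row
  oracle_keep <- vapply(seq_len(nrow(recs)), function(i) {
    cs <- recs$callers[[i]]
    ok_callers <- if (recs$variant_class[i] == "SNV") {
      sum(cs %in% c("mutect2", "somaticsniper", "varscan", "muse")) >= 2
    } else {
      ("mutect2" %in% cs) && ("varscan" %in% cs)
    }
    ok_callers && recs$impact[i] %in% c("MODERATE", "HIGH")
  }, logical(1))
  expect_equal(rownames(kept), rownames(recs)[oracle_keep])
})

test_that("adding callers never removes records; raising the bar never adds", {
  recs <- rbind(
    make_mut_record("S1", "TP53", "SNV", "MODERATE", c("mutect2", "muse")),
    make_mut_record("S2", "TP53", "SNV", "HIGH", "varscan"))
  kept1 <- apply_consensus_filter(recs, pol)
  boosted <- recs
  boosted$callers <- lapply(boosted$callers, function(cs)
    unique(c(cs, "somaticsniper")))
  kept2 <- apply_consensus_filter(boosted, pol)
  expect_true(all(rownames(kept1) %in% rownames(kept2)))
  stricter <- consensus_policy(snv_min_callers = 3L)
  kept3 <- apply_consensus_filter(recs, stricter)
  expect_true(all(rownames(kept3) %in% rownames(kept1)))
})

test_that("whitelist filtering is case-sensitive and rejects empty lists", {
  recs <- rbind(
    make_mut_record("S1", "TP53", "SNV", "HIGH", c("mutect2", "muse")),
    make_mut_record("S2", "WEIRD9", "SNV", "HIGH", c("mutect2", "muse")))
  expect_equal(apply_gene_whitelist(recs, c("TP53"))$gene, "TP53")
  expect_equal(nrow(apply_gene_whitelist(recs, c("tp53"))), 0L)
  expect_equal(nrow(apply_gene_whitelist(recs, c("TP53", "WEIRD9", "MYC"))),
               2L)
  expect_error(apply_gene_whitelist(recs, character(0)), "empty")
})

test_that("consensus and whitelist filters commute", {
  spec <- cohort_spec(n_samples = 60, seed = 9, false_call_rate = 0.2)
  raw <- generate_cohort(spec)
  recs <- raw$mutations
  recs$callers <- strsplit(recs$callers, ";", fixed = TRUE)
  wl <- spec$genes$gene[1:7]
  a <- apply_gene_whitelist(apply_consensus_filter(recs, pol), wl)
  b <- apply_consensus_filter(apply_gene_whitelist(recs, wl), pol)
  expect_equal(a, b)
})

test_that("loaders validate their closed vocabularies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene\tvariant_class\timpact\tcallers",
               "S1\tTP53\tSNV\tMODERATE\tmutect2;muse"), path)
  recs <- load_mutations(path)
  expect_equal(length(recs$callers[[1]]), 2L)
  writeLines(c("sample_id\tgene\tvariant_class\timpact\tcallers",
               "S1\tTP53\tSNV\tBANANA\tmutect2"), path)
  expect_error(load_mutations(path), "bad impact at row\\(s\\) 1")
  writeLines(c("sample_id\tgene\tvariant_class\timpact\tcallers",
               "S1\tTP53\tSNV\tHIGH\tfancycaller"), path)
  expect_error(load_mutations(path), "unknown caller")
  writeLines(c("sample_id\tgene\tcategory",
               "S1\tTP53\tamplification", "S2\tTP53\tneutral",
               "S3\tTP53\tdeletion"), path)
  expect_equal(nrow(load_cna(path)), 3L)
  writeLines(c("sample_id\tgene\tcategory",
               "S1\tTP53\tgain"), path)
  expect_error(load_cna(path), "unknown CNA category")
  writeLines(c("sample_id\tgene\tcategory",
               "S1\tTP53\tamplification", "S1\tTP53\tdeletion"), path)
  expect_error(load_cna(path), "duplicate")
  writeLines(c("gene\tS1\tS2", "TP53\t1.5\toops"), path)
  expect_error(load_expression(path), "non-numeric")
})

test_that("knowledge base honors the both-assays sample rule and round-trips", {
  # 10 mutation samples, 8 CNA samples, overlap 6
  mut_samples <- sprintf("S%02d", 1:10)
  cna_samples <- sprintf("S%02d", 5:12)
  mutations <- do.call(rbind, lapply(mut_samples, function(s)
    make_mut_record(s, "TP53", "SNV", "HIGH", c("mutect2", "muse"))))
  cna <- data.frame(sample_id = cna_samples, gene = "TP53",
                    category = "neutral")
  expr <- matrix(5, 1, 10, dimnames = list("TP53", mut_samples))
  kb <- withr::local_tempdir()
  build_knowledge_base(mutations, cna, expr, pol, "TP53", kb,
                       "lung cancer", require_both = TRUE)
  ds <- load_cohort(kb, "lung cancer")
  expect_equal(nrow(ds$manifest), 6L)
  expect_setequal(ds$manifest$sample_id, intersect(mut_samples, cna_samples))
  # without the rule, per-assay manifests are kept as-is
  kb2 <- withr::local_tempdir()
  build_knowledge_base(mutations, cna, expr, pol, "TP53", kb2,
                       "lung cancer", require_both = FALSE)
  ds2 <- load_cohort(kb2, "lung cancer")
  expect_equal(sum(ds2$manifest$mutations), 10L)
  expect_equal(sum(ds2$manifest$cna), 8L)
  # round trip: frequencies recomputed from the written kb equal brute force
  freq <- mutation_frequency(ds2, "TP53")
  expect_equal(freq$frequency, 1)
  expect_error(build_knowledge_base(mutations[0, ], cna[0, ],
                                    expr[, 0, drop = FALSE],
                                    pol, "TP53", kb, "empty cohort",
                                    require_both = TRUE),
               "zero surviving samples|empty")
})
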