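ds <- make_toy_cohort()

test_that("mutation frequency counts distinct altered samples over the manifest", {
  gs <- mutation_frequency(ds, "TP53")
  # S02 carries two TP53 records but counts once
  expect_equal(gs$altered_sample_count, 4L)
  expect_equal(gs$cohort_size, 10L)
  expect_equal(gs$frequency, 0.4)
  expect_equal(mutation_frequency(ds, "NOSUCH")$frequency, 0)
  all_mut <- ds
  all_mut$mutations <- data.frame(sample_id = ds$manifest$sample_id,
                                  gene = "TP53", variant_class = "SNV",
                                  impact = "HIGH",
                                  callers = I(rep(list("mutect2"), 10)))
  expect_equal(mutation_frequency(all_mut, "TP53")$frequency, 1)
})

test_that("top gene ranking is frequency-descending with alphabetical ties", {
  top <- top_mutated_genes(ds, k = 10)
  expect_equal(top$gene, c("TP53", "PIK3CA", "KRAS"))
  expect_equal(top$frequency, c(0.4, 0.3, 0.1))
  expect_equal(nrow(top_mutated_genes(ds, k = 2)), 2L)
  # plant a tie: ABL1 also in one sample -> alphabetical before KRAS
  tied <- ds
  tied$mutations <- rbind(ds$mutations,
                          make_mut_record("S09", "ABL1", "SNV", "HIGH",
                                          c("mutect2", "muse")))
  top2 <- top_mutated_genes(tied, k = 10)
  expect_equal(top2$gene[3:4], c("ABL1", "KRAS"))
})

test_that("CNA frequencies use the CNA manifest as denominator and conserve", {
  cf <- cna_frequency(ds, "TP53")
  expect_equal(cf$amplification$frequency, 0.3)
  expect_equal(cf$deletion$frequency, 0.2)
  neutral <- cf$amplification$cohort_size -
    cf$amplification$altered_sample_count - cf$deletion$altered_sample_count
  expect_equal(cf$amplification$altered_sample_count +
                 cf$deletion$altered_sample_count + neutral, 10L)
  cf2 <- cna_frequency(ds, "PIK3CA") # all neutral
  expect_equal(cf2$amplification$frequency, 0)
  expect_equal(cf2$deletion$frequency, 0)
})

test_that("expression summaries handle constants, missing values and absent genes", {
  const <- ds
  const$expression["TP53", ] <- 7
  es <- expression_summary(const, "TP53")
  expect_equal(es$sd, 0)
  expect_equal(es$mean, 7)
  holey <- ds
  holey$expression["TP53", 1:3] <- NA
  expect_equal(expression_summary(holey, "TP53")$n, 7L)
  expect_error(expression_summary(ds, "NOSUCH"), "not in expression")
  # sampling check: N(5, 1) at n = 200 lands near its mean
  spec <- cohort_spec(n_samples = 200, seed = 31)
  raw <- generate_cohort(spec)
  big <- cohort_dataset("x", raw$mutations[0, ], raw$cna[0, ],
                        raw$expression, raw$manifest)
  expect_lt(abs(expression_summary(big, "MDM2")$mean - 5), 0.2)
})

test_that("data-type comparison builds a conserved 2x2 over shared samples", {
  s <- new_session()
  s <- apply_attribute(s, "GENE", "TP53")
  s <- apply_attribute(s, "CANCER_TYPE", "breast cancer")
  s <- apply_attribute(s, "DATA_TYPE", "mutations")
  cr <- compare_attributes(ds, s, "DATA_TYPE", "copy number alterations")
  # brute force: mutated {S01..S04}; CNA-altered {S01..S05}; both assays all 10
  expect_equal(unname(cr$contingency["both"]), 4L)
  expect_equal(unname(cr$contingency["a_only"]), 0L)
  expect_equal(unname(cr$contingency["b_only"]), 1L)
  expect_equal(unname(cr$contingency["neither"]), 5L)
  expect_equal(sum(cr$contingency), cr$n)
})

test_that("gene and cancer-type comparisons report paired frequencies", {
  s <- new_session()
  s <- apply_attribute(s, "GENE", "TP53")
  s <- apply_attribute(s, "CANCER_TYPE", "breast cancer")
  s <- apply_attribute(s, "DATA_TYPE", "mutations")
  cr <- compare_attributes(ds, s, "GENE", "PIK3CA")
  expect_equal(cr$freq_a, 0.4)
  expect_equal(cr$freq_b, 0.3)
  expect_equal(cr$co_mutated, 1L) # S01 carries both
  # self-comparison has identical margins
  self <- compare_attributes(ds, s, "GENE", "TP53")
  expect_equal(self$freq_a, self$freq_b)
  expect_equal(self$co_mutated, 4L)
  ds2 <- ds
  ds2$cancer_type <- "lung cancer"
  cc <- compare_attributes(ds, s, "CANCER_TYPE", "lung cancer",
                           dataset_b = ds2)
  expect_equal(cc$freq_a, cc$freq_b)
  expect_error(compare_attributes(ds, s, "CANCER_TYPE", "lung cancer"),
               "second cohort")
})

test_that("split-by partitions eligible samples and detects a planted shift", {
  sb0 <- split_by(ds, "PIK3CA", "TP53")
  expect_equal(sb0$group_mutant$n + sb0$group_wildtype$n, sb0$n_eligible)
  expect_true(sb0$p_value >= 0 && sb0$p_value <= 1)
  # planted +2 sd shift in mutants, about 100 per group
  spec <- cohort_spec(
    n_samples = 200,
    genes = data.frame(gene = c("TP53", "PIK3CA"), mut_rate = c(0.5, 0),
                       amp_rate = 0, del_rate = 0, expr_mean = 5, expr_sd = 1),
    shifts = data.frame(quant_gene = "PIK3CA", partition_gene = "TP53",
                        shift_sd = 2),
    false_call_rate = 0, seed = 11)
  raw <- generate_cohort(spec)
  big <- cohort_dataset("x", {
    m <- raw$mutations; m$callers <- strsplit(m$callers, ";"); m
  }, raw$cna, raw$expression, raw$manifest)
  sb <- split_by(big, "PIK3CA", "TP53")
  expect_lt(sb$p_value, 0.01)
  expect_gt(sb$group_mutant$mean, sb$group_wildtype$mean)
  # oracle: rank-sum on the generated arrays directly
  status <- big$manifest$sample_id %in%
    big$mutations$sample_id[big$mutations$gene == "TP53"]
  oracle <- stats::wilcox.test(raw$expression["PIK3CA", status],
                               raw$expression["PIK3CA", !status],
                               exact = FALSE)
  expect_equal(sb$p_value, oracle$p.value)
  # degenerate partition warns and stays descriptive
  expect_warning(sb_empty <- split_by(big, "PIK3CA", "NOSUCH"),
                 "empty")
  expect_true(is.na(sb_empty$p_value))
  expect_error(split_by(big, "NOSUCH", "TP53"), "not in expression")
  # Welch alternative is available
  sbw <- split_by(big, "PIK3CA", "TP53", test = "welch")
  expect_lt(sbw$p_value, 0.01)
})

test_that("label permutation under the null keeps p-values well behaved", {
  spec <- cohort_spec(
    n_samples = 120,
    genes = data.frame(gene = c("TP53", "PIK3CA"), mut_rate = c(0.5, 0),
                       amp_rate = 0, del_rate = 0, expr_mean = 5, expr_sd = 1),
    shifts = data.frame(quant_gene = "PIK3CA", partition_gene = "TP53",
                        shift_sd = 0),
    false_call_rate = 0, seed = 13)
  raw <- generate_cohort(spec)
  v <- raw$expression["PIK3CA", ]
  status <- raw$manifest$sample_id %in%
    raw$mutations$sample_id[raw$mutations$gene == "TP53"]
  set.seed(13)
  ps <- replicate(100, {
    perm <- sample(status)
    stats::wilcox.test(v[perm], v[!perm], exact = FALSE)$p.value
  })
  expect_gte(mean(ps > 0.05), 0.9)
})
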