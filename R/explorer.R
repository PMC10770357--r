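# Cohort analytics behind each response class: alteration frequencies,
# rankings, cross-assay comparison, and mutation-stratified expression.

#' Load a cohort dataset from the knowledge base
#'
#' Reads `<kb_dir>/<cohort_dir>/{mutations.tsv, cna.tsv, expression.tsv,
#' manifest.tsv}` written by [build_knowledge_base()].
#'
#' @param kb_dir Knowledge-base root.
#' @param cancer_type Cohort label or directory slug.
#' @return A `cohort_dataset`.
#' @export
load_cohort <- function(kb_dir, cancer_type) {
  slug <- gsub("[^A-Za-z0-9]+", "_", cancer_type)
  dir_in <- file.path(kb_dir, slug)
  if (!dir.exists(dir_in)) {
    stop("no cohort '", cancer_type, "' in knowledge base ", kb_dir,
         " (run the ingest step first)")
  }
  label_file <- file.path(dir_in, "label.txt")
  label <- if (file.exists(label_file)) readLines(label_file, warn = FALSE)[1] else cancer_type
  mut <- load_mutations(file.path(dir_in, "mutations.tsv"),
                        caller_set = unique(unlist(strsplit(
                          utils::read.delim(file.path(dir_in, "mutations.tsv"),
                                            colClasses = "character")$callers,
                          ";", fixed = TRUE))))
  cna <- load_cna(file.path(dir_in, "cna.tsv"))
  expr <- load_expression(file.path(dir_in, "expression.tsv"))
  manifest <- utils::read.delim(file.path(dir_in, "manifest.tsv"),
                                colClasses = c(sample_id = "character"))
  structure(list(cancer_type = label, manifest = manifest, mutations = mut,
                 cna = cna, expression = expr),
            class = "cohort_dataset")
}

#' Assemble a cohort dataset in memory
#'
#' @param cancer_type Cohort label.
#' @param mutations Post-filter mutation records.
#' @param cna CNA records.
#' @param expression Expression matrix (genes x samples).
#' @param manifest Sample-by-assay availability data frame.
#' @return A `cohort_dataset`.
#' @export
cohort_dataset <- function(cancer_type, mutations, cna, expression, manifest) {
  structure(list(cancer_type = cancer_type, manifest = manifest,
                 mutations = mutations, cna = cna, expression = expression),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s: %d samples, %d mutation records, %d CNA records, %d expression genes\n",
              x$cancer_type, nrow(x$manifest), nrow(x$mutations),
              nrow(x$cna), nrow(x$expression)))
  invisible(x)
}

assay_samples <- function(dataset, assay) {
  m <- dataset$manifest
  if (!assay %in% names(m)) stop("manifest lacks assay column: ", assay)
  m$sample_id[m[[assay]] == 1L]
}

#' Mutation frequency of one gene in a cohort
#'
#' The numerator is the number of distinct samples carrying at least one
#' post-filter mutation in the gene (multiple qualifying mutations in one
#' sample count once); the denominator is the number of samples in the
#' cohort's mutation-assay manifest.
#'
#' @param dataset A `cohort_dataset`.
#' @param gene Gene symbol; a gene absent from the records has frequency 0.
#' @return A `gene_stats` list: gene, cancer_type, altered_sample_count,
#'   cohort_size, frequency.
#' @export
mutation_frequency <- function(dataset, gene) {
  cohort <- assay_samples(dataset, "mutations")
  if (length(cohort) == 0L) stop("empty cohort: no samples with mutation data")
  hits <- dataset$mutations[dataset$mutations$gene == gene &
                            dataset$mutations$sample_id %in% cohort, , drop = FALSE]
  k <- length(unique(hits$sample_id))
  structure(list(gene = gene, cancer_type = dataset$cancer_type,
                 altered_sample_count = k, cohort_size = length(cohort),
                 frequency = k / length(cohort), kind = "mutation"),
            class = "gene_stats")
}

#' @export
print.gene_stats <- function(x, ...) {
  cat(sprintf("<gene_stats> %s in %s: %d/%d samples (%.1f%%) [%s]\n",
              x$gene, x$cancer_type, x$altered_sample_count, x$cohort_size,
              100 * x$frequency, x$kind))
  invisible(x)
}

#' Most frequently mutated genes
#'
#' Genes ranked by post-filter mutation frequency, descending; ties broken
#' lexicographically by symbol for reproducible output.
#'
#' @param dataset A `cohort_dataset`.
#' @param k Number of genes to report (at least 1); the result has
#'   `min(k, genes present)` rows.
#' @return Data frame: gene, altered_sample_count, cohort_size, frequency.
#' @export
top_mutated_genes <- function(dataset, k = 10L) {
  stopifnot(k >= 1L)
  cohort <- assay_samples(dataset, "mutations")
  recs <- dataset$mutations[dataset$mutations$sample_id %in% cohort, , drop = FALSE]
  counts <- tapply(recs$sample_id, recs$gene,
                   function(s) length(unique(s)))
  if (length(counts) == 0L) {
    return(data.frame(gene = character(0), altered_sample_count = integer(0),
                      cohort_size = integer(0), frequency = numeric(0)))
  }
  df <- data.frame(gene = names(counts),
                   altered_sample_count = as.integer(counts),
                   cohort_size = length(cohort),
                   frequency = as.integer(counts) / length(cohort))
  df <- df[order(-df$frequency, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Amplification and deletion frequencies of one gene
#'
#' Per-category frequencies with denominator the number of samples in the
#' CNA-assay manifest.
#'
#' @param dataset A `cohort_dataset`.
#' @param gene Gene symbol.
#' @return List with `amplification` and `deletion` `gene_stats`.
#' @export
cna_frequency <- function(dataset, gene) {
  cohort <- assay_samples(dataset, "cna")
  if (length(cohort) == 0L) stop("empty cohort: no samples with CNA data")
  recs <- dataset$cna[dataset$cna$gene == gene &
                      dataset$cna$sample_id %in% cohort, , drop = FALSE]
  one <- function(cat) {
    k <- length(unique(recs$sample_id[recs$category == cat]))
    structure(list(gene = gene, cancer_type = dataset$cancer_type,
                   altered_sample_count = k, cohort_size = length(cohort),
                   frequency = k / length(cohort), kind = cat),
              class = "gene_stats")
  }
  list(amplification = one("amplification"), deletion = one("deletion"))
}

#' Expression summary of one gene
#'
#' @param dataset A `cohort_dataset`.
#' @param gene Gene symbol; an absent gene is an error (distinct from a
#'   present gene whose values are all missing).
#' @return List: gene, n, mean, median, sd, min, max (missing values are
#'   excluded from `n`).
#' @export
expression_summary <- function(dataset, gene) {
  if (!gene %in% rownames(dataset$expression)) {
    stop("gene not in expression matrix: ", gene)
  }
  v <- dataset$expression[gene, ]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(list(gene = gene, n = 0L, mean = NA_real_, median = NA_real_,
                sd = NA_real_, min = NA_real_, max = NA_real_))
  }
  list(gene = gene, n = length(v), mean = mean(v), median = stats::median(v),
       sd = stats::sd(v), min = min(v), max = max(v))
}

# samples with at least one post-filter mutation in `gene`
mutant_samples <- function(dataset, gene) {
  unique(dataset$mutations$sample_id[dataset$mutations$gene == gene])
}

#' Compare two attribute values of the same type
#'
#' Three comparison modes, one per attribute type:
#' \describe{
#'   \item{DATA_TYPE}{for the state's gene, a 2x2 contingency of alteration
#'     status under the two data types (e.g. mutations vs copy number
#'     alterations) over samples present in both assays.}
#'   \item{GENE}{mutation frequencies of both genes plus the co-mutated
#'     sample count, over the mutation-assay manifest.}
#'   \item{CANCER_TYPE}{the focal gene's mutation frequency in each of two
#'     cohorts (a second dataset must be supplied).}
#' }
#'
#' @param dataset A `cohort_dataset` (the state's cohort).
#' @param state A `nav_state` supplying the fixed slots.
#' @param attribute_type The attribute type being compared.
#' @param value_b The second value of that type.
#' @param dataset_b Second `cohort_dataset` for CANCER_TYPE comparison.
#' @return A `compare_result`.
#' @export
compare_attributes <- function(dataset, state, attribute_type, value_b,
                               dataset_b = NULL) {
  if (attribute_type == "DATA_TYPE") {
    gene <- state$gene
    if (is.na(gene)) stop("data-type comparison requires a gene in the state")
    shared <- intersect(assay_samples(dataset, "mutations"),
                        assay_samples(dataset, "cna"))
    mut <- intersect(mutant_samples(dataset, gene), shared)
    cna_alt <- unique(dataset$cna$sample_id[
      dataset$cna$gene == gene &
      dataset$cna$category %in% c("amplification", "deletion")])
    cna_alt <- intersect(cna_alt, shared)
    both <- length(intersect(mut, cna_alt))
    contingency <- c(a_only = length(mut) - both,
                     b_only = length(cna_alt) - both,
                     both = both,
                     neither = length(shared) - length(union(mut, cna_alt)))
    return(structure(list(attribute_type = attribute_type,
                          value_a = state$data_type, value_b = value_b,
                          gene = gene, n = length(shared),
                          contingency = contingency),
                     class = "compare_result"))
  }
  if (attribute_type == "GENE") {
    gene_a <- state$gene
    if (is.na(gene_a)) stop("gene comparison requires a gene in the state")
    cohort <- assay_samples(dataset, "mutations")
    sa <- intersect(mutant_samples(dataset, gene_a), cohort)
    sb <- intersect(mutant_samples(dataset, value_b), cohort)
    return(structure(list(attribute_type = attribute_type,
                          value_a = gene_a, value_b = value_b,
                          n = length(cohort),
                          freq_a = length(sa) / length(cohort),
                          freq_b = length(sb) / length(cohort),
                          co_mutated = length(intersect(sa, sb))),
                     class = "compare_result"))
  }
  if (attribute_type == "CANCER_TYPE") {
    if (is.null(dataset_b)) stop("cancer-type comparison needs a second cohort")
    gene <- state$gene
    if (is.na(gene)) stop("cancer-type comparison requires a gene in the state")
    fa <- mutation_frequency(dataset, gene)
    fb <- mutation_frequency(dataset_b, gene)
    return(structure(list(attribute_type = attribute_type,
                          value_a = dataset$cancer_type,
                          value_b = dataset_b$cancer_type,
                          gene = gene,
                          freq_a = fa$frequency, freq_b = fb$frequency,
                          n_a = fa$cohort_size, n_b = fb$cohort_size),
                     class = "compare_result"))
  }
  stop("unknown attribute_type for comparison: ", attribute_type)
}

#' Stratify a gene's expression by another gene's mutation status
#'
#' Splits samples that have both expression values and mutation-assay
#' coverage into mutant / wild-type groups by the post-filter mutation
#' status of `partition_gene`, summarizes the quantitative variable per
#' group, and tests for a location difference (two-sided Wilcoxon rank-sum
#' by default; Welch t-test available).
#'
#' @param dataset A `cohort_dataset`.
#' @param quant_gene Gene whose expression is the quantitative variable.
#' @param partition_gene Gene whose mutation status partitions samples.
#' @param test "wilcoxon" (default) or "welch".
#' @return A `splitby_result`: per-group n / mean / median / sd, statistic,
#'   p_value, test name. If either group is empty the result is
#'   descriptive-only (`p_value` NA) with a warning.
#' @export
split_by <- function(dataset, quant_gene, partition_gene,
                     test = c("wilcoxon", "welch")) {
  test <- match.arg(test)
  if (!quant_gene %in% rownames(dataset$expression)) {
    stop("gene not in expression matrix: ", quant_gene)
  }
  v <- dataset$expression[quant_gene, ]
  eligible <- intersect(names(v)[!is.na(v)], assay_samples(dataset, "mutations"))
  mut <- intersect(eligible, mutant_samples(dataset, partition_gene))
  wt <- setdiff(eligible, mut)
  grp <- function(samples) {
    x <- v[samples]
    list(n = length(x),
         mean = if (length(x)) mean(x) else NA_real_,
         median = if (length(x)) stats::median(x) else NA_real_,
         sd = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  res <- list(quant_gene = quant_gene, partition_gene = partition_gene,
              group_mutant = grp(mut), group_wildtype = grp(wt),
              statistic = NA_real_, p_value = NA_real_, test = test,
              n_eligible = length(eligible))
  if (length(mut) == 0L || length(wt) == 0L) {
    warning("one group is empty; returning descriptive summaries only")
    return(structure(res, class = "splitby_result"))
  }
  ht <- if (test == "wilcoxon") {
    stats::wilcox.test(v[mut], v[wt], alternative = "two.sided", exact = FALSE)
  } else {
    stats::t.test(v[mut], v[wt], alternative = "two.sided", var.equal = FALSE)
  }
  res$statistic <- unname(ht$statistic)
  res$p_value <- ht$p.value
  structure(res, class = "splitby_result")
}

#' @export
print.splitby_result <- function(x, ...) {
  cat(sprintf("<splitby_result> %s expression by %s status: mutant n=%d (mean %.2f), wild-type n=%d (mean %.2f), %s p=%.3g\n",
              x$quant_gene, x$partition_gene, x$group_mutant$n,
              x$group_mutant$mean, x$group_wildtype$n, x$group_wildtype$mean,
              x$test, x$p_value))
  invisible(x)
}
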