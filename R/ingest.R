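# Harmonization of raw cohort tables into the knowledge base: multi-caller
# consensus filtering, functional-impact gating, coding-gene whitelisting,
# CNA category checks, and the both-assays sample rule.

VARIANT_CLASSES <- c("SNV", "INS", "DEL")
IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
CNA_CATEGORIES <- c("amplification", "neutral", "deletion")
DEFAULT_CALLERS <- c("mutect2", "somaticsniper", "varscan", "muse")

#' Consensus policy for somatic mutation filtering
#'
#' MAJORITY mode mirrors multi-caller exome harmonization: an SNV is kept
#' when called by at least `snv_min_callers` of the SNV caller set, and an
#' indel only when called by every caller in the indel set (indels are
#' typically emitted by just two of the callers, so both are required).
#' UNION mode keeps any record supported by at least one caller of the
#' configured pair, as used for whole-genome call sets built as caller
#' unions. Records then pass an impact gate keeping only the listed
#' functional impact levels.
#'
#' @param mode "MAJORITY" or "UNION".
#' @param snv_caller_set Callers considered for SNVs.
#' @param snv_min_callers Minimum supporting callers for an SNV (MAJORITY).
#' @param indel_caller_set Callers considered for indels.
#' @param impact_keep Impact levels retained.
#' @return A `consensus_policy`.
#' @export
consensus_policy <- function(mode = c("MAJORITY", "UNION"),
                             snv_caller_set = DEFAULT_CALLERS,
                             snv_min_callers = 2L,
                             indel_caller_set = c("mutect2", "varscan"),
                             impact_keep = c("HIGH", "MODERATE")) {
  mode <- match.arg(mode)
  stopifnot(snv_min_callers <= length(snv_caller_set),
            all(impact_keep %in% IMPACT_LEVELS))
  structure(list(mode = mode, snv_caller_set = snv_caller_set,
                 snv_min_callers = as.integer(snv_min_callers),
                 indel_caller_set = indel_caller_set,
                 impact_keep = impact_keep),
            class = "consensus_policy")
}

#' Load a mutation TSV
#'
#' The mutation dialect is a minimal five-column TSV: `sample_id`, `gene`,
#' `variant_class` (SNV|INS|DEL), `impact` (HIGH|MODERATE|LOW|MODIFIER) and
#' `callers` (semicolon-separated caller names). Gene symbols are
#' uppercase-normalized at load, with a warning when any change.
#'
#' @param path TSV path.
#' @param caller_set Allowed caller names; unknown names are a load error.
#' @return Data frame of raw mutation records; `callers` is a list column of
#'   character vectors.
#' @export
load_mutations <- function(path, caller_set = DEFAULT_CALLERS) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  need <- c("sample_id", "gene", "variant_class", "impact", "callers")
  if (!all(need %in% names(df))) {
    stop("mutation table requires columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty mutation table: ", path)
  bad_vc <- which(!df$variant_class %in% VARIANT_CLASSES)
  if (length(bad_vc)) {
    stop("bad variant_class at row(s) ", paste(utils::head(bad_vc, 5), collapse = ", "),
         ": ", paste(utils::head(unique(df$variant_class[bad_vc]), 5), collapse = ", "))
  }
  bad_imp <- which(!df$impact %in% IMPACT_LEVELS)
  if (length(bad_imp)) {
    stop("bad impact at row(s) ", paste(utils::head(bad_imp, 5), collapse = ", "),
         ": ", paste(utils::head(unique(df$impact[bad_imp]), 5), collapse = ", "))
  }
  callers <- strsplit(df$callers, ";", fixed = TRUE)
  if (any(lengths(callers) == 0L)) stop("record with empty callers field")
  unknown <- setdiff(unique(unlist(callers)), caller_set)
  if (length(unknown)) {
    stop("unknown caller name(s): ", paste(unknown, collapse = ", "))
  }
  up <- toupper(df$gene)
  if (any(up != df$gene)) {
    warning("gene symbols uppercase-normalized at load (",
            sum(up != df$gene), " records)")
    df$gene <- up
  }
  df$callers <- callers
  df[, c("sample_id", "gene", "variant_class", "impact", "callers")]
}

#' Apply the consensus caller and impact filter
#'
#' @param records Mutation records from [load_mutations()].
#' @param policy A `consensus_policy`.
#' @return The kept records.
#' @export
apply_consensus_filter <- function(records, policy) {
  stopifnot(inherits(policy, "consensus_policy"))
  if (nrow(records) == 0L) return(records)
  is_indel <- records$variant_class %in% c("INS", "DEL")
  keep_caller <- vapply(seq_len(nrow(records)), function(i) {
    cs <- records$callers[[i]]
    if (policy$mode == "UNION") {
      set <- if (is_indel[i]) policy$indel_caller_set else policy$snv_caller_set
      length(intersect(cs, set)) >= 1L
    } else if (is_indel[i]) {
      all(policy$indel_caller_set %in% cs)
    } else {
      length(intersect(cs, policy$snv_caller_set)) >= policy$snv_min_callers
    }
  }, logical(1))
  keep <- keep_caller & records$impact %in% policy$impact_keep
  records[keep, , drop = FALSE]
}

#' Restrict records to a coding-gene whitelist
#'
#' @param records Mutation (or CNA) records with a `gene` column.
#' @param whitelist Character vector of gene symbols (e.g. a consensus
#'   coding sequence gene set); matching is case-sensitive.
#' @return The records whose gene is on the whitelist.
#' @export
apply_gene_whitelist <- function(records, whitelist) {
  if (length(whitelist) == 0L) stop("empty gene whitelist (suspicious input)")
  records[records$gene %in% whitelist, , drop = FALSE]
}

#' Read a gene whitelist file (one symbol per line)
#' @param path Text file path.
#' @return Character vector of symbols.
#' @export
read_gene_whitelist <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Load a gene-level CNA TSV
#'
#' Columns: `sample_id`, `gene`, `category` (amplification|neutral|deletion).
#' Duplicate (sample, gene) rows are a load error.
#'
#' @param path TSV path.
#' @return Data frame of CNA records.
#' @export
load_cna <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  need <- c("sample_id", "gene", "category")
  if (!all(need %in% names(df))) {
    stop("CNA table requires columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!df$category %in% CNA_CATEGORIES)
  if (length(bad)) {
    stop("unknown CNA category at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(utils::head(unique(df$category[bad]), 5), collapse = ", "))
  }
  key <- paste(df$sample_id, df$gene)
  if (anyDuplicated(key)) {
    stop("duplicate (sample, gene) CNA rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  df$gene <- toupper(df$gene)
  df
}

#' Load an expression matrix TSV
#'
#' First column `gene`, remaining columns are sample ids; cells numeric
#' (values are taken as already normalized / log scale).
#'
#' @param path TSV path.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
load_expression <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1] != "gene") stop("expression table must start with a 'gene' column")
  genes <- toupper(as.character(df$gene))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression cell(s) in ", path)
  rownames(m) <- genes
  m
}

#' Build the knowledge base for one cancer type
#'
#' Applies the consensus and whitelist filters to the mutation records,
#' whitelists CNA and expression genes, and writes the explorer's directory
#' layout: `<kb_dir>/<cancer_type>/{mutations.tsv, cna.tsv, expression.tsv,
#' manifest.tsv}`. The manifest records per-sample assay availability; with
#' `require_both = TRUE` it is restricted to samples present in both the
#' mutation and CNA inputs (the rule used for cohorts distributed only with
#' complete DNA data).
#'
#' @param mutations Raw mutation records ([load_mutations()]).
#' @param cna CNA records ([load_cna()]).
#' @param expression Expression matrix ([load_expression()]).
#' @param policy A `consensus_policy`.
#' @param whitelist Gene whitelist (character vector).
#' @param kb_dir Knowledge-base root directory.
#' @param cancer_type Canonical cancer type label (directory name is its
#'   slug).
#' @param sample_manifest Optional data frame `sample_id`, `mutations`,
#'   `cna`, `expression` (1/0 assay availability). When absent it is derived
#'   from the samples observed in each input table.
#' @param require_both Restrict the manifest to samples with both mutation
#'   and CNA data.
#' @return The cohort directory path, invisibly.
#' @export
build_knowledge_base <- function(mutations, cna, expression, policy,
                                 whitelist, kb_dir, cancer_type,
                                 sample_manifest = NULL,
                                 require_both = FALSE) {
  filt <- apply_consensus_filter(mutations, policy)
  filt <- apply_gene_whitelist(filt, whitelist)
  cna_w <- apply_gene_whitelist(cna, whitelist)
  expr_w <- expression[rownames(expression) %in% whitelist, , drop = FALSE]

  if (is.null(sample_manifest)) {
    all_samples <- sort(unique(c(mutations$sample_id, cna$sample_id,
                                 colnames(expression))))
    sample_manifest <- data.frame(
      sample_id = all_samples,
      mutations = as.integer(all_samples %in% mutations$sample_id),
      cna = as.integer(all_samples %in% cna$sample_id),
      expression = as.integer(all_samples %in% colnames(expression)))
  }
  if (require_both) {
    keep <- sample_manifest$mutations == 1L & sample_manifest$cna == 1L
    sample_manifest <- sample_manifest[keep, , drop = FALSE]
    filt <- filt[filt$sample_id %in% sample_manifest$sample_id, , drop = FALSE]
    cna_w <- cna_w[cna_w$sample_id %in% sample_manifest$sample_id, , drop = FALSE]
    keep_cols <- colnames(expr_w) %in% sample_manifest$sample_id
    expr_w <- expr_w[, keep_cols, drop = FALSE]
  }
  if (nrow(sample_manifest) == 0L) stop("zero surviving samples")

  dir_out <- file.path(kb_dir, gsub("[^A-Za-z0-9]+", "_", cancer_type))
  dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)
  mut_out <- filt
  mut_out$callers <- vapply(mut_out$callers, paste, character(1), collapse = ";")
  utils::write.table(mut_out, file.path(dir_out, "mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cna_w, file.path(dir_out, "cna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr_df <- data.frame(gene = rownames(expr_w), expr_w, check.names = FALSE)
  utils::write.table(expr_df, file.path(dir_out, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sample_manifest, file.path(dir_out, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cancer_type, file.path(dir_out, "label.txt"))
  invisible(dir_out)
}
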