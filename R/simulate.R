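# Seeded synthetic generators: cohorts with planted mutation/CNA rates and
# expression shifts, gene/cancer-type/data-type lexicons, and perturbed
# pronunciation corpora. Every generator is a deterministic function of its
# seed, and every planted parameter is recorded in a truth object so tests
# can check recovery.

#' Specification of a synthetic cohort
#'
#' Planted structure: each gene mutates each sample independently at its
#' `mut_rate`; a planted mutation always carries qualifying evidence (at
#' least the minimum caller support and a MODERATE/HIGH impact) so the
#' post-filter mutation frequency is an exact binomial draw of the planted
#' rate. Separately, spurious sub-threshold records (single-caller or
#' LOW/MODIFIER impact) are emitted at `false_call_rate` per gene-sample so
#' the consensus filter has genuine work to do. Expression is per-gene
#' Gaussian with an additive shift, in standard-deviation units, applied to
#' samples mutant in a partner gene.
#'
#' @param n_samples Cohort size.
#' @param genes Data frame with columns `gene`, `mut_rate`, `amp_rate`,
#'   `del_rate`, `expr_mean`, `expr_sd`. Defaults to a 20-gene panel with
#'   rates spanning 0.05-0.6 and expression N(5, 1).
#' @param shifts Data frame `quant_gene`, `partition_gene`, `shift_sd`
#'   (expression shift in sd units for mutants of the partner gene).
#' @param caller_sensitivity Probability each additional caller supports a
#'   planted SNV beyond the two guaranteed ones.
#' @param false_call_rate Per gene-sample rate of spurious sub-threshold
#'   records among unmutated samples.
#' @param indel_fraction Fraction of planted mutations that are indels
#'   (carrying both indel callers).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 1000L, genes = NULL, shifts = NULL,
                        caller_sensitivity = 0.9, false_call_rate = 0.05,
                        indel_fraction = 0.2, seed = 1L) {
  if (is.null(genes)) {
    syms <- c("TP53", "PIK3CA", "KRAS", "MYC", "BRCA1", "BRCA2", "EGFR",
              "PTEN", "RB1", "APC", "CDH1", "GATA3", "MAP3K1", "NF1",
              "ARID1A", "CTCF", "AKT1", "ERBB2", "CCND1", "MDM2")
    genes <- data.frame(
      gene = syms,
      mut_rate = round(seq(0.6, 0.05, length.out = length(syms)), 3),
      amp_rate = rep(c(0.15, 0.05), length.out = length(syms)),
      del_rate = rep(c(0.05, 0.10), length.out = length(syms)),
      expr_mean = 5, expr_sd = 1)
  }
  if (is.null(shifts)) {
    shifts <- data.frame(quant_gene = "PIK3CA", partition_gene = "TP53",
                         shift_sd = 2)
  }
  stopifnot(n_samples >= 1L,
            all(genes$mut_rate >= 0 & genes$mut_rate <= 1),
            all(genes$amp_rate + genes$del_rate <= 1))
  structure(list(n_samples = as.integer(n_samples), genes = genes,
                 shifts = shifts, caller_sensitivity = caller_sensitivity,
                 false_call_rate = false_call_rate,
                 indel_fraction = indel_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Writes (or returns in memory) the raw TSV bundle in the ingest dialect —
#' mutations with per-caller evidence, gene-level CNA categories, a gene x
#' sample expression matrix and a sample/assay manifest — plus a truth
#' object recording every planted rate and shift.
#'
#' @param spec A `cohort_spec`.
#' @param out_dir Output directory; when `NULL` nothing is written and the
#'   tables are returned in memory only.
#' @param cancer_type Label attached to the cohort.
#' @return List: `mutations`, `cna`, `expression`, `manifest`, `truth`, and
#'   `paths` when written.
#' @export
generate_cohort <- function(spec, out_dir = NULL, cancer_type = "synthetic cohort") {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    samples <- sprintf("S%04d", seq_len(spec$n_samples))
    callers <- DEFAULT_CALLERS
    mut_rows <- list()
    mut_status <- list() # gene -> logical vector over samples
    for (gi in seq_len(nrow(spec$genes))) {
      g <- spec$genes$gene[gi]
      mutated <- stats::runif(spec$n_samples) < spec$genes$mut_rate[gi]
      mut_status[[g]] <- mutated
      for (si in which(mutated)) {
        is_indel <- stats::runif(1) < spec$indel_fraction
        if (is_indel) {
          vc <- sample(c("INS", "DEL"), 1)
          cs <- c("mutect2", "varscan")
        } else {
          vc <- "SNV"
          base <- sample(callers, 2)
          extra <- setdiff(callers, base)
          cs <- c(base, extra[stats::runif(length(extra)) < spec$caller_sensitivity])
        }
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          sample_id = samples[si], gene = g, variant_class = vc,
          impact = sample(c("MODERATE", "HIGH"), 1),
          callers = paste(sort(cs), collapse = ";"))
      }
      # spurious sub-threshold records in unmutated samples
      for (si in which(!mutated & stats::runif(spec$n_samples) < spec$false_call_rate)) {
        if (stats::runif(1) < 0.5) {
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            sample_id = samples[si], gene = g, variant_class = "SNV",
            impact = sample(c("MODERATE", "HIGH"), 1),
            callers = sample(callers, 1))
        } else {
          mut_rows[[length(mut_rows) + 1L]] <- data.frame(
            sample_id = samples[si], gene = g, variant_class = "SNV",
            impact = sample(c("LOW", "MODIFIER"), 1),
            callers = paste(sort(sample(callers, 3)), collapse = ";"))
        }
      }
    }
    mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
      data.frame(sample_id = character(0), gene = character(0),
                 variant_class = character(0), impact = character(0),
                 callers = character(0))

    cna_rows <- lapply(seq_len(nrow(spec$genes)), function(gi) {
      g <- spec$genes$gene[gi]
      u <- stats::runif(spec$n_samples)
      cat <- ifelse(u < spec$genes$amp_rate[gi], "amplification",
             ifelse(u < spec$genes$amp_rate[gi] + spec$genes$del_rate[gi],
                    "deletion", "neutral"))
      data.frame(sample_id = samples, gene = g, category = cat)
    })
    cna <- do.call(rbind, cna_rows)

    expr <- matrix(NA_real_, nrow(spec$genes), spec$n_samples,
                   dimnames = list(spec$genes$gene, samples))
    for (gi in seq_len(nrow(spec$genes))) {
      expr[gi, ] <- stats::rnorm(spec$n_samples, spec$genes$expr_mean[gi],
                                 spec$genes$expr_sd[gi])
    }
    for (si in seq_len(nrow(spec$shifts))) {
      qg <- spec$shifts$quant_gene[si]
      pg <- spec$shifts$partition_gene[si]
      if (qg %in% rownames(expr) && pg %in% names(mut_status)) {
        sd_g <- spec$genes$expr_sd[spec$genes$gene == qg][1]
        expr[qg, mut_status[[pg]]] <- expr[qg, mut_status[[pg]]] +
          spec$shifts$shift_sd[si] * sd_g
      }
    }

    manifest <- data.frame(sample_id = samples, mutations = 1L, cna = 1L,
                           expression = 1L)
    truth <- list(
      seed = spec$seed, n_samples = spec$n_samples,
      cancer_type = cancer_type,
      planted_mut_rate = stats::setNames(as.list(spec$genes$mut_rate),
                                         spec$genes$gene),
      planted_amp_rate = stats::setNames(as.list(spec$genes$amp_rate),
                                         spec$genes$gene),
      planted_del_rate = stats::setNames(as.list(spec$genes$del_rate),
                                         spec$genes$gene),
      planted_mutant_count = stats::setNames(
        lapply(mut_status, sum), names(mut_status)),
      shifts = spec$shifts)

    out <- list(mutations = mutations, cna = cna, expression = expr,
                manifest = manifest, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(out_dir, f)
      utils::write.table(mutations, p("mutations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(cna, p("cna.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      expr_df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
      utils::write.table(expr_df, p("expression.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                           pretty = TRUE, dataframe = "rows")
      out$paths <- list(mutations = p("mutations.tsv"), cna = p("cna.tsv"),
                        expression = p("expression.tsv"),
                        manifest = p("manifest.tsv"), truth = p("truth.json"))
    }
    out
  })
}

#' Generate a synthetic attribute lexicon
#'
#' Synthetic gene-like symbols (letters plus digits), multiword cancer-type
#' names with synonyms, and the three standard genomic data types
#' (mutations, copy number alterations, gene expression) with synonyms.
#'
#' @param n_genes Number of gene symbols.
#' @param n_cancer_types Number of cancer types (at most 16).
#' @param n_data_types Number of data types; the three standard types are
#'   always present and come first.
#' @param seed Integer seed.
#' @return A `term_lexicon`.
#' @export
generate_lexicon <- function(n_genes = 50L, n_cancer_types = 10L,
                             n_data_types = 3L, seed = 1L) {
  stopifnot(n_genes >= 1L, n_cancer_types >= 1L, n_data_types >= 3L)
  with_seed(seed, {
    syms <- character(0)
    while (length(syms) < n_genes) {
      nl <- sample(2:4, 1)
      nd <- sample(1:2, 1)
      s <- paste0(paste(sample(LETTERS, nl, replace = TRUE), collapse = ""),
                  paste(sample(0:9, nd, replace = TRUE), collapse = ""))
      syms <- unique(c(syms, s))
    }
    syms <- syms[seq_len(n_genes)]

    sites <- c("breast", "lung", "colon", "skin", "brain", "kidney", "liver",
               "ovarian", "gastric", "prostate", "pancreatic", "bladder",
               "thyroid", "cervical", "endometrial", "testicular")
    stopifnot(n_cancer_types <= length(sites))
    sites <- sample(sites, n_cancer_types)
    ct <- data.frame(value = paste(sites, "cancer"),
                     attribute_type = "CANCER_TYPE",
                     synonyms = paste0(sites, " carcinoma|", sites, " tumor"))

    dt <- data.frame(
      value = c("mutations", "copy number alterations", "gene expression",
                "dna methylation", "protein abundance"),
      attribute_type = "DATA_TYPE",
      synonyms = c("mutation|snvs and indels",
                   "copy number|cna|copy number alteration",
                   "expression|rna expression",
                   "methylation", "proteomics"))
    dt <- dt[seq_len(min(n_data_types, nrow(dt))), , drop = FALSE]

    gn <- data.frame(value = syms, attribute_type = "GENE", synonyms = "")
    term_lexicon(rbind(gn, ct, dt))
  })
}

#' Specification of pronunciation perturbations
#'
#' The perturbation inventory emulates how speech-to-text garbles
#' domain-specific terms: digits spelled out as words, letters expanded to
#' their spoken names, phonetic substitutions within word tokens, token
#' splitting/joining, and character drops. Each operation applies
#' independently with probability `noise_level`; at noise 0 every
#' transcription equals its term verbatim.
#'
#' @param noise_level Probability in `[0, 1]` that each operation applies.
#' @param variants_per_term Transcriptions generated per term.
#' @param seed Integer seed.
#' @return A `perturbation_spec`.
#' @export
perturbation_spec <- function(noise_level = 0.3, variants_per_term = 10L,
                              seed = 1L) {
  stopifnot(noise_level >= 0, noise_level <= 1, variants_per_term >= 1L)
  structure(list(noise_level = noise_level,
                 variants_per_term = as.integer(variants_per_term),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

LETTER_NAMES <- c(a = "ay", b = "bee", c = "see", d = "dee", e = "ee",
                  f = "eff", g = "gee", h = "aitch", i = "eye", j = "jay",
                  k = "kay", l = "ell", m = "em", n = "en", o = "oh",
                  p = "pee", q = "cue", r = "are", s = "ess", t = "tee",
                  u = "you", v = "vee", w = "double you", x = "ex",
                  y = "why", z = "zee")
DIGIT_NAMES <- c("zero", "one", "two", "three", "four", "five", "six",
                 "seven", "eight", "nine")

# one perturbed transcription of a term; caller controls the RNG state
perturb_term <- function(term, noise_level) {
  if (noise_level == 0) return(term)
  x <- tolower(term)
  gene_like <- grepl("^[a-z]+[0-9]+[a-z0-9]*$", gsub(" ", "", x))
  # letter-name expansion (gene-like tokens): "tp" -> "tee pee"
  if (gene_like && stats::runif(1) < noise_level) {
    chars <- strsplit(gsub(" ", "", x), "")[[1]]
    x <- paste(vapply(chars, function(ch) {
      if (ch %in% names(LETTER_NAMES)) LETTER_NAMES[[ch]] else ch
    }, character(1)), collapse = " ")
  }
  # digit spell-out: "53" -> "five three"
  if (stats::runif(1) < noise_level && grepl("[0-9]", x)) {
    chars <- strsplit(x, "")[[1]]
    x <- paste0(vapply(chars, function(ch) {
      if (grepl("[0-9]", ch)) paste0(" ", DIGIT_NAMES[as.integer(ch) + 1L], " ")
      else ch
    }, character(1)), collapse = "")
    x <- trimws(gsub("  +", " ", x))
  }
  # phonetic substitution within a word token
  if (stats::runif(1) < noise_level) {
    subs <- list(c("ph", "f"), c("c", "k"), c("s", "z"), c("i", "y"),
                 c("o", "u"), c("a", "e"), c("ee", "ea"))
    s <- subs[[sample(length(subs), 1)]]
    if (grepl(s[1], x, fixed = TRUE)) x <- sub(s[1], s[2], x, fixed = TRUE)
  }
  # token split or join
  if (stats::runif(1) < noise_level) {
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    if (length(toks) > 1 && stats::runif(1) < 0.5) {
      j <- sample(length(toks) - 1L, 1)
      toks <- c(utils::head(toks, j - 1L), paste0(toks[j], toks[j + 1L]),
                utils::tail(toks, length(toks) - j - 1L))
    } else {
      longest <- which.max(nchar(toks))
      if (nchar(toks[longest]) >= 4L) {
        cut <- sample(2:(nchar(toks[longest]) - 1L), 1)
        toks[longest] <- paste(substr(toks[longest], 1, cut),
                               substr(toks[longest], cut + 1L,
                                      nchar(toks[longest])))
      }
    }
    x <- paste(toks, collapse = " ")
  }
  # character drop from a long token
  if (stats::runif(1) < noise_level) {
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    longest <- which.max(nchar(toks))
    if (nchar(toks[longest]) >= 4L) {
      drop <- sample(nchar(toks[longest]), 1)
      toks[longest] <- paste0(substr(toks[longest], 1, drop - 1L),
                              substr(toks[longest], drop + 1L,
                                     nchar(toks[longest])))
    }
    x <- paste(toks, collapse = " ")
  }
  if (!nzchar(trimws(x))) x <- tolower(term)
  x
}

#' Generate a perturbed pronunciation corpus
#'
#' Emits `variants_per_term` transcriptions for every canonical lexicon
#' value, each labeled with its true target, plus a truth mapping.
#'
#' @param lexicon A `term_lexicon`.
#' @param spec A `perturbation_spec`.
#' @param out_path Optional TSV output path (a `.truth.json` sidecar is
#'   written next to it).
#' @return Utterance data frame (`transcription`, `target_value`,
#'   `attribute_type`, `speaker_id`, `norm`).
#' @export
generate_utterance_corpus <- function(lexicon, spec = perturbation_spec(),
                                      out_path = NULL) {
  stopifnot(inherits(lexicon, "term_lexicon"),
            inherits(spec, "perturbation_spec"))
  with_seed(spec$seed, {
    ent <- lexicon$entries
    rows <- lapply(seq_len(nrow(ent)), function(i) {
      data.frame(
        transcription = vapply(seq_len(spec$variants_per_term), function(j)
          perturb_term(ent$value[i], spec$noise_level), character(1)),
        target_value = ent$value[i],
        attribute_type = ent$attribute_type[i],
        speaker_id = sprintf("synthetic%02d",
                             seq_len(spec$variants_per_term)))
    })
    corpus <- do.call(rbind, rows)
    corpus$norm <- normalize_text(corpus$transcription)
    if (!is.null(out_path)) {
      utils::write.table(
        corpus[, c("transcription", "target_value", "attribute_type",
                   "speaker_id")],
        out_path, sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(seed = spec$seed, noise_level = spec$noise_level,
             variants_per_term = spec$variants_per_term,
             n_terms = nrow(ent), n_records = nrow(corpus)),
        paste0(out_path, ".truth.json"), auto_unbox = TRUE, pretty = TRUE)
    }
    corpus
  })
}
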