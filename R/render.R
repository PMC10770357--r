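# Figure/table export for analysis results: every renderer writes a PNG and
# a TSV with deterministic tabular content.

#' Render an analysis result to figure and table files
#'
#' Writes `<out_prefix>.png` and `<out_prefix>.tsv`. The TSV content is a
#' deterministic function of the result, so re-rendering the same input
#' reproduces it byte for byte.
#'
#' @param result A `gene_stats`, `compare_result`, `splitby_result`, or the
#'   data frame returned by [top_mutated_genes()].
#' @param out_prefix Output path prefix (directories must exist and be
#'   writable).
#' @param ... Unused.
#' @return Named character vector with the `figure` and `table` paths.
#' @export
render_result <- function(result, out_prefix, ...) UseMethod("render_result")

.write_outputs <- function(tab, plot, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  tsv <- paste0(out_prefix, ".tsv")
  png <- paste0(out_prefix, ".png")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ggplot2::ggsave(png, plot, width = 6, height = 4, dpi = 150)
  c(figure = png, table = tsv)
}

#' @export
render_result.gene_stats <- function(result, out_prefix, ...) {
  tab <- data.frame(gene = result$gene, cancer_type = result$cancer_type,
                    kind = result$kind,
                    altered_sample_count = result$altered_sample_count,
                    cohort_size = result$cohort_size,
                    frequency = result$frequency)
  df <- data.frame(status = c("altered", "unaltered"),
                   n = c(result$altered_sample_count,
                         result$cohort_size - result$altered_sample_count))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = c("#b2182b", "#969696")) +
    ggplot2::labs(title = sprintf("%s %s in %s", result$gene, result$kind,
                                  result$cancer_type),
                  x = NULL, y = "samples") +
    ggplot2::theme_minimal()
  .write_outputs(tab, p, out_prefix)
}

#' @export
render_result.data.frame <- function(result, out_prefix, ...) {
  stopifnot(all(c("gene", "frequency") %in% names(result)))
  df <- result
  df$gene <- factor(df$gene, levels = rev(df$gene))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$gene)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(title = "Most frequently altered genes",
                  x = "frequency", y = NULL) +
    ggplot2::theme_minimal()
  .write_outputs(result, p, out_prefix)
}

#' @export
render_result.compare_result <- function(result, out_prefix, ...) {
  if (!is.null(result$contingency)) {
    tab <- data.frame(cell = names(result$contingency),
                      n = as.integer(result$contingency))
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$cell, y = .data$n)) +
      ggplot2::geom_col(fill = "#762a83") +
      ggplot2::labs(title = sprintf("%s: %s vs %s (n = %d)", result$gene,
                                    result$value_a, result$value_b, result$n),
                    x = NULL, y = "samples") +
      ggplot2::theme_minimal()
  } else {
    tab <- data.frame(value = c(result$value_a, result$value_b),
                      frequency = c(result$freq_a, result$freq_b))
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$value,
                                           y = .data$frequency)) +
      ggplot2::geom_col(fill = "#1b7837") +
      ggplot2::labs(title = sprintf("Comparison (%s)", result$attribute_type),
                    x = NULL, y = "frequency") +
      ggplot2::theme_minimal()
  }
  .write_outputs(tab, p, out_prefix)
}

#' @export
render_result.splitby_result <- function(result, out_prefix, ...) {
  tab <- data.frame(
    group = c("mutant", "wildtype"),
    n = c(result$group_mutant$n, result$group_wildtype$n),
    mean = c(result$group_mutant$mean, result$group_wildtype$mean),
    median = c(result$group_mutant$median, result$group_wildtype$median),
    sd = c(result$group_mutant$sd, result$group_wildtype$sd),
    statistic = result$statistic, p_value = result$p_value,
    test = result$test)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = c("#b2182b", "#969696")) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(title = sprintf("%s expression by %s status (p = %.2g)",
                                  result$quant_gene, result$partition_gene,
                                  result$p_value),
                  x = sprintf("%s mutation status", result$partition_gene),
                  y = sprintf("%s expression", result$quant_gene)) +
    ggplot2::theme_minimal()
  .write_outputs(tab, p, out_prefix)
}
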