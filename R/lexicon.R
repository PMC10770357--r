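# Attribute-value lexicon: canonical genes, cancer types and data types with
# synonyms, plus the normalized lookup index used by exact matching.

ATTRIBUTE_TYPES <- c("GENE", "CANCER_TYPE", "DATA_TYPE")

#' Build a term lexicon from a data frame
#'
#' @param df Data frame with columns `value`, `attribute_type`
#'   (GENE|CANCER_TYPE|DATA_TYPE) and `synonyms` (pipe-separated string,
#'   possibly empty).
#' @return A `term_lexicon` object: the entry table plus a normalized
#'   key -> entry lookup index.
#' @details Loading fails if two entries share a normalized value within an
#'   attribute type, or if a synonym collides with a different entry's value
#'   after normalization.
#' @export
term_lexicon <- function(df) {
  need <- c("value", "attribute_type", "synonyms")
  if (!all(need %in% names(df))) {
    stop("lexicon requires columns: ", paste(need, collapse = ", "))
  }
  df$value <- as.character(df$value)
  df$attribute_type <- as.character(df$attribute_type)
  df$synonyms <- as.character(df$synonyms)
  df$synonyms[is.na(df$synonyms)] <- ""
  bad <- setdiff(unique(df$attribute_type), ATTRIBUTE_TYPES)
  if (length(bad)) stop("unknown attribute_type: ", paste(bad, collapse = ", "))

  # normalized canonical values must be unique within attribute type
  nv <- normalize_text(df$value)
  if (anyNA(nv)) stop("lexicon value normalizes to empty")
  key <- paste(df$attribute_type, nv)
  if (anyDuplicated(key)) {
    stop("duplicate normalized value within attribute type: ",
         paste(unique(df$value[duplicated(key) | duplicated(key, fromLast = TRUE)]),
               collapse = ", "))
  }

  rows <- list()
  for (i in seq_len(nrow(df))) {
    rows[[length(rows) + 1L]] <- data.frame(
      key = nv[i], value = df$value[i],
      attribute_type = df$attribute_type[i], stringsAsFactors = FALSE)
    syns <- strsplit(df$synonyms[i], "|", fixed = TRUE)[[1]]
    syns <- syns[nzchar(trimws(syns))]
    for (s in syns) {
      ks <- normalize_text(s)
      if (is.na(ks)) next
      rows[[length(rows) + 1L]] <- data.frame(
        key = ks, value = df$value[i],
        attribute_type = df$attribute_type[i], stringsAsFactors = FALSE)
    }
  }
  index <- do.call(rbind, rows)
  # a synonym colliding with a *different* entry's key is a load error;
  # a synonym repeating its own entry's value is harmless and deduplicated
  index <- unique(index)
  dup <- index$key[duplicated(index$key)]
  if (length(dup)) {
    stop("lexicon collision: key(s) map to multiple entries: ",
         paste(unique(dup), collapse = ", "))
  }
  structure(list(entries = df, index = index), class = "term_lexicon")
}

#' Read a lexicon TSV
#'
#' Expects a UTF-8 TSV with header columns `value`, `attribute_type`,
#' `synonyms` (pipe-separated, may be empty).
#'
#' @param path Path to the TSV file.
#' @return A `term_lexicon`.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", fileEncoding = "UTF-8")
  term_lexicon(df)
}

#' Write a lexicon TSV
#' @param lexicon A `term_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "term_lexicon"))
  utils::write.table(lexicon$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.term_lexicon <- function(x, ...) {
  tab <- table(x$entries$attribute_type)
  cat("<term_lexicon> ", nrow(x$entries), " entries (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      "), ", nrow(x$index), " lookup keys\n", sep = "")
  invisible(x)
}

# internal: vector lookup of normalized keys -> index rows (NA row if absent)
.lexicon_lookup <- function(lexicon, keys) {
  m <- match(keys, lexicon$index$key)
  lexicon$index[m, , drop = FALSE]
}
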